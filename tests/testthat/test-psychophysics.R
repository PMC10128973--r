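simulate_counts <- function(pse, sigma, levels, n) {
  data.frame(n_var = levels, n_trials = n,
             n_more = rbinom(length(levels), n,
                             pnorm((levels - pse) / sigma)))
}

test_that("probit fit recovers known parameters and maximizes the likelihood", {
  set.seed(14)
  f <- fit_probit(simulate_counts(5, 1, 1:9, 800))
  expect_true(f$converged)
  expect_lt(abs(f$pse - 5), 0.2)
  expect_lt(abs(f$sigma - 1), 0.2)
  # the fitted (pse, sigma) beat nearby parameter pairs in log-likelihood
  d <- simulate_counts(4, 1.5, 1:9, 400)
  f2 <- fit_probit(d)
  ll <- function(pse, sigma) {
    p <- pmin(pmax(pnorm((d$n_var - pse) / sigma), 1e-12), 1 - 1e-12)
    sum(d$n_more * log(p) + (d$n_trials - d$n_more) * log(1 - p))
  }
  ll_hat <- ll(f2$pse, f2$sigma)
  for (dp in c(-0.3, 0.3)) {
    expect_gte(ll_hat, ll(f2$pse + dp, f2$sigma))
    expect_gte(ll_hat, ll(f2$pse, f2$sigma * (1 + dp)))
  }
  # and F(PSE) = 0.5 by construction of the Probit parameterization
  expect_equal(pnorm((f2$pse - f2$pse) / f2$sigma), 0.5)
})

test_that("degenerate psychometric data are flagged, not fitted", {
  allzero <- data.frame(n_var = 1:5, n_trials = 50, n_more = 0)
  f <- fit_probit(allzero)
  expect_false(f$converged)
  expect_equal(f$sigma, 1e-3)
  step <- data.frame(n_var = 1:6, n_trials = 50,
                     n_more = c(0, 0, 0, 50, 50, 50))
  fs <- fit_probit(step)
  expect_false(fs$converged)           # complete separation: sigma at bound
  expect_equal(fs$sigma, 1e-3)
  expect_error(fit_probit(data.frame(n_var = c(1, 2), n_trials = 10,
                                     n_more = c(1, 9))), "3 distinct")
})

test_that("weber curve distinguishes Weber scaling from constant noise", {
  mkfit <- function(sigma, n_ref)
    structure(list(pse = n_ref, sigma = sigma, loglik = 0,
                   converged = TRUE, n_ref = n_ref), class = "probit_fit")
  refs <- 2:5
  prop <- weber_curve(lapply(refs, function(r) mkfit(0.4 * r, r)))
  expect_equal(attr(prop, "flatness"), 1, tolerance = 1e-12)
  expect_equal(prop$weber, rep(0.4, 4))
  const <- weber_curve(lapply(refs, function(r) mkfit(1, r)))
  expect_true(all(diff(const$weber) < 0))    # 1/N decay
  mixed <- lapply(refs, function(r) mkfit(0.4 * r, r))
  mixed[[2]]$converged <- FALSE
  expect_warning(wb <- weber_curve(mixed), "excluded")
  expect_equal(nrow(wb), 3)
  expect_error(weber_curve(list(mkfit(1, 2))), "2 reference")
})

test_that("2AFC on a noisy synthetic decoder is symmetric and monotone", {
  lib <- structure(list(freq = 1:30,
                        templates = vapply(1:5, function(N)
                          exp(-((1:30) - 5 * N)^2 / 6), numeric(30)),
                        numerosities = 1:5, n_traj = 1, spec = NULL,
                        window = c(0, 1), dt = 1, seed = NA),
                   class = "template_library")
  colnames(lib$templates) <- 1:5
  noisy_probe <- function(N) {
    structure(list(freq = lib$freq,
                   amp = pmax(lib$templates[, N] +
                                rnorm(30, sd = 0.25), 0),
                   dt = 1, n = NA), class = "amplitude_spectrum")
  }
  pd <- run_2afc(lib, n_ref = 3, n_var = 1:5, n_trials = 60, seed = 5,
                 probe_fun = noisy_probe)
  p <- pd$n_more / pd$n_trials
  expect_gt(p[1], -0.01); expect_lt(p[1], 0.25)
  expect_gt(p[5], 0.75)
  # equal numerosities: fair coin keeps the proportion near one half
  expect_gt(p[3], 0.3); expect_lt(p[3], 0.7)
  # reproducibility
  pd2 <- run_2afc(lib, n_ref = 3, n_var = 1:5, n_trials = 60, seed = 5,
                  probe_fun = noisy_probe)
  expect_identical(pd$n_more, pd2$n_more)
  ft <- fit_probit(pd)
  expect_true(ft$converged)
  expect_lt(abs(ft$pse - 3), 0.6)
})

test_that("probe banks decode consistently and feed psychometrics", {
  sp <- network_spec(6, "all_to_all", delta0 = 0)
  lib <- build_template_library(sp, 1:3, n_traj = 4, window = c(5, 10),
                                dt = 0.1, seed = 21)
  bank <- probe_bank(sp, 1:3, n_draws = 6, window = c(5, 10), dt = 0.1,
                     seed = 22)
  dec <- decode_bank(bank, lib)
  expect_equal(dim(dec), c(6, 3))
  expect_true(all(dec %in% 1:3))
  pd <- bank_psychometrics(dec, n_ref = 2, n_var = 1:3, seed = 23)
  expect_equal(attr(pd, "n_ref"), 2)
  expect_true(all(pd$n_more >= 0 & pd$n_more <= pd$n_trials))
  expect_identical(pd$n_more,
                   bank_psychometrics(dec, 2, 1:3, seed = 23)$n_more)
})
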