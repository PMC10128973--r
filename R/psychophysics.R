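# Virtual two-alternative forced choice (2AFC): which of two stimuli is
# more numerous? Probit psychometric fits and Weber-fraction analysis.

#' Probe generator over the quantum pipeline
#'
#' Returns a `function(N)` that simulates one fresh stimulus realization
#' at numerosity N and returns its space-averaged amplitude spectrum.
#' Draws from the current RNG stream, so a single seed upstream makes a
#' whole experiment reproducible.
#'
#' @param spec a [network_spec()]
#' @param protocol_fun function(N) giving the stimulus protocol
#' @param window,dt recording window and step
#' @param config a [solver_config()]
#' @return function(N) -> `amplitude_spectrum`
#' @export
quantum_probe_fun <- function(spec, protocol_fun = function(N)
                                protocol_spec(N),
                              window = c(10, 20), dt = 0.02,
                              config = solver_config()) {
  times <- record_grid(window, dt)
  function(N) {
    proto <- protocol_fun(N)
    proto$seed <- NULL
    ev <- sample_events(proto, spec)
    rec <- evolve_trajectory(spec, ev, times, config = config)
    space_average_spectrum(rec)
  }
}

#' Run a 2AFC numerosity-comparison block
#'
#' Per trial, one fresh probe at the reference numerosity and one at the
#' variable numerosity are simulated and decoded; the variable is judged
#' "more numerous" iff its decoded numerosity exceeds the reference's,
#' with a fair coin on equal decodes (trial outcomes stay Bernoulli).
#'
#' @param library a `template_library`
#' @param n_ref reference numerosity
#' @param n_var vector of variable numerosities
#' @param n_trials trials per variable level
#' @param seed seed for the whole block
#' @param probe_fun probe generator `function(N)`; default
#'   [quantum_probe_fun()] on the library's own network
#' @param spec network for the default probe generator (default
#'   `library$spec`)
#' @param protocol_fun protocol family for the default probe generator
#' @return `psychometric_data`: data.frame (n_var, n_trials, n_more)
#'   with the reference as attribute `n_ref`
#' @export
run_2afc <- function(library, n_ref, n_var, n_trials = 100, seed = 1,
                     probe_fun = NULL, spec = NULL,
                     protocol_fun = function(N) protocol_spec(N)) {
  stopifnot(inherits(library, "template_library"), n_trials >= 1,
            n_ref %in% library$numerosities,
            all(n_var %in% library$numerosities))
  if (is.null(probe_fun)) {
    if (is.null(spec)) spec <- library$spec
    probe_fun <- quantum_probe_fun(spec, protocol_fun, library$window,
                                   library$dt)
  }
  set.seed(seed)
  n_more <- integer(length(n_var))
  for (v in seq_along(n_var)) {
    for (t in seq_len(n_trials)) {
      d_ref <- decode_numerosity(probe_fun(n_ref), library)$decoded
      d_var <- decode_numerosity(probe_fun(n_var[v]), library)$decoded
      more <- if (d_var > d_ref) TRUE else if (d_var < d_ref) FALSE
              else runif(1) < 0.5
      n_more[v] <- n_more[v] + more
    }
  }
  structure(data.frame(n_var = n_var, n_trials = n_trials,
                       n_more = n_more),
            n_ref = n_ref, class = c("psychometric_data", "data.frame"))
}

#' Fit the Probit psychometric function
#'
#' Maximum-likelihood Bernoulli fit of
#' \eqn{F(N) = \Phi((N - \bar N)/\sigma)} to judged-more proportions
#' (probit regression); \eqn{\bar N} is the point of subjective equality
#' (PSE, where F = 0.5) and \eqn{\sigma} the psychometric width. No
#' lapse or guess-rate parameters. Degenerate data (all 0s/1s, or a
#' perfect step giving complete separation) are flagged non-convergent
#' with `sigma` pinned at `sigma_floor`.
#'
#' @param data a `psychometric_data` (or data.frame with n_var,
#'   n_trials, n_more)
#' @param sigma_floor lower bound flagging degenerate slopes
#' @return object of class `probit_fit`: `pse`, `sigma`, `loglik`,
#'   `converged`, `n_ref`
#' @export
fit_probit <- function(data, sigma_floor = 1e-3) {
  stopifnot(all(c("n_var", "n_trials", "n_more") %in% names(data)),
            all(data$n_more >= 0), all(data$n_more <= data$n_trials))
  if (length(unique(data$n_var)) < 3)
    stop("need at least 3 distinct variable levels")
  out <- list(pse = NA_real_, sigma = NA_real_, loglik = NA_real_,
              converged = FALSE, n_ref = attr(data, "n_ref"))
  class(out) <- "probit_fit"
  k <- data$n_more
  if (all(k == 0) || all(k == data$n_trials)) {
    out$sigma <- sigma_floor
    return(out)
  }
  fit <- suppressWarnings(
    glm(cbind(n_more, n_trials - n_more) ~ n_var,
        family = binomial(link = "probit"), data = data))
  b <- coef(fit)[["n_var"]]
  a <- coef(fit)[["(Intercept)"]]
  out$loglik <- as.numeric(logLik(fit))
  if (!fit$converged || !is.finite(b) || b <= 0) {
    out$sigma <- sigma_floor
    return(out)
  }
  sigma <- 1 / b
  out$pse <- -a / b
  if (sigma < sigma_floor) {            # separation: step-like data
    out$sigma <- sigma_floor
    return(out)
  }
  out$sigma <- sigma
  out$converged <- TRUE
  out
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("<probit_fit> PSE = %.3f, sigma = %.3f (%s)\n",
              x$pse, x$sigma,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Weber-fraction curve across reference numerosities
#'
#' Collects the fitted psychometric widths and the Weber fractions
#' `sigma / n_ref`; Weber's law predicts the fractions are flat in the
#' reference. Non-converged fits are excluded with a warning.
#'
#' @param fits list of [fit_probit()] results, each carrying `n_ref`
#'   (or supply `n_ref` explicitly)
#' @param n_ref optional vector of reference numerosities
#' @return `weber_result`: data.frame (n_ref, sigma, weber) with the
#'   flatness statistic (max/min Weber fraction) as attribute
#'   `flatness`
#' @export
weber_curve <- function(fits, n_ref = NULL) {
  if (inherits(fits, "probit_fit")) fits <- list(fits)
  if (is.null(n_ref))
    n_ref <- vapply(fits, function(f) as.numeric(f$n_ref), numeric(1))
  stopifnot(length(n_ref) == length(fits), !anyNA(n_ref))
  if (length(fits) < 2) stop("need at least 2 reference levels")
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    warning(sum(!conv), " non-converged fit(s) excluded")
  sigma <- vapply(fits, function(f) f$sigma, numeric(1))[conv]
  n_ref <- n_ref[conv]
  out <- data.frame(n_ref = n_ref, sigma = sigma,
                    weber = sigma / n_ref)
  attr(out, "flatness") <- if (nrow(out) >= 2)
    max(out$weber) / min(out$weber) else NA_real_
  class(out) <- c("weber_result", "data.frame")
  out
}

# ---- shared probe banks -------------------------------------------------
# Simulating probes dominates the cost of a psychophysics experiment,
# while decoding is nearly free. A bank draws the probe spectra once per
# (level, trial); the same bank can then be decoded under different
# template libraries (paired comparisons, e.g. template-count
# convergence) or reused across reference levels.

#' Draw a bank of probe spectra
#'
#' @param spec a [network_spec()]
#' @param levels numerosity levels to draw
#' @param n_draws probes per level
#' @param protocol_fun protocol family `function(N)`
#' @param window,dt recording window and step
#' @param seed master seed
#' @param config a [solver_config()]
#' @return `probe_bank`: list of per-level lists of spectra
#' @export
probe_bank <- function(spec, levels, n_draws,
                       protocol_fun = function(N) protocol_spec(N),
                       window = c(10, 20), dt = 0.02, seed = 1,
                       config = solver_config()) {
  pf <- quantum_probe_fun(spec, protocol_fun, window, dt, config)
  set.seed(seed)
  spectra <- lapply(levels, function(N)
    lapply(seq_len(n_draws), function(i) pf(N)))
  names(spectra) <- levels
  structure(list(levels = levels, n_draws = n_draws, spectra = spectra),
            class = "probe_bank")
}

#' Decode every probe in a bank
#'
#' @param bank a [probe_bank()]
#' @param library a `template_library`
#' @return numeric matrix (n_draws x levels) of decoded numerosities
#' @export
decode_bank <- function(bank, library) {
  stopifnot(inherits(bank, "probe_bank"))
  vapply(as.character(bank$levels), function(nm)
    vapply(bank$spectra[[nm]], function(s)
      as.numeric(decode_numerosity(s, library)$decoded),
      numeric(1)),
    numeric(bank$n_draws))
}

#' Psychometric counts from decoded bank columns
#'
#' Trial t compares draw t of the variable level against draw
#' n_trials + 1 - t of the reference level (fair coin on equal
#' decodes); the reversed reference indexing keeps the two probes of a
#' trial distinct even when the variable equals the reference.
#'
#' @param decoded matrix from [decode_bank()]
#' @param n_ref reference level (a column name of `decoded`)
#' @param n_var variable levels
#' @param n_trials trials per level (<= bank draws)
#' @param seed seed for the equal-decode coin flips
#' @return `psychometric_data`
#' @export
bank_psychometrics <- function(decoded, n_ref, n_var,
                               n_trials = nrow(decoded), seed = 1) {
  stopifnot(n_trials <= nrow(decoded),
            as.character(n_ref) %in% colnames(decoded),
            all(as.character(n_var) %in% colnames(decoded)))
  set.seed(seed)
  dref <- decoded[rev(seq_len(n_trials)), as.character(n_ref)]
  n_more <- vapply(as.character(n_var), function(nm) {
    dvar <- decoded[seq_len(n_trials), nm]
    eq <- dvar == dref
    sum(dvar > dref) + sum(runif(sum(eq)) < 0.5)
  }, numeric(1))
  structure(data.frame(n_var = n_var, n_trials = n_trials,
                       n_more = as.integer(n_more)),
            n_ref = n_ref, class = c("psychometric_data", "data.frame"))
}
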