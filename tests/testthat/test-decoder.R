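# toy library: three well-separated synthetic templates on one grid
toy_library <- function(n_bins = 40, levels = 1:3) {
  freq <- seq_len(n_bins)
  templates <- vapply(levels, function(N)
    exp(-(freq - 10 * N)^2 / 8), numeric(n_bins))
  colnames(templates) <- levels
  structure(list(freq = freq, templates = templates,
                 numerosities = as.integer(levels), n_traj = 1,
                 spec = NULL, window = c(0, 1), dt = 1, seed = NA),
            class = "template_library")
}

as_spec <- function(lib, amp) {
  structure(list(freq = lib$freq, amp = amp, dt = lib$dt, n = NA),
            class = "amplitude_spectrum")
}

test_that("spectrum correlation is Pearson with its invariances", {
  lib <- toy_library()
  t1 <- numspin:::template_spectrum(lib, 1)
  expect_equal(correlate_spectra(t1, t1), 1)
  shifted <- as_spec(lib, 3 * t1$amp + 0.7)       # positive affine
  expect_equal(correlate_spectra(shifted, t1), 1)
  flipped <- as_spec(lib, -t1$amp)
  expect_equal(correlate_spectra(flipped, t1), -1)
  expect_true(is.na(correlate_spectra(as_spec(lib, rep(1, 40)), t1)))
  other <- structure(list(freq = 1:39, amp = t1$amp[1:39], dt = 1, n = NA),
                     class = "amplitude_spectrum")
  expect_error(correlate_spectra(other, t1), "grids")
})

test_that("decoding picks the argmax and handles ties and degeneracy", {
  lib <- toy_library()
  for (N in 1:3) {
    d <- decode_numerosity(numspin:::template_spectrum(lib, N), lib)
    expect_equal(d$decoded, N)
    expect_false(d$tie)
    expect_equal(unname(d$correlations[as.character(N)]), 1)
  }
  # decoding is invariant under common positive affine transforms
  probe <- as_spec(lib, 5 * lib$templates[, 2] + 1)
  expect_equal(decode_numerosity(probe, lib)$decoded, 2)
  # duplicated templates tie and the tie-break is seeded
  dup <- lib
  dup$templates[, 3] <- dup$templates[, 1]
  dd <- decode_numerosity(numspin:::template_spectrum(dup, 1), dup,
                          tie_seed = 5)
  expect_true(dd$tie)
  expect_identical(dd$decoded,
                   decode_numerosity(numspin:::template_spectrum(dup, 1),
                                     dup, tie_seed = 5)$decoded)
  picks <- vapply(1:40, function(s)
    decode_numerosity(numspin:::template_spectrum(dup, 1), dup,
                      tie_seed = s)$decoded, integer(1))
  expect_setequal(unique(picks), c(1L, 3L))
  # zero-variance probe cannot be decoded
  expect_error(decode_numerosity(as_spec(lib, rep(0, 40)), lib),
               "zero variance")
  empty <- lib
  empty$numerosities <- integer(0)
  expect_error(decode_numerosity(probe, empty), "empty")
})

test_that("confusion matrix conserves probes and finds exact templates", {
  lib <- toy_library()
  # probes that are exact templates give the identity
  cm <- vapply(1:3, function(N) {
    d <- decode_numerosity(numspin:::template_spectrum(lib, N), lib)
    as.integer(1:3 == d$decoded)
  }, integer(3))
  expect_equal(cm, diag(3L)[, 1:3])
  # simulated confusion rows sum to n_probes
  sp <- network_spec(6, "all_to_all", delta0 = 0)
  qlib <- build_template_library(sp, 1:2, n_traj = 2, window = c(5, 10),
                                 dt = 0.1, seed = 11)
  conf <- decode_confusion(qlib, sp, n_probes = 3, seed = 12)
  expect_equal(unname(rowSums(conf)), c(3L, 3L))
})
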