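# Classical control experiments: the decoder must classify the frequency
# of plain sinusoidal activation maps (with optional 1/f noise) without
# adding noise structure of its own, and the numerosity decoding must be
# stable against the number of trajectories used to build the templates.

#' Synthesize 1/f ("pink") noise
#'
#' Frequency-domain recipe: spectral amplitude proportional to
#' `scale / k` at bin k with uniform random phases, inverse-transformed
#' to a real time series. In the conventions of
#' [amplitude_spectrum()] (amplitude = `Mod(fft)/n`), bin k of the
#' output has amplitude `scale / k`, so noise power falls off as
#' `1/k^2`.
#'
#' @param n number of samples
#' @param scale amplitude of the k = 1 bin
#' @return numeric vector of length n (zero mean)
#' @export
one_over_f_noise <- function(n, scale = 1) {
  stopifnot(n >= 8)
  X <- complex(n)
  K <- floor((n - 1) / 2)
  ph <- runif(K, 0, 2 * pi)
  X[2:(K + 1)] <- (scale * n / (1:K)) * exp(1i * ph)
  X[n + 1 - (1:K)] <- Conj(X[2:(K + 1)])
  if (n %% 2 == 0)
    X[n / 2 + 1] <- (scale * n / (n / 2)) * sign(runif(1) - 0.5)
  Re(fft(X, inverse = TRUE)) / n
}

#' Sinusoidal activation-map record ("grating")
#'
#' All M sites carry the same sinusoid at integer frequency index f
#' (f cycles across `duration`, i.e. exactly FFT bin f of the analysis
#' window), optionally corrupted by independent per-site 1/f noise.
#' Amplitude 1; site values are classical activities, not constrained to
#' [-1, 1].
#'
#' @param f frequency index (1 .. below Nyquist)
#' @param n_sites number of sites M
#' @param duration window length (units 1/J); matched to the quantum
#'   recording window so grids coincide
#' @param dt sampling step
#' @param noise `"none"` or `"one_over_f"`
#' @param noise_scale k = 1 noise amplitude relative to the tone's
#'   spectral amplitude 0.5 (default 1: noise dominates the lowest bins,
#'   is negligible at high f)
#' @param t0 start time of the grid
#' @return a `trajectory_record`
#' @export
grating_record <- function(f, n_sites = 18, duration = 10, dt = 0.05,
                           noise = c("none", "one_over_f"),
                           noise_scale = 1, t0 = 0) {
  noise <- match.arg(noise)
  n <- round(duration / dt)
  stopifnot(f >= 1, f == round(f))
  if (f >= n / 2) stop("frequency index ", f, " at or beyond Nyquist")
  times <- t0 + dt * (0:(n - 1))
  base <- sin(2 * pi * f * (times - t0) / duration)
  mag <- matrix(rep(base, each = n_sites), n_sites, n, byrow = FALSE)
  if (noise == "one_over_f")
    for (i in seq_len(n_sites))
      mag[i, ] <- mag[i, ] + one_over_f_noise(n, noise_scale)
  new_trajectory_record(times, mag)
}

# template_library over frequency indices built from grating records
grating_library <- function(freqs, n_sites, duration, dt, noise,
                            noise_scale, n_traj) {
  templates <- NULL
  freq_grid <- NULL
  for (k in seq_along(freqs)) {
    amps <- NULL
    for (tr in seq_len(n_traj)) {
      rec <- grating_record(freqs[k], n_sites, duration, dt, noise,
                            noise_scale)
      s <- space_average_spectrum(rec)
      if (is.null(freq_grid)) freq_grid <- s$freq
      if (is.null(amps)) amps <- matrix(0, length(freq_grid), n_traj)
      amps[, tr] <- s$amp
    }
    if (is.null(templates))
      templates <- matrix(NA_real_, length(freq_grid), length(freqs),
                          dimnames = list(NULL, freqs))
    templates[, k] <- rowMeans(amps)
  }
  structure(list(freq = freq_grid, templates = templates,
                 numerosities = as.integer(freqs), n_traj = n_traj,
                 spec = NULL, window = c(0, duration), dt = dt,
                 seed = NA), class = "template_library")
}

#' Frequency-decoding control experiment
#'
#' Builds one template per sinusoid frequency, decodes fresh probes, and
#' reports the decoding error per true frequency. Noise-free gratings
#' must decode (near-)perfectly; 1/f noise hurts mostly the low
#' frequencies, where its spectral amplitude rivals the tone's.
#'
#' @param freqs frequency indices (default 1:18)
#' @param n_sites sites per grating (default 18)
#' @param Nt grating realizations averaged per template
#' @param n_probes probes per frequency
#' @param noise `"none"` or `"one_over_f"` (applies to templates and
#'   probes alike)
#' @param noise_scale see [grating_record()]
#' @param duration,dt analysis window and step
#' @param seed master seed
#' @return data.frame (f, mean_abs_error, error_rate), class
#'   `freq_decode_result`
#' @export
frequency_decoding_experiment <- function(freqs = 1:18, n_sites = 18,
                                          Nt = 10, n_probes = 20,
                                          noise = c("none", "one_over_f"),
                                          noise_scale = 1, duration = 10,
                                          dt = 0.05, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_probes >= 1, Nt >= 1)
  set.seed(seed)
  lib <- grating_library(freqs, n_sites, duration, dt, noise, noise_scale,
                         n_traj = Nt)
  abs_err <- err <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    dec <- vapply(seq_len(n_probes), function(p) {
      rec <- grating_record(freqs[k], n_sites, duration, dt, noise,
                            noise_scale)
      as.numeric(decode_numerosity(space_average_spectrum(rec),
                                   lib)$decoded)
    }, numeric(1))
    abs_err[k] <- mean(abs(dec - freqs[k]))
    err[k] <- mean(dec != freqs[k])
  }
  structure(data.frame(f = freqs, mean_abs_error = abs_err,
                       error_rate = err),
            noise = noise, class = c("freq_decode_result", "data.frame"))
}

#' Template-count convergence of the numerosity decoding
#'
#' Rebuilds the template library from nested subsets of `nt_values`
#' trajectories (the largest serving as reference), decodes one shared
#' probe bank under each, and compares the resulting Weber-fraction
#' curves. Convergence with a handful of trajectories shows the decoder
#' needs very few samples.
#'
#' @param spec a [network_spec()]
#' @param nt_values trajectory counts (default `c(3, 5, 10, 40)`); the
#'   maximum is the reference
#' @param numerosities template levels (default 1..floor(M/2))
#' @param refs reference numerosities for the psychometric fits
#' @param n_trials 2AFC trials per (reference, variable) level
#' @param protocol_fun stimulus protocol family
#' @param window,dt recording window and step
#' @param seed master seed
#' @return list with `table` (nt, n_ref, sigma, weber) and `deviation`
#'   (nt, mean absolute Weber-fraction deviation from the reference)
#' @export
template_count_convergence <- function(spec, nt_values = c(3, 5, 10, 40),
                                       numerosities = NULL, refs = 2:4,
                                       n_trials = 40,
                                       protocol_fun = function(N)
                                         protocol_spec(N),
                                       window = c(10, 20), dt = 0.05,
                                       seed = 1) {
  stopifnot(all(nt_values >= 1))
  nt_values <- sort(unique(nt_values))
  nt_ref <- max(nt_values)
  if (is.null(numerosities)) numerosities <- seq_len(spec$n_sites %/% 2)
  stopifnot(all(refs %in% numerosities))
  lib_full <- build_template_library(spec, numerosities, n_traj = nt_ref,
                                     protocol_fun = protocol_fun,
                                     window = window, dt = dt,
                                     seed = seed,
                                     keep_trajectories = TRUE)
  bank <- probe_bank(spec, numerosities, n_draws = n_trials,
                     protocol_fun = protocol_fun, window = window,
                     dt = dt, seed = seed + 1)
  rows <- list()
  webers <- list()
  accuracy <- NA_real_
  for (nt in nt_values) {
    lib <- if (nt == nt_ref) lib_full else sub_library(lib_full, nt)
    lib$traj_amps <- NULL
    decoded <- decode_bank(bank, lib)
    if (nt == nt_ref)
      accuracy <- mean(t(decoded) == numerosities)
    fits <- lapply(refs, function(r)
      fit_probit(bank_psychometrics(decoded, r, numerosities, n_trials,
                                    seed = seed + 2 + r)))
    wb <- suppressWarnings(weber_curve(fits, n_ref = refs))
    webers[[as.character(nt)]] <- wb
    rows[[as.character(nt)]] <-
      data.frame(nt = rep(nt, nrow(wb)), n_ref = wb$n_ref,
                 sigma = wb$sigma, weber = wb$weber)
  }
  ref_wb <- webers[[as.character(nt_ref)]]
  dev <- vapply(nt_values, function(nt) {
    wb <- webers[[as.character(nt)]]
    shared <- intersect(wb$n_ref, ref_wb$n_ref)
    if (length(shared) == 0) return(NA_real_)
    mean(abs(wb$weber[match(shared, wb$n_ref)] -
               ref_wb$weber[match(shared, ref_wb$n_ref)]))
  }, numeric(1))
  list(table = do.call(rbind, rows),
       deviation = data.frame(nt = nt_values, deviation = dev),
       decode_accuracy = accuracy)
}
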