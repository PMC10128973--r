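# Headline reproduction experiments, each a self-contained function so
# the same code backs the test suite and the acceptance script.

#' Decodability-bound check via sector-restricted evolution
#'
#' With all-to-all coupling, no interaction offset and deterministic pi
#' flips (applied at t = 0 on distinct sites, so the state stays in one
#' magnetization sector), the spin-flip (up-down) symmetry makes the
#' space-averaged amplitude spectra of N and M - N excitations
#' coincide: numerosities above M/2 are indistinguishable from their
#' complements, so the largest decodable numerosity is floor(M/2).
#' This function measures both halves of that statement on complement
#' pairs: spectra of N and M - N must match (correlation ~ 1), while
#' spectra of different N <= M/2 must differ.
#'
#' @param n_sites network size (default 18)
#' @param pairs_n numerosities whose complement pairs are checked
#'   (default `c(2, 4, 9)`; 9 is self-complementary at M = 18 and is
#'   checked across two disjoint site sets)
#' @param window,dt recording window and step
#' @param config a [solver_config()]
#' @return list: `bound` (floor(M/2) if all complement pairs coincide),
#'   `pair_cor` (minimum complement-pair correlation),
#'   `pair_maxdiff` (max absolute spectral difference across pairs,
#'   after peak normalization), `cross_cor` (maximum correlation
#'   between distinct numerosities)
#' @export
decodability_bound_experiment <- function(n_sites = 18,
                                          pairs_n = c(2, 4, 9),
                                          window = c(10, 20), dt = 0.1,
                                          config = solver_config()) {
  spec <- network_spec(n_sites, "all_to_all", delta0 = 0)
  times <- record_grid(window, dt)
  spread_sites <- function(N, avoid = integer(0)) {
    pool <- setdiff(seq_len(n_sites), avoid)
    pool[round(seq(1, length(pool), length.out = N))]
  }
  specs_lo <- list()
  pair_cor <- c()
  pair_maxdiff <- c()
  for (N in pairs_n) {
    lo_sites <- spread_sites(N)
    hi_sites <- if (2 * N == n_sites) setdiff(seq_len(n_sites), lo_sites)
                else spread_sites(n_sites - N)
    s_lo <- space_average_spectrum(sector_record(spec, lo_sites, times,
                                                 config = config))
    s_hi <- space_average_spectrum(sector_record(spec, hi_sites, times,
                                                 config = config))
    specs_lo[[as.character(N)]] <- s_lo
    pair_cor <- c(pair_cor, correlate_spectra(s_lo, s_hi))
    pair_maxdiff <- c(pair_maxdiff,
                      max(abs(s_lo$amp - s_hi$amp)) / max(s_lo$amp))
  }
  cross <- utils::combn(seq_along(pairs_n), 2)
  cross_cor <- max(apply(cross, 2, function(ix)
    correlate_spectra(specs_lo[[ix[1]]], specs_lo[[ix[2]]])))
  coincide <- min(pair_cor) > 0.999
  list(bound = if (coincide) floor(n_sites / 2) else NA_integer_,
       pair_cor = min(pair_cor), pair_maxdiff = max(pair_maxdiff),
       cross_cor = cross_cor)
}

#' Collective oscillation frequency of the all-to-all network
#'
#' One pi flip in an all-to-all network with no interaction offset
#' leaves the one-excitation sector, whose spectrum is J(M-1) (the
#' symmetric mode) and -J ((M-1)-fold): the magnetization oscillates at
#' the gap J*M. The FFT peak must land within one bin of it.
#'
#' @param sizes network sizes to check
#' @param window,dt recording window and step
#' @return data.frame (n_sites, peak_freq, expected, bin_width)
#' @export
oscillation_frequency_check <- function(sizes = c(5, 7, 9),
                                        window = c(10, 20), dt = 0.02) {
  times <- record_grid(c(0, window[2]), dt)
  out <- lapply(sizes, function(M) {
    spec <- network_spec(M, "all_to_all", delta0 = 0)
    mid <- (M + 1) %/% 2
    rec <- evolve_trajectory(spec, stimulus_event(0, mid, pi), times)
    s <- site_spectrum(rec, mid, window = window)
    data.frame(n_sites = M, peak_freq = s$freq[which.max(s$amp)],
               expected = spec$J * M, bin_width = s$freq[1])
  })
  do.call(rbind, out)
}

#' Trajectory-average versus master-equation check
#'
#' Averages `n_traj` quantum trajectories of a lossy chain and compares
#' every site/time magnetization with the exact GKSL solution, in units
#' of the Monte-Carlo standard error.
#'
#' @param n_sites chain length (default 4, within the oracle cap)
#' @param gamma_loss loss rate (default 0.3)
#' @param n_traj number of trajectories (default 2000)
#' @param times recording grid (default 0..10 step 1)
#' @param seed RNG seed
#' @return list: `max_z` (max |mean - exact| / SE), `mean_abs_diff`,
#'   `n_traj`
#' @export
unraveling_check <- function(n_sites = 4, gamma_loss = 0.3,
                             n_traj = 2000, times = seq(0, 10, by = 1),
                             seed = 1) {
  spec <- network_spec(n_sites, "nearest_neighbour",
                       gamma_loss = gamma_loss)
  ev <- stimulus_event(0, 1, pi)
  exact <- evolve_master(spec, ev, times)$mag
  set.seed(seed)
  acc <- 0
  acc2 <- 0
  for (k in seq_len(n_traj)) {
    m <- evolve_trajectory(spec, ev, times)$mag
    acc <- acc + m
    acc2 <- acc2 + m^2
  }
  mbar <- acc / n_traj
  se <- sqrt(pmax(acc2 / n_traj - mbar^2, 0) / n_traj)
  z <- abs(mbar - exact) / pmax(se, 1e-9)
  z[se < 1e-8] <- 0   # deterministic entries (e.g. t = 0)
  list(max_z = max(z), mean_abs_diff = mean(abs(mbar - exact)),
       n_traj = n_traj)
}

#' Staggered-flip peak counting
#'
#' The deterministic demonstration protocol: N = 1, 2, 3 pi flips at
#' sites 1, 3, 5 at fixed times in the stimulus window, all-to-all
#' coupling with a narrow Gaussian interaction. Each additional flip
#' must add one dominant peak at a constant frequency spacing in the
#' recording-window spectrum.
#'
#' @param n_sites network size (default 7)
#' @param delta0,sigma_int interaction profile (defaults 0.1, 1/sqrt(2))
#' @param window,dt recording window and step
#' @param rel_threshold relative peak threshold (default 0.2)
#' @return data.frame (n_flips, n_peaks, spacing_range) where
#'   `spacing_range` is the max - min gap between adjacent dominant
#'   peaks (NA below 3 peaks); attribute `bin_width`
#' @export
staggered_peak_experiment <- function(n_sites = 7, delta0 = 0.1,
                                      sigma_int = 1 / sqrt(2),
                                      window = c(10, 20), dt = 0.02,
                                      rel_threshold = 0.2) {
  spec <- network_spec(n_sites, "all_to_all", delta0 = delta0,
                       sigma_int = sigma_int)
  times <- record_grid(c(0, window[2]), dt)
  out <- lapply(1:3, function(N) {
    rec <- evolve_trajectory(spec, demo_event_sequence(N), times)
    s <- space_average_spectrum(rec, window = window)
    pk <- dominant_peak_frequencies(s, rel_threshold)
    spacing <- if (length(pk) >= 3) diff(range(diff(sort(pk))))
               else NA_real_
    data.frame(n_flips = N, n_peaks = length(pk),
               spacing_range = spacing)
  })
  res <- do.call(rbind, out)
  attr(res, "bin_width") <- 2 * pi / diff(window)
  res
}

#' No-information-in-the-mean check
#'
#' Averaging magnetization over random-rotation trajectories washes out
#' all spatial structure (the stimuli are uniform on sites), so the
#' site-to-site variance of the trajectory-averaged signal must be a
#' small fraction of the single-trajectory site variance — decoding
#' must happen per trajectory, which is why the pipeline computes
#' spectra before averaging.
#'
#' @param n_sites network size (default 10)
#' @param numerosity stimulus count per trajectory (default 3)
#' @param n_traj trajectories averaged (default 100)
#' @param window,dt recording window and step
#' @param seed RNG seed
#' @return list: `var_ratio` (spatial variance of the mean signal over
#'   mean spatial variance of single trajectories), `n_traj`
#' @export
mean_signal_check <- function(n_sites = 10, numerosity = 3, n_traj = 100,
                              window = c(10, 20), dt = 0.05, seed = 1) {
  spec <- network_spec(n_sites, "all_to_all", delta0 = 0)
  times <- record_grid(window, dt)
  proto <- protocol_spec(numerosity)
  set.seed(seed)
  acc <- 0
  v_single <- numeric(n_traj)
  for (k in seq_len(n_traj)) {
    ev <- sample_events(proto, spec)
    m <- evolve_trajectory(spec, ev, times)$mag
    acc <- acc + m
    v_single[k] <- mean(apply(m, 2, var))
  }
  mbar <- acc / n_traj
  list(var_ratio = mean(apply(mbar, 2, var)) / mean(v_single),
       n_traj = n_traj)
}

#' Weber-law experiment (random-rotation and constant-energy protocols)
#'
#' Runs the full pipeline at desk scale: template libraries, probe
#' banks, 2AFC comparisons, Probit fits, Weber fractions — for the
#' random-rotation (RR) protocol across several template counts
#' (convergence check included) and the constant-energy (CE) protocol
#' at the reference template count.
#'
#' @param n_sites network size (default 10)
#' @param numerosities template/probe levels (default 1..5)
#' @param refs reference numerosities (default 2:4)
#' @param nt_values RR template counts (default `c(3, 5, 10, 40, 200)`,
#'   largest = reference)
#' @param n_trials 2AFC trials per (reference, variable) level
#' @param ce_total total rotation of the constant-energy protocol. The
#'   default pi keeps the constraint feasible for every numerosity down
#'   to N = 1 under the (0, pi] per-event angle cap (a total of 3 pi
#'   requires N >= 3) while still removing total input energy as a cue.
#' @param window,dt recording window and step
#' @param seed master seed
#' @return list with `rr` (template-count convergence object; its
#'   largest-nt rows are the RR Weber curve), `ce` (CE Weber table),
#'   `decode_accuracy` (RR probe bank decoded with the reference
#'   library), `chance` (1 / number of levels)
#' @export
weber_experiment <- function(n_sites = 10, numerosities = 1:5,
                             refs = 2:4,
                             nt_values = c(3, 5, 10, 40, 200),
                             n_trials = 300, ce_total = pi,
                             window = c(10, 20), dt = 0.05, seed = 1) {
  spec <- network_spec(n_sites, "all_to_all", delta0 = 0)
  rr_proto <- function(N) protocol_spec(N, angle_mode = "random_rotation")
  ce_proto <- function(N) protocol_spec(N, angle_mode = "constant_energy",
                                        total_angle = ce_total)
  rr <- template_count_convergence(spec, nt_values = nt_values,
                                   numerosities = numerosities,
                                   refs = refs, n_trials = n_trials,
                                   protocol_fun = rr_proto,
                                   window = window, dt = dt, seed = seed)
  ce <- template_count_convergence(spec, nt_values = max(nt_values),
                                   numerosities = numerosities,
                                   refs = refs, n_trials = n_trials,
                                   protocol_fun = ce_proto,
                                   window = window, dt = dt,
                                   seed = seed + 1000)
  list(rr = rr, ce = ce$table,
       decode_accuracy = rr$decode_accuracy,
       chance = 1 / length(numerosities))
}

#' Probit parameter recovery on synthetic data
#'
#' Simulates binomial psychometric data from a known cumulative
#' Gaussian and refits, over many replicates.
#'
#' @param pse,sigma true parameters (defaults 5, 1)
#' @param levels variable levels (default 1..9)
#' @param n_per_level trials per level (default 500)
#' @param n_rep replicates (default 100)
#' @param seed RNG seed
#' @return list: `pse_err` and `sigma_err` (95th percentile of absolute
#'   recovery errors), `pse_bias`, `sigma_bias`
#' @export
probit_recovery_experiment <- function(pse = 5, sigma = 1, levels = 1:9,
                                       n_per_level = 500, n_rep = 100,
                                       seed = 1) {
  set.seed(seed)
  est <- t(vapply(seq_len(n_rep), function(r) {
    k <- rbinom(length(levels), n_per_level,
                pnorm((levels - pse) / sigma))
    f <- fit_probit(data.frame(n_var = levels, n_trials = n_per_level,
                               n_more = k))
    c(f$pse, f$sigma)
  }, numeric(2)))
  list(pse_err = unname(quantile(abs(est[, 1] - pse), 0.95)),
       sigma_err = unname(quantile(abs(est[, 2] - sigma), 0.95)),
       pse_bias = mean(est[, 1]) - pse,
       sigma_bias = mean(est[, 2]) - sigma)
}

#' Grating-decoder noise control
#'
#' Decodes noiseless and 1/f-corrupted sinusoidal activation maps; the
#' noiseless error floor must be (near) zero and the 1/f errors must
#' concentrate at low frequencies.
#'
#' @param freqs frequency indices (default 1:18)
#' @param Nt template realizations (default 10)
#' @param n_probes probes per frequency (default 20)
#' @param noise_scale 1/f noise scale (default 1)
#' @param seed RNG seed
#' @return list: `clean_error` (mean abs decode error, noiseless),
#'   `noisy_low`, `noisy_high` (mean abs error over the lower/upper
#'   half of the frequency range under 1/f noise)
#' @export
grating_noise_experiment <- function(freqs = 1:18, Nt = 10,
                                     n_probes = 20, noise_scale = 1,
                                     seed = 1) {
  clean <- frequency_decoding_experiment(freqs, Nt = Nt,
                                         n_probes = n_probes,
                                         noise = "none", seed = seed)
  noisy <- frequency_decoding_experiment(freqs, Nt = Nt,
                                         n_probes = n_probes,
                                         noise = "one_over_f",
                                         noise_scale = noise_scale,
                                         seed = seed + 1)
  half <- freqs <= stats::median(freqs)
  list(clean_error = mean(clean$mean_abs_error),
       noisy_low = mean(noisy$mean_abs_error[half]),
       noisy_high = mean(noisy$mean_abs_error[!half]))
}
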