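test_that("amplitude spectrum resolves pure tones and kills DC", {
  dt <- 0.05
  t <- dt * (0:199)
  w0 <- 2 * pi * 7 / (200 * dt)       # bin 7 exactly
  s <- amplitude_spectrum(3 + sin(w0 * t), dt)
  expect_equal(s$freq[which.max(s$amp)], w0)
  expect_lt(sum(s$amp > 1e-10), 2)    # a single nonzero bin
  expect_equal(max(s$amp), 0.5, tolerance = 1e-10)
  flat <- amplitude_spectrum(rep(2.5, 64), dt)
  expect_equal(max(flat$amp), 0)      # constant signal: all zero
  expect_error(amplitude_spectrum(1:5, dt), "8 samples")
  expect_true(all(diff(s$freq) > 0))
})

test_that("Parseval consistency fixes the FFT normalization", {
  set.seed(21)
  x <- rnorm(257)                      # odd length: no Nyquist bin
  s <- amplitude_spectrum(x, 0.1)
  expect_equal(2 * sum(s$amp^2), mean((x - mean(x))^2),
               tolerance = 1e-10)
})

test_that("windowing selects [ta, tb) and validates bounds", {
  times <- 0.1 * (0:299)
  x <- sin(2 * pi * times / 10)
  s <- amplitude_spectrum(x, times = times, window = c(10, 20))
  expect_length(s$amp, 50)             # 100 samples -> 50 positive bins
  expect_error(amplitude_spectrum(x, times = times, window = c(25, 35)),
               "outside")
})

test_that("space averaging averages magnitudes across sites", {
  sp <- aa7(delta0 = 0)
  times <- record_grid(c(0, 12), 0.05)
  rec <- evolve_trajectory(sp, stimulus_event(0, 1, pi), times)
  persite <- lapply(1:7, function(i)
    site_spectrum(rec, i, window = c(2, 12)))
  # non-stimulated sites are interchangeable
  for (i in 3:7)
    expect_spectra_equal(persite[[i]], persite[[2]], tol = 1e-9)
  sa <- space_average_spectrum(rec, window = c(2, 12))
  manual <- (persite[[1]]$amp + 6 * persite[[2]]$amp) / 7
  expect_equal(sa$amp, manual, tolerance = 1e-10)
})

test_that("peak positions are robust to window, angle and length", {
  sp <- aa7(delta0 = 0)
  times <- record_grid(c(0, 20), 0.02)
  base <- evolve_trajectory(sp, stimulus_event(0, 4, pi), times)
  ref_pk <- dominant_peak_frequencies(
    site_spectrum(base, 4, window = c(10, 20)))
  variants <- list(
    site_spectrum(base, 4, window = c(12, 20)),          # start shift
    site_spectrum(base, 4, window = c(10, 16)),          # length change
    site_spectrum(evolve_trajectory(sp, stimulus_event(0, 4, 2.0), times),
                  4, window = c(10, 20)))                # rotation angle
  for (s in variants) {
    pk <- dominant_peak_frequencies(s)
    expect_length(pk, length(ref_pk))
    bin <- max(s$freq[1], 2 * pi / 10)
    expect_true(all(abs(pk - ref_pk) <= bin + 1e-9))
  }
})

test_that("per-trajectory spectra average differs from the spectrum of the mean signal", {
  sp <- network_spec(8, "all_to_all", delta0 = 0)
  times <- record_grid(c(10, 20), 0.05)
  proto <- protocol_spec(3)
  set.seed(31)
  n <- 20
  acc_sig <- 0
  acc_amp <- 0
  for (k in 1:n) {
    rec <- evolve_trajectory(sp, sample_events(proto, sp), times)
    acc_sig <- acc_sig + rec$mag
    acc_amp <- acc_amp + space_average_spectrum(rec)$amp
  }
  mean_amp <- acc_amp / n
  mean_rec <- numspin:::new_trajectory_record(times, acc_sig / n)
  amp_of_mean <- space_average_spectrum(mean_rec)$amp
  # random phases cancel in the averaged time signal: its spectrum is
  # much weaker than the average of the per-trajectory spectra
  expect_lt(sum(amp_of_mean), 0.5 * sum(mean_amp))
})

test_that("dominant-peak counting thresholds and merges correctly", {
  dt <- 0.1
  t <- dt * (0:199)
  tone <- function(k, a = 1) a * sin(2 * pi * k * t / (200 * dt))
  expect_equal(count_dominant_peaks(amplitude_spectrum(tone(9), dt)), 1)
  two <- amplitude_spectrum(tone(5) + 0.5 * tone(30), dt)
  expect_equal(count_dominant_peaks(two, 0.2), 2)
  weak <- amplitude_spectrum(tone(5) + 0.1 * tone(30), dt)
  expect_equal(count_dominant_peaks(weak, 0.2), 1)
  zero <- amplitude_spectrum(rep(0, 64), dt)
  expect_equal(count_dominant_peaks(zero), 0)
  expect_error(count_dominant_peaks(two, 0))
  # leaked spectral mass in adjacent bins merges into one peak
  off <- amplitude_spectrum(sin(2 * pi * 5.5 * t / (200 * dt)), dt)
  expect_equal(count_dominant_peaks(off, 0.5), 1)
})

test_that("template libraries are deterministic and nested", {
  sp <- network_spec(6, "all_to_all", delta0 = 0)
  lib1 <- build_template_library(sp, 1:3, n_traj = 3, window = c(5, 10),
                                 dt = 0.1, seed = 4,
                                 keep_trajectories = TRUE)
  lib2 <- build_template_library(sp, 1:3, n_traj = 3, window = c(5, 10),
                                 dt = 0.1, seed = 4)
  expect_equal(lib1$templates, lib2$templates)
  expect_equal(colnames(lib1$templates), c("1", "2", "3"))
  # n_traj = 1 template equals that single run's space-averaged spectrum
  s1 <- numspin:::sub_library(lib1, 1)
  expect_equal(s1$templates[, "2"], lib1$traj_amps[["2"]][, 1])
  # full nested average
  expect_equal(lib1$templates[, "1"], rowMeans(lib1$traj_amps[["1"]]))
})

test_that("complementary pi-flip patterns give identical spectra (up-down symmetry)", {
  sp <- network_spec(8, "all_to_all", delta0 = 0)
  times <- record_grid(c(5, 15), 0.05)
  s3 <- space_average_spectrum(sector_record(sp, c(1, 4, 7), times))
  s5 <- space_average_spectrum(sector_record(sp, setdiff(1:8, c(1, 4, 7)),
                                             times))
  expect_spectra_equal(s3, s5, tol = 1e-9)
})
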