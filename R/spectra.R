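# Amplitude spectra of magnetization signals and per-numerosity template
# libraries (space average per trajectory, then trajectory average).

#' Uniform recording grid for a time window
#'
#' Samples `[window[1], window[2])` at spacing `dt` (the right endpoint is
#' excluded so the window length times the bin spacing recover the FFT
#' grid exactly).
#'
#' @param window `c(ta, tb)` in units 1/J
#' @param dt sampling step (units 1/J)
#' @return numeric time grid
#' @export
record_grid <- function(window = c(10, 20), dt = 0.02) {
  stopifnot(length(window) == 2, window[2] > window[1], dt > 0)
  n <- round(diff(window) / dt)
  stopifnot(n >= 8)
  window[1] + dt * (0:(n - 1))
}

#' Amplitude spectrum of a uniformly sampled signal
#'
#' Magnitude of the discrete Fourier transform of the mean-subtracted
#' signal, positive frequencies only (rectangular window, no padding or
#' taper; the DC bin is zero by construction and dropped). Frequencies
#' are angular, in units of J: bin k sits at `2*pi*k / (n*dt)`.
#' Amplitudes are `Mod(fft(x))/n`.
#'
#' @param signal numeric time series
#' @param dt sampling step; required unless `times` is given
#' @param times optional time stamps of `signal` (uniform); used with
#'   `window` to select a sub-window `[ta, tb)`
#' @param window optional `c(ta, tb)` selection on `times`
#' @return object of class `amplitude_spectrum` with fields `freq`
#'   (angular) and `amp`
#' @export
amplitude_spectrum <- function(signal, dt = NULL, times = NULL,
                               window = NULL) {
  x <- as.numeric(signal)
  if (!is.null(times)) {
    stopifnot(length(times) == length(x))
    if (!is.null(window)) {
      if (window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9 +
            (times[2] - times[1]))
        stop("window outside the recorded time range")
      sel <- times >= window[1] - 1e-9 & times < window[2] - 1e-9
      x <- x[sel]
      times <- times[sel]
    }
    dts <- diff(times)
    if (diff(range(dts)) > 1e-8 * mean(dts))
      stop("signal must be uniformly sampled")
    dt <- mean(dts)
  }
  if (is.null(dt)) stop("supply dt or times")
  n <- length(x)
  if (n < 8) stop("need at least 8 samples")
  x <- x - mean(x)
  X <- fft(x)
  K <- floor(n / 2)
  structure(list(freq = 2 * pi * (1:K) / (n * dt),
                 amp = Mod(X[2:(K + 1)]) / n,
                 dt = dt, n = n),
            class = "amplitude_spectrum")
}

same_grid <- function(a, b) {
  length(a$freq) == length(b$freq) &&
    max(abs(a$freq - b$freq)) <= 1e-9 * max(a$freq)
}

#' Spectrum of one site's magnetization trace
#'
#' @param record a `trajectory_record`
#' @param site site index
#' @param window analysis window `c(ta, tb)` (default the full record)
#' @return an `amplitude_spectrum`
#' @export
site_spectrum <- function(record, site, window = NULL) {
  stopifnot(inherits(record, "trajectory_record"),
            site >= 1, site <= nrow(record$mag))
  amplitude_spectrum(record$mag[site, ], times = record$times,
                     window = window)
}

#' Space-averaged amplitude spectrum of a record
#'
#' Per-site amplitude spectra averaged across the M sites — magnitudes
#' are averaged, not complex transforms, because phases are random
#' across trajectories and carry no numerosity information.
#'
#' @param record a `trajectory_record`
#' @param window analysis window `c(ta, tb)` (default the full record)
#' @return an `amplitude_spectrum`
#' @export
space_average_spectrum <- function(record, window = NULL) {
  stopifnot(inherits(record, "trajectory_record"))
  specs <- lapply(seq_len(nrow(record$mag)), function(i)
    site_spectrum(record, i, window))
  out <- specs[[1]]
  out$amp <- rowMeans(vapply(specs, function(s) s$amp,
                             numeric(length(out$amp))))
  out
}

#' Build a numerosity template library
#'
#' For each numerosity N, runs `n_traj` seeded stimulus realizations,
#' space-averages each trajectory's spectrum, and averages the
#' magnitudes over trajectories into the template the ideal observer
#' will correlate against. All templates share one frequency grid.
#' Per-trajectory seeds are derived deterministically from `seed`.
#'
#' @param spec a [network_spec()]
#' @param numerosities integer vector of N values (a warning is issued
#'   above floor(M/2), the decodability limit)
#' @param n_traj trajectories per numerosity (order 10^2 for production
#'   templates; a handful already converges)
#' @param protocol_fun function(N) returning the [protocol_spec()] to
#'   sample events from (its own seed field is ignored)
#' @param window recording window `c(ta, tb)` (default `c(10, 20)`)
#' @param dt recording step (default 0.02)
#' @param seed master seed for the library
#' @param config a [solver_config()]
#' @param keep_trajectories keep per-trajectory spectra (needed for
#'   nested sub-libraries, e.g. template-count convergence)
#' @return object of class `template_library`
#' @export
build_template_library <- function(spec, numerosities, n_traj,
                                   protocol_fun = function(N)
                                     protocol_spec(N),
                                   window = c(10, 20), dt = 0.02,
                                   seed = 1,
                                   config = solver_config(),
                                   keep_trajectories = FALSE) {
  stopifnot(inherits(spec, "network_spec"), n_traj >= 1,
            all(numerosities >= 1))
  times <- record_grid(window, dt)
  seed_tab <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1, length(numerosities) * n_traj),
    nrow = n_traj))
  templates <- NULL
  freq <- NULL
  traj_amps <- list()
  for (k in seq_along(numerosities)) {
    N <- numerosities[k]
    proto <- protocol_fun(N)
    proto$seed <- NULL
    amps <- NULL
    for (tr in seq_len(n_traj)) {
      s <- seed_tab[tr, k]
      set.seed(s)
      ev <- sample_events(proto, spec)
      rec <- evolve_trajectory(spec, ev, times,
                               config = solver_config(tol = config$tol,
                                 krylov_dim = config$krylov_dim))
      sas <- space_average_spectrum(rec)
      if (is.null(freq)) freq <- sas$freq
      if (is.null(amps)) amps <- matrix(NA_real_, length(freq), n_traj)
      amps[, tr] <- sas$amp
    }
    if (is.null(templates))
      templates <- matrix(NA_real_, length(freq), length(numerosities),
                          dimnames = list(NULL, numerosities))
    templates[, k] <- rowMeans(amps)
    if (keep_trajectories) traj_amps[[as.character(N)]] <- amps
  }
  structure(list(freq = freq, templates = templates,
                 numerosities = as.integer(numerosities),
                 n_traj = n_traj, spec = spec, window = window, dt = dt,
                 seed = seed, seed_table = seed_tab,
                 traj_amps = if (keep_trajectories) traj_amps),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf(
    "<template_library> N in {%s}, %d trajectories each, %d bins\n",
    paste(x$numerosities, collapse = ", "), x$n_traj, length(x$freq)))
  invisible(x)
}

# sub-library from the first n_traj trajectories (requires
# keep_trajectories = TRUE in the parent build)
sub_library <- function(library, n_traj) {
  stopifnot(inherits(library, "template_library"),
            !is.null(library$traj_amps), n_traj <= library$n_traj)
  out <- library
  out$templates <- vapply(as.character(library$numerosities), function(nm)
    rowMeans(library$traj_amps[[nm]][, seq_len(n_traj), drop = FALSE]),
    numeric(length(library$freq)))
  colnames(out$templates) <- library$numerosities
  out$n_traj <- n_traj
  out$traj_amps <- NULL
  out
}

# retrieve one template as an amplitude_spectrum
template_spectrum <- function(library, numerosity) {
  k <- match(numerosity, library$numerosities)
  if (is.na(k)) stop("no template for numerosity ", numerosity)
  structure(list(freq = library$freq, amp = library$templates[, k],
                 dt = library$dt, n = NA_integer_),
            class = "amplitude_spectrum")
}

#' Count dominant spectral peaks
#'
#' Local maxima exceeding `rel_threshold` times the global maximum,
#' after merging maxima closer than one frequency bin. This quantifies
#' the "one new equally spaced peak per additional flip" signature of
#' the all-to-all network.
#'
#' @param spectrum an `amplitude_spectrum`
#' @param rel_threshold relative threshold in (0, 1), default 0.2
#' @return integer peak count
#' @export
count_dominant_peaks <- function(spectrum, rel_threshold = 0.2) {
  length(dominant_peak_frequencies(spectrum, rel_threshold))
}

#' @rdname count_dominant_peaks
#' @return `dominant_peak_frequencies`: angular frequencies of the
#'   merged dominant peaks
#' @export
dominant_peak_frequencies <- function(spectrum, rel_threshold = 0.2) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"),
            rel_threshold > 0, rel_threshold < 1)
  a <- spectrum$amp
  if (length(a) == 0) stop("empty spectrum")
  mx <- max(a)
  if (mx <= 0) return(numeric(0))
  n <- length(a)
  left <- c(-Inf, a[-n])
  right <- c(a[-1], -Inf)
  cand <- which(a > left & a >= right & a >= rel_threshold * mx)
  if (length(cand) == 0) return(numeric(0))
  groups <- cumsum(c(1, diff(cand) > 1))
  vapply(split(cand, groups), function(ix)
    spectrum$freq[ix[which.max(a[ix])]], numeric(1))
}
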