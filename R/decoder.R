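# Ideal-observer decoding: correlate a probe spectrum against every
# template and pick the numerosity with the highest correlation. All
# correlations are accepted; there is no rejection threshold.

#' Pearson correlation of two amplitude spectra
#'
#' Computed across frequency bins; the two spectra must share one grid.
#' A zero-variance spectrum has no defined correlation: `NA` is returned
#' and treated as minus infinity in the decoder ranking.
#'
#' @param sample,template `amplitude_spectrum` objects on one grid
#' @return correlation in `[-1, 1]`, or `NA` for zero variance
#' @export
correlate_spectra <- function(sample, template) {
  stopifnot(inherits(sample, "amplitude_spectrum"),
            inherits(template, "amplitude_spectrum"))
  if (!same_grid(sample, template))
    stop("spectra live on different frequency grids")
  if (sd(sample$amp) == 0 || sd(template$amp) == 0) return(NA_real_)
  cor(sample$amp, template$amp)
}

#' Decode numerosity from a probe spectrum
#'
#' Argmax of the template correlations; exact ties (within `tie_tol`)
#' are broken uniformly at random. Deterministic given `(sample,
#' library, tie_seed)`.
#'
#' @param sample probe `amplitude_spectrum`
#' @param library a `template_library`
#' @param tie_seed seed for the tie-breaking draw; `NULL` uses (and
#'   advances) the current RNG stream
#' @param tie_tol tolerance on correlation differences counting as a tie
#' @return list with `decoded` (numerosity), `correlations` (named
#'   vector) and `tie` (logical)
#' @export
decode_numerosity <- function(sample, library, tie_seed = NULL,
                              tie_tol = 1e-12) {
  stopifnot(inherits(library, "template_library"))
  if (length(library$numerosities) == 0) stop("empty template library")
  cors <- vapply(library$numerosities, function(N)
    correlate_spectra(sample, template_spectrum(library, N)), numeric(1))
  names(cors) <- library$numerosities
  score <- ifelse(is.na(cors), -Inf, cors)
  if (all(score == -Inf))
    stop("probe spectrum has zero variance; nothing to decode")
  best <- max(score)
  cand <- which(score >= best - tie_tol)
  tie <- length(cand) > 1
  pick <- if (tie) {
    with_seed(tie_seed, cand[sample.int(length(cand), 1)])
  } else cand
  list(decoded = library$numerosities[pick], correlations = cors,
       tie = tie)
}

#' Decoder confusion matrix
#'
#' Simulates `n_probes` fresh stimulus realizations per true numerosity,
#' decodes each against the library, and tabulates decoded against true
#' counts (rows sum to `n_probes`).
#'
#' @param library a `template_library`
#' @param spec the [network_spec()] probes are simulated on
#' @param protocol_fun function(N) giving the probe protocol
#' @param n_probes probes per true numerosity
#' @param seed master seed
#' @return integer matrix, rows true N, columns decoded N
#' @export
decode_confusion <- function(library, spec, protocol_fun = function(N)
                               protocol_spec(N),
                             n_probes = 20, seed = 1) {
  stopifnot(n_probes >= 1)
  Ns <- library$numerosities
  cm <- matrix(0L, length(Ns), length(Ns), dimnames = list(Ns, Ns))
  times <- record_grid(library$window, library$dt)
  set.seed(seed)
  for (k in seq_along(Ns)) {
    proto <- protocol_fun(Ns[k])
    proto$seed <- NULL
    for (p in seq_len(n_probes)) {
      ev <- sample_events(proto, spec)
      rec <- evolve_trajectory(spec, ev, times)
      dec <- decode_numerosity(space_average_spectrum(rec), library)
      j <- match(dec$decoded, Ns)
      cm[k, j] <- cm[k, j] + 1L
    }
  }
  cm
}
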