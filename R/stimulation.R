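# Stimulus protocols: seeded random event sequences realizing a given
# numerosity, plus the deterministic staggered-flip demonstration
# sequence.

# run code with a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Stimulation protocol
#'
#' Describes how `numerosity` stimulus events are drawn: event times
#' i.i.d. uniform on the stimulus `window` (then sorted), sites either
#' uniform on 1..M (with replacement by default) or a fixed list, and
#' angles by one of three modes: `fixed_pi` (full flips),
#' `random_rotation` ("RR": angles i.i.d. uniform on (0, pi]) or
#' `constant_energy` ("CE": random angles constrained to sum to
#' `total_angle`, default 3 pi, removing total input energy as a cue).
#'
#' @param numerosity number of events N (>= 1); a warning is issued above
#'   the decodability limit floor(M/2) when sampling
#' @param window stimulus time window `c(t0, t1)` (units 1/J); default
#'   `c(0, 10)`, ahead of the default recording window `c(10, 20)`
#' @param site_mode `"uniform_random"` or `"fixed_list"`
#' @param sites site list for `fixed_list` (length N, used in order)
#' @param angle_mode `"random_rotation"`, `"fixed_pi"` or
#'   `"constant_energy"`
#' @param total_angle total rotation for `constant_energy` (default 3 pi)
#' @param replace sample sites with replacement (default TRUE)
#' @param seed optional seed making [sample_events()] reproducible
#' @return object of class `protocol_spec`
#' @export
protocol_spec <- function(numerosity, window = c(0, 10),
                          site_mode = c("uniform_random", "fixed_list"),
                          sites = NULL,
                          angle_mode = c("random_rotation", "fixed_pi",
                                         "constant_energy"),
                          total_angle = 3 * pi, replace = TRUE,
                          seed = NULL) {
  site_mode <- match.arg(site_mode)
  angle_mode <- match.arg(angle_mode)
  stopifnot(numerosity >= 1, numerosity == round(numerosity),
            length(window) == 2, window[2] > window[1], window[1] >= 0)
  if (site_mode == "fixed_list") {
    if (is.null(sites) || length(sites) != numerosity)
      stop("fixed_list requires `sites` of length ", numerosity)
  }
  if (angle_mode == "constant_energy") {
    stopifnot(total_angle > 0)
    if (total_angle > numerosity * pi)
      stop("total_angle > N*pi is infeasible with angles <= pi")
  }
  structure(list(numerosity = as.integer(numerosity), window = window,
                 site_mode = site_mode, sites = sites,
                 angle_mode = angle_mode, total_angle = total_angle,
                 replace = replace, seed = seed),
            class = "protocol_spec")
}

#' Random angles with a fixed total
#'
#' Draws N angles in (0, pi] summing exactly to `total`: uniform on the
#' scaled simplex (spacings of sorted uniforms), rejection-sampled until
#' every angle is <= pi. At the feasibility boundary `total = N*pi` the
#' only solution, all angles pi, is returned directly.
#'
#' @param n number of angles N
#' @param total required sum (0 < total <= N*pi)
#' @param max_iter rejection cap
#' @return numeric vector of N angles; `sum(angles) == total` to 1e-12
#' @export
constant_energy_angles <- function(n, total, max_iter = 100000) {
  stopifnot(n >= 1, total > 0)
  if (total > n * pi) stop("total > N*pi is infeasible with angles <= pi")
  if (n == 1) return(total)
  if (abs(total - n * pi) < 1e-12) return(rep(pi, n))
  for (it in seq_len(max_iter)) {
    w <- diff(sort(c(0, runif(n - 1), 1))) * total
    w <- w * (total / sum(w))
    if (all(w > 0 & w <= pi)) return(w)
  }
  stop("rejection sampling failed near the feasibility boundary ",
       "(total = ", total, ", N = ", n, ")")
}

#' Sample a stimulus event sequence
#'
#' @param protocol a [protocol_spec()]
#' @param spec the target [network_spec()] (provides M)
#' @return data.frame of events (time, site, angle) sorted by time, with
#'   the generating protocol and seed attached as attributes
#' @export
sample_events <- function(protocol, spec) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(spec, "network_spec"))
  M <- spec$n_sites
  N <- protocol$numerosity
  if (N > floor(M / 2))
    warning("numerosity ", N, " exceeds the decodability limit floor(M/2) = ",
            floor(M / 2))
  with_seed(protocol$seed, {
    tms <- sort(runif(N, protocol$window[1], protocol$window[2]))
    sites <- switch(protocol$site_mode,
      uniform_random = sample.int(M, N, replace = protocol$replace),
      fixed_list = as.integer(protocol$sites))
    angles <- switch(protocol$angle_mode,
      fixed_pi = rep(pi, N),
      random_rotation = pi * runif(N),
      constant_energy = constant_energy_angles(N, protocol$total_angle))
    ev <- data.frame(time = tms, site = sites, angle = angles)
    attr(ev, "protocol") <- protocol
    attr(ev, "seed") <- protocol$seed
    ev
  })
}

#' Deterministic staggered-flip demonstration sequence
#'
#' N in 1..3 full (pi) flips at odd sites 1, 3, 5, evenly spaced inside
#' the stimulus window, so the recording window that follows is free of
#' events. Used to demonstrate that each additional flip adds one
#' equally-spaced low-frequency peak to the all-to-all spectrum.
#'
#' @param n_flips numerosity N in 1..3
#' @param window stimulus window (default `c(0, 10)`)
#' @return event data.frame (time, site, angle)
#' @export
demo_event_sequence <- function(n_flips, window = c(0, 10)) {
  stopifnot(n_flips %in% 1:3)
  sites <- c(1L, 3L, 5L)[seq_len(n_flips)]
  tms <- window[1] + diff(window) * (seq_len(n_flips) - 1) / n_flips
  data.frame(time = tms, site = sites, angle = rep(pi, n_flips))
}

#' Serialize / restore an event sequence
#'
#' @param events event data.frame
#' @return `events_to_json`: JSON string (fields time, site, angle_rad,
#'   axis); `events_from_json`: event data.frame
#' @export
events_to_json <- function(events) {
  jsonlite::toJSON(data.frame(time = events$time, site = events$site,
                              angle_rad = events$angle, axis = "x"),
                   digits = NA)
}

#' @rdname events_to_json
#' @param json JSON produced by [events_to_json()]
#' @export
events_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  data.frame(time = x$time, site = as.integer(x$site), angle = x$angle_rad)
}
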