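# Time evolution: quantum trajectories (pure states, with waiting-time
# jump sampling) and a density-matrix master-equation oracle for small M.

#' Solver configuration
#'
#' @param tol local Krylov error tolerance per substep
#' @param krylov_dim maximal Arnoldi subspace dimension
#' @param seed optional RNG seed applied at the start of a trajectory
#' @param method closed-dynamics propagator: `"auto"` picks a cached
#'   dense eigendecomposition up to dimension 2048 and Krylov beyond
#'   (the two must and do agree; see tests); dissipative runs always use
#'   Krylov
#' @return object of class `solver_config`
#' @export
solver_config <- function(tol = 1e-9, krylov_dim = 30, seed = NULL,
                          method = c("auto", "dense", "krylov")) {
  stopifnot(tol > 0, krylov_dim >= 2)
  structure(list(tol = tol, krylov_dim = as.integer(krylov_dim),
                 seed = seed, method = match.arg(method)),
            class = "solver_config")
}

#' Stimulus event
#'
#' A transient stimulus is an instantaneous single-site rotation
#' \eqn{\exp(-i \theta \sigma^x_{site} / 2)} applied at `time`. A pi
#' rotation flips a resting (down) spin fully up; intermediate angles
#' create partial excitations. The x axis is a fixed convention: for
#' \eqn{\sigma^z} observables any axis in the xy plane is equivalent up to
#' phases.
#'
#' @param time event time (units 1/J, >= 0)
#' @param site stimulated site (1..M)
#' @param angle rotation angle in `[0, pi]`
#' @return one-row data.frame (events concatenate with `rbind`)
#' @export
stimulus_event <- function(time, site, angle) {
  stopifnot(time >= 0, angle >= 0, angle <= pi, site == round(site))
  data.frame(time = time, site = as.integer(site), angle = angle)
}

check_events <- function(events, n_sites) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(time = numeric(0), site = integer(0),
                      angle = numeric(0)))
  stopifnot(all(c("time", "site", "angle") %in% names(events)))
  if (is.unsorted(events$time)) stop("events must be sorted by time")
  if (any(events$site < 1 | events$site > n_sites))
    stop("event site out of range 1..", n_sites)
  if (any(events$angle < 0 | events$angle > pi))
    stop("event angle outside [0, pi]")
  if (any(events$time < 0)) stop("event times must be >= 0")
  events
}

#' Pure state of the network
#'
#' @param n_sites number of spins M
#' @param up_sites sites prepared spin-up (all others down); default the
#'   all-down resting state
#' @return complex amplitude vector over the 2^M computational basis with
#'   attribute `n_sites`, class `pure_state`
#' @export
pure_state <- function(n_sites, up_sites = integer(0)) {
  stopifnot(all(up_sites %in% seq_len(n_sites)),
            !anyDuplicated(up_sites))
  psi <- complex(2^n_sites)
  psi[sum(2^(up_sites - 1)) + 1] <- 1 + 0i
  structure(psi, n_sites = as.integer(n_sites), class = "pure_state")
}

#' Apply a stimulus rotation to a pure state
#'
#' \eqn{\exp(-i\theta\sigma^x/2) = \cos(\theta/2) I - i \sin(\theta/2)
#' \sigma^x}; norm-preserving.
#'
#' @param state a [pure_state()] (or plain complex vector with
#'   `n_sites` attribute)
#' @param event a [stimulus_event()] (its `time` is ignored here)
#' @return the rotated state
#' @export
apply_stimulus <- function(state, event) {
  M <- attr(state, "n_sites")
  if (is.null(M)) stop("state lacks an n_sites attribute")
  event <- check_events(event, M)
  psi <- unclass(state)
  for (k in seq_len(nrow(event))) {
    site <- event$site[k]
    th <- event$angle[k]
    if (th == 0) next
    perm <- bitwXor(0:(2^M - 1), bitwShiftL(1L, site - 1L)) + 1L
    psi <- cos(th / 2) * psi - 1i * sin(th / 2) * psi[perm]
  }
  structure(psi, n_sites = M, class = "pure_state")
}

new_trajectory_record <- function(times, mag, events = NULL, spec = NULL,
                                  seed = NULL, norms = NULL,
                                  n_jumps = NA_integer_) {
  rownames(mag) <- paste0("site_", seq_len(nrow(mag)))
  structure(list(times = times, mag = mag, events = events, spec = spec,
                 seed = seed, norms = norms, n_jumps = n_jumps),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record> %d sites x %d times, t in [%g, %g]\n",
              nrow(x$mag), ncol(x$mag), min(x$times), max(x$times)))
  if (!is.null(x$events) && nrow(x$events))
    cat(sprintf("  %d stimulus events\n", nrow(x$events)))
  invisible(x)
}

# complex sparse matvec (Matrix's dgCMatrix is real-only)
sp_cmatvec <- function(A, v) {
  as.vector(A %*% Re(v)) + 1i * as.vector(A %*% Im(v))
}

# interleave events and recording times; events first on ties
make_schedule <- function(events, times) {
  ev <- if (nrow(events)) data.frame(t = events$time, type = "e",
                                     idx = seq_len(nrow(events)))
  sched <- rbind(ev, data.frame(t = times, type = "r",
                                idx = seq_along(times)))
  sched[order(sched$t, sched$type == "r"), , drop = FALSE]
}

#' Evolve one quantum trajectory
#'
#' Integrates a single stochastic unraveling of the master equation:
#' between jumps the state follows the non-Hermitian generator
#' \eqn{H - (i/2)\sum_m \gamma_m J_m^\dagger J_m} (Krylov-propagated
#' exactly to each event/recording time), jumps are drawn by the
#' waiting-time (norm-threshold) algorithm, and stimulus rotations are
#' applied as instantaneous unitaries at their event times (events at a
#' recording time are applied first). With no dissipation the evolution
#' is deterministic Schroedinger dynamics. Bit-reproducible given the
#' seed.
#'
#' @param spec a [network_spec()]
#' @param events data.frame of [stimulus_event()]s sorted by time
#' @param times increasing recording grid (units 1/J); magnetization
#'   \eqn{\langle\sigma^z_i\rangle} is recorded at each
#' @param state initial [pure_state()]; default all-down
#' @param config a [solver_config()]
#' @return a `trajectory_record`
#' @export
evolve_trajectory <- function(spec, events = NULL, times,
                              state = NULL, config = solver_config()) {
  stopifnot(inherits(spec, "network_spec"))
  M <- spec$n_sites
  events <- check_events(events, M)
  stopifnot(length(times) >= 1, !is.unsorted(times, strictly = TRUE),
            times[1] >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(state)) state <- pure_state(M)
  psi <- as.complex(unclass(state))

  masks <- full_basis(M)
  H <- cached_hamiltonian(spec)
  d <- decay_diagonal(spec, masks)
  jumps <- build_jump_operators(spec)
  closed <- length(jumps) == 0

  sched <- make_schedule(events, times)

  mag <- matrix(NA_real_, M, length(times))
  norms <- numeric(length(times))
  t_cur <- 0
  n_jumps <- 0L

  if (closed) {
    use_dense <- config$method == "dense" ||
      (config$method == "auto" && length(masks) <= dense_limit())
    if (use_dense) {
      eig <- get_eigen(spec, H = H)
      zs <- zsign_matrix(masks, M)
    }
    k <- 1L
    while (k <= nrow(sched)) {
      if (sched$type[k] == "e") {
        tau <- sched$t[k] - t_cur
        if (tau > 0) {
          psi <- if (use_dense) dense_propagate(eig, psi, tau)
                 else krylov_propagate(H, d, psi, tau, config$krylov_dim,
                                       config$tol)
        }
        t_cur <- sched$t[k]
        psi <- unclass(apply_stimulus(structure(psi, n_sites = M),
                                      events[sched$idx[k], , drop = FALSE]))
        k <- k + 1L
      } else {
        # maximal run of record actions -> one batched call
        k2 <- k
        while (k2 < nrow(sched) && sched$type[k2 + 1L] == "r") k2 <- k2 + 1L
        rts <- sched$t[k:k2]
        taus <- diff(c(t_cur, rts))
        res <- if (use_dense) dense_propagate_record(eig, zs, psi, taus)
               else cpp_propagate_record(H, d, psi, taus, masks, M,
                                         config$krylov_dim, config$tol)
        cols <- sched$idx[k:k2]
        mag[, cols] <- res$mag
        norms[cols] <- res$norm
        psi <- res$psi
        t_cur <- rts[length(rts)]
        k <- k2 + 1L
      }
    }
    if (max(abs(norms - 1)) > 1e-6)
      warning("norm drift ", signif(max(abs(norms - 1)), 3),
              " in closed evolution")
  } else {
    rthr <- runif(1)
    nrm2 <- sum(Mod(psi)^2)
    advance <- function(tau) {
      while (tau > 1e-14) {
        cand <- krylov_propagate(H, d, psi, tau, config$krylov_dim,
                                 config$tol)
        c2 <- sum(Mod(cand)^2)
        if (c2 >= rthr) {
          psi <<- cand
          nrm2 <<- c2
          return(invisible())
        }
        # bisect the jump time s in (0, tau]: norm^2 decays monotonically
        lo <- 0; hi <- tau
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          pm <- krylov_propagate(H, d, psi, mid, config$krylov_dim,
                                 config$tol)
          if (sum(Mod(pm)^2) >= rthr) lo <- mid else hi <- mid
        }
        s <- (lo + hi) / 2
        psi_s <- krylov_propagate(H, d, psi, s, config$krylov_dim,
                                  config$tol)
        jv <- lapply(jumps, function(j) sp_cmatvec(j$op, psi_s))
        w <- vapply(seq_along(jumps),
                    function(i) jumps[[i]]$rate * sum(Mod(jv[[i]])^2),
                    numeric(1))
        if (sum(w) <= 0) stop("norm underflow at jump sampling")
        ch <- sample.int(length(jumps), 1, prob = w)
        psi_new <- jv[[ch]]
        psi <<- psi_new / sqrt(sum(Mod(psi_new)^2))
        nrm2 <<- 1
        rthr <<- runif(1)
        n_jumps <<- n_jumps + 1L
        tau <- tau - s
      }
      invisible()
    }
    for (k in seq_len(nrow(sched))) {
      advance(sched$t[k] - t_cur)
      t_cur <- sched$t[k]
      if (sched$type[k] == "e") {
        psi <- unclass(apply_stimulus(structure(psi, n_sites = M),
                                      events[sched$idx[k], , drop = FALSE]))
      } else {
        mag[, sched$idx[k]] <- cpp_site_mags(psi, masks, M)
        norms[sched$idx[k]] <- sqrt(nrm2)
      }
    }
  }
  new_trajectory_record(times, mag, events = events, spec = spec,
                        seed = config$seed, norms = norms,
                        n_jumps = n_jumps)
}

#' Closed-system evolution inside one magnetization sector
#'
#' Fast path for deterministic pi-flip protocols: all flips are applied
#' at t = 0 on distinct sites, the state then lives in the C(M, N)
#' sector, and closed dynamics never leave it. Must (and does, see
#' tests) match full-space [evolve_trajectory()].
#'
#' @param spec a [network_spec()] with zero dissipation
#' @param up_sites distinct sites flipped up at t = 0
#' @param times increasing recording grid
#' @param config a [solver_config()]
#' @return a `trajectory_record`
#' @export
sector_record <- function(spec, up_sites, times, config = solver_config()) {
  stopifnot(inherits(spec, "network_spec"),
            spec$gamma_loss == 0, spec$gamma_dephase == 0,
            !anyDuplicated(up_sites),
            all(up_sites %in% seq_len(spec$n_sites)))
  sh <- sector_hamiltonian(spec, length(up_sites))
  n <- length(sh$masks)
  psi <- complex(n)
  psi[match_masks(sum(bitwShiftL(1L, as.integer(up_sites) - 1L)),
                  sh$masks)] <- 1 + 0i
  d <- numeric(n)
  taus <- diff(c(0, times))
  if (any(taus < 0)) stop("times must be increasing and >= 0")
  use_dense <- config$method == "dense" ||
    (config$method == "auto" && n <= dense_limit())
  res <- if (use_dense) {
    eig <- get_eigen(spec, H = sh$H,
                     key = spec_key(spec, paste0("sector", length(up_sites))))
    dense_propagate_record(eig, zsign_matrix(sh$masks, spec$n_sites),
                           psi, taus)
  } else {
    cpp_propagate_record(sh$H, d, psi, taus, sh$masks, spec$n_sites,
                         config$krylov_dim, config$tol)
  }
  ev <- do.call(rbind, lapply(up_sites, stimulus_event, time = 0,
                              angle = pi))
  new_trajectory_record(times, res$mag, events = ev, spec = spec,
                        norms = res$norm, n_jumps = 0L)
}

#' Master-equation oracle (small networks)
#'
#' Integrates the GKSL equation
#' \eqn{\dot\rho = -i[H,\rho] - \tfrac12\sum_m \gamma_m
#' (J_m^\dagger J_m \rho + \rho J_m^\dagger J_m - 2 J_m \rho
#' J_m^\dagger)} by Arnoldi propagation of the vectorized density matrix
#' (dense, hence capped at M <= 8). Stimuli enter as unitary
#' conjugations. Serves as the correctness oracle for the trajectory
#' unraveling.
#'
#' @param spec a [network_spec()]
#' @param events sorted stimulus events
#' @param times increasing recording grid
#' @param rho0 initial density matrix (default: all-down pure state)
#' @param max_sites memory guard (default 8)
#' @param tol Arnoldi tolerance
#' @return a `trajectory_record` (magnetization traces of the exact
#'   ensemble average)
#' @export
evolve_master <- function(spec, events = NULL, times, rho0 = NULL,
                          max_sites = 8, tol = 1e-10) {
  stopifnot(inherits(spec, "network_spec"))
  M <- spec$n_sites
  if (M > max_sites)
    stop("master-equation oracle capped at M = ", max_sites)
  events <- check_events(events, M)
  stopifnot(!is.unsorted(times, strictly = TRUE), times[1] >= 0)
  n <- 2^M
  H <- as.matrix(build_hamiltonian(spec))
  jumps <- lapply(build_jump_operators(spec),
                  function(j) list(op = as.matrix(j$op), rate = j$rate))
  pj <- lapply(jumps, function(j) crossprod(j$op)) # J^+ J (real)
  zs <- zsign_matrix(full_basis(M), M)

  lfun <- function(v) {
    rho <- matrix(v, n, n)
    out <- -1i * (H %*% rho - rho %*% H)
    for (k in seq_along(jumps)) {
      g <- jumps[[k]]$rate; J <- jumps[[k]]$op; P <- pj[[k]]
      out <- out + g * (J %*% rho %*% t(J)) -
        (g / 2) * (P %*% rho + rho %*% P)
    }
    as.vector(out)
  }

  if (is.null(rho0)) {
    rho <- matrix(0i, n, n)
    rho[1, 1] <- 1 + 0i
  } else {
    rho <- rho0
    stopifnot(all(dim(rho) == n))
  }
  if (abs(sum(diag(rho)) - 1) > 1e-8) stop("initial state must have trace 1")

  conj_event <- function(rho, ev) {
    th <- ev$angle
    if (th == 0) return(rho)
    perm <- bitwXor(0:(n - 1), bitwShiftL(1L, ev$site - 1L)) + 1L
    U <- diag(cos(th / 2) + 0i, n)
    U[cbind(seq_len(n), perm)] <- U[cbind(seq_len(n), perm)] -
      1i * sin(th / 2)
    U %*% rho %*% Conj(t(U))
  }

  sched <- make_schedule(events, times)

  mag <- matrix(NA_real_, M, length(times))
  t_cur <- 0
  for (k in seq_len(nrow(sched))) {
    tau <- sched$t[k] - t_cur
    if (tau > 0) {
      v <- expmv_arnoldi(lfun, as.vector(rho), tau, tol = tol)
      rho <- matrix(v, n, n)
      t_cur <- sched$t[k]
    }
    tr <- Re(sum(diag(rho)))
    if (abs(tr - 1) > 1e-6)
      stop("trace drift ", signif(abs(tr - 1), 3), " at t = ", t_cur)
    if (sched$type[k] == "e") {
      rho <- conj_event(rho, events[sched$idx[k], , drop = FALSE])
    } else {
      p <- Re(diag(rho)) / tr
      mag[, sched$idx[k]] <- as.vector(zs %*% p)
    }
  }
  new_trajectory_record(times, mag, events = events, spec = spec)
}

#' Light-cone arrival analysis of a chain record
#'
#' For a nearest-neighbour chain with a single initial excitation, the
#' magnetization deviation from rest spreads ballistically: the first
#' time each site deviates from -1 by more than `threshold` should
#' increase with its distance from the stimulated site. Refuses
#' all-to-all records, where no cone exists.
#'
#' @param record a `trajectory_record`
#' @param spec the generating [network_spec()]
#' @param threshold deviation threshold on \eqn{|\langle\sigma^z_i\rangle
#'   + 1|} (default 0.05); a non-positive threshold is flagged degenerate
#' @return list with `arrival` (data.frame site, distance, arrival_time),
#'   `monotone` (arrival non-decreasing with distance) and `degenerate`
#' @export
lightcone_check <- function(record, spec, threshold = 0.05) {
  stopifnot(inherits(record, "trajectory_record"),
            inherits(spec, "network_spec"))
  if (spec$connectivity == "all_to_all")
    stop("light-cone analysis is meaningless for all-to-all coupling")
  if (is.null(record$events) || nrow(record$events) < 1)
    stop("record has no stimulus events; no source site")
  origin <- record$events$site[1]
  M <- nrow(record$mag)
  degenerate <- threshold <= 0
  arrival <- vapply(seq_len(M), function(i) {
    hit <- which(abs(record$mag[i, ] + 1) > threshold)
    if (degenerate) record$times[1]
    else if (length(hit)) record$times[hit[1]] else NA_real_
  }, numeric(1))
  dist <- abs(seq_len(M) - origin)
  ord <- order(dist)
  a <- arrival[ord]
  monotone <- !anyNA(a) && !is.unsorted(a)
  list(arrival = data.frame(site = seq_len(M), distance = dist,
                            arrival_time = arrival),
       monotone = monotone, degenerate = degenerate)
}
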