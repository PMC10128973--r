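# Model definition: spin-1/2 network with exchange coupling J on linked
# pairs, a Gaussian-profile Ising (sigma^z sigma^z) interaction acting on
# all pairs, and per-site loss / dephasing channels.

#' Define a spin network
#'
#' The network Hamiltonian (hbar = 1, energies in units of the exchange J,
#' times in 1/J) is
#' \deqn{H = \sum_{i<j} J A_{ij} (\sigma^+_i \sigma^-_j + h.c.)
#'          + \sum_{i<j} \Delta_{ij} \sigma^z_i \sigma^z_j,}
#' with \eqn{A} the 0/1 adjacency matrix and
#' \eqn{\Delta_{ij} = \Delta_0 \exp[-(i-j)^2/(2\sigma^2)]} a
#' distance-dependent interaction profile acting on all pairs (it does not
#' require a link; set `delta0 = 0` to switch it off). Dissipation enters
#' through per-site channels: loss \eqn{\sigma^-_m} at rate `gamma_loss`
#' and dephasing \eqn{\sigma^z_m} at rate `gamma_dephase`.
#'
#' @param n_sites number of spins M (sites are indexed 1..M, 1 = leftmost)
#' @param connectivity `"all_to_all"`, `"nearest_neighbour"` (open chain)
#'   or `"custom"` (supply `adjacency`)
#' @param J exchange amplitude between linked sites (default 1)
#' @param delta0 overall amplitude of the interaction profile (>= 0)
#' @param sigma_int width of the interaction profile, in lattice sites
#' @param gamma_loss per-site excitation-loss rate (>= 0, units of J)
#' @param gamma_dephase per-site dephasing rate (>= 0, units of J)
#' @param adjacency symmetric 0/1 matrix with zero diagonal (custom only)
#' @return an object of class `network_spec`
#' @export
network_spec <- function(n_sites,
                         connectivity = c("all_to_all", "nearest_neighbour",
                                          "custom"),
                         J = 1, delta0 = 0, sigma_int = 1 / sqrt(2),
                         gamma_loss = 0, gamma_dephase = 0,
                         adjacency = NULL) {
  connectivity <- match.arg(connectivity)
  stopifnot(length(n_sites) == 1, n_sites >= 1, n_sites == round(n_sites),
            is.numeric(J), length(J) == 1,
            delta0 >= 0, sigma_int > 0,
            gamma_loss >= 0, gamma_dephase >= 0)
  n_sites <- as.integer(n_sites)
  if (connectivity == "custom") {
    if (is.null(adjacency)) stop("custom connectivity requires `adjacency`")
    adjacency <- as.matrix(adjacency)
    if (!all(dim(adjacency) == n_sites))
      stop("adjacency must be ", n_sites, " x ", n_sites)
    if (!isTRUE(all.equal(adjacency, t(adjacency))))
      stop("adjacency must be symmetric")
    if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
    if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  } else {
    adjacency <- switch(connectivity,
      nearest_neighbour = {
        a <- matrix(0, n_sites, n_sites)
        if (n_sites > 1) {
          idx <- cbind(1:(n_sites - 1), 2:n_sites)
          a[idx] <- 1
          a[idx[, 2:1, drop = FALSE]] <- 1
        }
        a
      },
      all_to_all = {
        a <- matrix(1, n_sites, n_sites)
        diag(a) <- 0
        a
      })
  }
  structure(list(n_sites = n_sites, connectivity = connectivity,
                 adjacency = adjacency, J = J, delta0 = delta0,
                 sigma_int = sigma_int, gamma_loss = gamma_loss,
                 gamma_dephase = gamma_dephase),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> M = %d, %s, J = %g, delta0 = %g, sigma = %g\n",
              x$n_sites, x$connectivity, x$J, x$delta0, x$sigma_int))
  cat(sprintf("  gamma_loss = %g, gamma_dephase = %g\n",
              x$gamma_loss, x$gamma_dephase))
  invisible(x)
}

#' Gaussian interaction profile between two sites
#'
#' \eqn{\Delta_{ij} = \Delta_0 \exp[-(i-j)^2 / (2\sigma^2)]}; symmetric in
#' (i, j), maximal at i = j, strictly decreasing in |i - j|.
#'
#' @param i,j site indices in 1..M (vectorized)
#' @param spec a [network_spec()]
#' @return numeric interaction energy (units of J)
#' @export
interaction_profile <- function(i, j, spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (any(i < 1 | i > spec$n_sites | j < 1 | j > spec$n_sites))
    stop("site index out of range 1..", spec$n_sites)
  spec$delta0 * exp(-(i - j)^2 / (2 * spec$sigma_int^2))
}

# full M x M interaction matrix (zero diagonal; self-terms are a constant
# energy shift since sigma^z squared is the identity)
delta_matrix <- function(spec) {
  M <- spec$n_sites
  d <- outer(1:M, 1:M, interaction_profile, spec = spec)
  diag(d) <- 0
  d
}

# Shared Hamiltonian assembly over an arbitrary (sorted) mask basis.
hamiltonian_on_basis <- function(spec, masks) {
  M <- spec$n_sites
  n <- length(masks)
  z <- 2 * bit_matrix(masks, M) - 1  # n x M of +-1
  dm <- delta_matrix(spec)
  dm_upper <- dm
  dm_upper[lower.tri(dm_upper, diag = TRUE)] <- 0
  diag_e <- rowSums((z %*% dm_upper) * z)

  ii <- vector("list", 0L); jj <- vector("list", 0L)
  links <- which(upper.tri(spec$adjacency) & spec$adjacency == 1,
                 arr.ind = TRUE)
  k <- 0L
  if (nrow(links) > 0) {
    ii <- vector("list", 2L * nrow(links))
    jj <- vector("list", 2L * nrow(links))
    for (l in seq_len(nrow(links))) {
      a <- links[l, 1]; b <- links[l, 2]
      ba <- bitwShiftL(1L, a - 1L); bb <- bitwShiftL(1L, b - 1L)
      # states with a up, b down -> hop a -> b
      sel <- which(bitwAnd(masks, ba) != 0L & bitwAnd(masks, bb) == 0L)
      if (length(sel)) {
        to <- match_masks(masks[sel] - ba + bb, masks)
        keep <- !is.na(to)
        k <- k + 1L; ii[[k]] <- sel[keep]; jj[[k]] <- to[keep]
        k <- k + 1L; ii[[k]] <- to[keep];  jj[[k]] <- sel[keep]
      }
    }
  }
  ii <- unlist(ii[seq_len(k)]); jj <- unlist(jj[seq_len(k)])
  Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                       x = c(diag_e, rep(spec$J, length(ii))),
                       dims = c(n, n))
}

#' Build the network Hamiltonian in the full 2^M space
#'
#' Returns a sparse real symmetric matrix over the computational basis
#' (tensor products of down/up, basis state b has site i up iff bit i-1 of
#' b is set). The exchange term only connects states within one
#' magnetization sector, so H commutes with the total \eqn{\sum_i
#' \sigma^z_i}.
#'
#' @param spec a [network_spec()]
#' @param max_sites memory guard on M for the full-space representation
#'   (use [sector_hamiltonian()] for larger networks)
#' @return `dgCMatrix` of dimension 2^M
#' @export
build_hamiltonian <- function(spec, max_sites = 14) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$n_sites > max_sites)
    stop("M = ", spec$n_sites, " exceeds the full-space guard (", max_sites,
         "); use sector_hamiltonian() or raise `max_sites`")
  hamiltonian_on_basis(spec, full_basis(spec$n_sites))
}

#' Hamiltonian restricted to a fixed-magnetization sector
#'
#' With only pi flips applied at t = 0 (or none), dynamics stay inside one
#' sector of dimension C(M, N); this is the representation that makes
#' M = 18 tractable.
#'
#' @param spec a [network_spec()]
#' @param n_up number of up spins N
#' @return list with `H` (sparse C(M,N) x C(M,N)) and `masks` (sorted
#'   basis bitmasks)
#' @export
sector_hamiltonian <- function(spec, n_up) {
  stopifnot(inherits(spec, "network_spec"))
  masks <- sector_basis(spec$n_sites, n_up)
  list(H = hamiltonian_on_basis(spec, masks), masks = masks)
}

#' Dissipation channel operators
#'
#' One loss channel \eqn{\sigma^-_m} per site when `gamma_loss > 0` and
#' one dephasing channel \eqn{\sigma^z_m} per site when
#' `gamma_dephase > 0`; an empty list for a closed system.
#'
#' @param spec a [network_spec()]
#' @return list of entries `list(op, rate, type, site)` with `op` sparse
#'   over the full 2^M basis
#' @export
build_jump_operators <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  M <- spec$n_sites
  masks <- full_basis(M)
  n <- length(masks)
  out <- list()
  if (spec$gamma_loss > 0) {
    for (m in 1:M) {
      bm <- bitwShiftL(1L, m - 1L)
      sel <- which(bitwAnd(masks, bm) != 0L)   # site m up
      op <- Matrix::sparseMatrix(i = match_masks(masks[sel] - bm, masks),
                                 j = sel, x = rep(1, length(sel)),
                                 dims = c(n, n))
      out[[length(out) + 1L]] <- list(op = op, rate = spec$gamma_loss,
                                      type = "loss", site = m)
    }
  }
  if (spec$gamma_dephase > 0) {
    zs <- zsign_matrix(masks, M)
    for (m in 1:M) {
      op <- Matrix::Diagonal(n, x = zs[m, ])
      out[[length(out) + 1L]] <- list(op = op, rate = spec$gamma_dephase,
                                      type = "dephase", site = m)
    }
  }
  out
}

#' Per-site magnetization operators
#'
#' \eqn{\sigma^z_i} is diagonal in the computational basis with
#' eigenvalues +1 (up) / -1 (down).
#'
#' @param spec a [network_spec()]
#' @return list of M sparse diagonal operators
#' @export
magnetization_operators <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  masks <- full_basis(spec$n_sites)
  zs <- zsign_matrix(masks, spec$n_sites)
  lapply(seq_len(spec$n_sites),
         function(i) Matrix::Diagonal(length(masks), x = zs[i, ]))
}

#' Serialize / restore a network definition
#'
#' @param spec a [network_spec()]
#' @return `spec_to_json`: a JSON string; `spec_from_json`: a
#'   `network_spec`
#' @export
spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  x <- list(n_sites = spec$n_sites, connectivity = spec$connectivity,
            J = spec$J, delta0 = spec$delta0, sigma_int = spec$sigma_int,
            gamma_loss = spec$gamma_loss, gamma_dephase = spec$gamma_dephase)
  if (spec$connectivity == "custom") x$adjacency <- spec$adjacency
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname spec_to_json
#' @param json a JSON string produced by [spec_to_json()]
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  network_spec(n_sites = x$n_sites, connectivity = x$connectivity,
               J = x$J, delta0 = x$delta0, sigma_int = x$sigma_int,
               gamma_loss = x$gamma_loss, gamma_dephase = x$gamma_dephase,
               adjacency = x$adjacency)
}
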