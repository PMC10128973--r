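# Computational-basis bookkeeping. Basis states are integer bitmasks:
# bit (i-1) set means site i carries an up spin; the all-down resting
# state is mask 0. Site 1 is the leftmost site of the chain.

#' Bitmasks of the full 2^M computational basis
#' @param n_sites number of spins M
#' @return integer vector of length 2^M (masks 0 .. 2^M - 1)
#' @keywords internal
full_basis <- function(n_sites) {
  stopifnot(n_sites >= 1, n_sites <= 25)
  0:(2L^n_sites - 1L)
}

#' Bitmasks of a fixed-magnetization sector
#'
#' Enumerates the C(M, N) basis states with exactly `n_up` up spins,
#' sorted increasingly so states can be located with a binary search.
#'
#' @param n_sites number of spins M
#' @param n_up number of up spins N in the sector
#' @return sorted integer vector of bitmasks
#' @export
sector_basis <- function(n_sites, n_up) {
  stopifnot(n_up >= 0, n_up <= n_sites)
  if (n_up == 0) return(0L)
  if (n_up == n_sites) return(as.integer(2^n_sites - 1))
  combos <- utils::combn(n_sites, n_up)
  masks <- as.integer(colSums(matrix(2^(combos - 1), nrow = n_up)))
  sort(masks)
}

# 0/1 matrix (n_states x n_sites) of up-spin occupations
bit_matrix <- function(masks, n_sites) {
  vapply(seq_len(n_sites),
         function(i) as.integer(bitwAnd(masks, bitwShiftL(1L, i - 1L)) != 0L),
         integer(length(masks)))
}

# n_sites x n_states matrix of sigma^z eigenvalues (+1 up / -1 down)
zsign_matrix <- function(masks, n_sites) {
  t(2 * bit_matrix(masks, n_sites) - 1)
}

# number of up spins per mask
popcount <- function(masks) {
  n <- integer(length(masks))
  x <- masks
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# position of each mask in a sorted basis (NA if absent)
match_masks <- function(masks, basis) {
  idx <- findInterval(masks, basis)
  idx[idx < 1L] <- NA_integer_
  ok <- !is.na(idx) & basis[pmax(idx, 1L)] == masks
  idx[!ok] <- NA_integer_
  idx
}
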