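# Shared fixtures: tiny networks and a dense brute-force Hamiltonian
# builder used as an independent oracle against the sparse constructor.

chain3 <- function(...) network_spec(3, "nearest_neighbour", ...)
aa7 <- function(...) network_spec(7, "all_to_all", ...)

# dense Hamiltonian from explicit Kronecker products (oracle)
kron_hamiltonian <- function(spec) {
  M <- spec$n_sites
  sx <- matrix(c(0, 1, 1, 0), 2)
  sy <- matrix(c(0, 1i, -1i, 0), 2)
  sz <- diag(c(-1, 1))          # site basis ordered down, up
  id <- diag(2)
  site_op <- function(op, i) {
    out <- 1
    for (k in 1:M) out <- kronecker(if (k == i) op else id, out)
    out
  }
  sp <- (sx + 1i * sy) / 2       # raising operator in this ordering
  H <- matrix(0i, 2^M, 2^M)
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    if (spec$adjacency[i, j] == 1) {
      t1 <- site_op(sp, i) %*% Conj(t(site_op(sp, j)))
      H <- H + spec$J * (t1 + Conj(t(t1)))
    }
    H <- H + interaction_profile(i, j, spec) *
      site_op(sz, i) %*% site_op(sz, j)
  }
  H
}

expect_spectra_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$freq, b$freq, tolerance = 1e-12)
  expect_lt(max(abs(a$amp - b$amp)), tol)
}
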