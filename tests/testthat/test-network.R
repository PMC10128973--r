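test_that("interaction profile follows the Gaussian distance law", {
  sp <- network_spec(7, "all_to_all", delta0 = 0.1,
                     sigma_int = 1 / sqrt(2))
  expect_equal(interaction_profile(3, 3, sp), 0.1)        # zero separation
  expect_equal(interaction_profile(1, 2, sp), 0.1 * exp(-1),
               tolerance = 1e-12)
  expect_equal(interaction_profile(2, 5, sp), interaction_profile(5, 2, sp))
  d <- interaction_profile(1, 1:7, sp)
  expect_true(all(diff(d) < 0))                            # strictly decreasing
  expect_error(interaction_profile(0, 1, sp), "out of range")
})

test_that("network_spec validates adjacency and rates", {
  expect_error(network_spec(3, gamma_loss = -0.1))
  expect_error(network_spec(3, "custom"), "adjacency")
  bad <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3)
  expect_error(network_spec(3, "custom", adjacency = bad), "symmetric")
  nn <- network_spec(4, "nearest_neighbour")
  expect_equal(which(nn$adjacency[1, ] == 1), 2)
  aa <- network_spec(4, "all_to_all")
  expect_true(all(aa$adjacency[upper.tri(aa$adjacency)] == 1))
})

test_that("sparse Hamiltonian matches a dense Kronecker-product oracle", {
  for (sp in list(chain3(delta0 = 0.3, sigma_int = 1.2),
                  network_spec(4, "all_to_all", delta0 = 0.15,
                               sigma_int = 0.8),
                  network_spec(4, "custom", J = 0.7,
                               adjacency = matrix(c(0,1,0,1, 1,0,0,0,
                                                    0,0,0,1, 1,0,1,0),
                                                  4)))) {
    H <- as.matrix(build_hamiltonian(sp))
    Hk <- kron_hamiltonian(sp)
    expect_lt(max(Mod(H - Hk)), 1e-12)
  }
})

test_that("one-excitation spectra match closed forms", {
  H2 <- as.matrix(build_hamiltonian(network_spec(2, "nearest_neighbour")))
  expect_equal(sort(eigen(H2[2:3, 2:3])$values), c(-1, 1))
  sh <- sector_hamiltonian(network_spec(7, "all_to_all", delta0 = 0), 1)
  ev <- sort(eigen(as.matrix(sh$H))$values)
  expect_equal(ev, c(rep(-1, 6), 6), tolerance = 1e-12)
})

test_that("Hamiltonian is symmetric and conserves total magnetization", {
  sp <- network_spec(5, "all_to_all", delta0 = 0.2, sigma_int = 1)
  H <- build_hamiltonian(sp)
  expect_equal(max(abs(H - Matrix::t(H))), 0)
  zs <- numspin:::zsign_matrix(numspin:::full_basis(5), 5)
  Sz <- Matrix::Diagonal(32, x = colSums(zs))
  comm <- H %*% Sz - Sz %*% H
  expect_lt(max(abs(comm)), 1e-12)
})

test_that("all-to-all spectrum is invariant under site permutations", {
  sp <- network_spec(5, "all_to_all", delta0 = 0)
  H <- as.matrix(build_hamiltonian(sp))
  set.seed(7)
  perm <- sample(5)
  masks <- numspin:::full_basis(5)
  bm <- numspin:::bit_matrix(masks, 5)
  pmask <- as.integer(bm[, perm, drop = FALSE] %*% 2^(0:4))
  idx <- match(masks, pmask)
  expect_equal(sort(eigen(H[idx, idx], symmetric = TRUE)$values),
               sort(eigen(H, symmetric = TRUE)$values),
               tolerance = 1e-10)
})

test_that("up-down symmetry: N and M-N sector spectra coincide", {
  sp <- network_spec(8, "all_to_all", delta0 = 0)
  e3 <- eigen(as.matrix(sector_hamiltonian(sp, 3)$H),
              symmetric = TRUE, only.values = TRUE)$values
  e5 <- eigen(as.matrix(sector_hamiltonian(sp, 5)$H),
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(e3), sort(e5), tolerance = 1e-10)
})

test_that("jump operators follow the configured channels", {
  expect_length(build_jump_operators(chain3()), 0)
  j7 <- build_jump_operators(network_spec(7, "nearest_neighbour",
                                          gamma_loss = 0.1))
  expect_length(j7, 7)
  expect_true(all(vapply(j7, function(j) j$rate, 1) == 0.1))
  expect_true(all(vapply(j7, function(j) j$type, "") == "loss"))
  jd <- build_jump_operators(chain3(gamma_dephase = 0.2))
  expect_length(jd, 3)
  expect_true(all(vapply(jd, function(j) j$type, "") == "dephase"))
  # loss operator lowers exactly one excitation
  masks <- numspin:::full_basis(7)
  psi <- complex(128); psi[which(masks == 3L)] <- 1  # sites 1, 2 up
  lowered <- as.vector(j7[[1]]$op %*% Re(psi))
  expect_equal(which(lowered != 0), which(masks == 2L))
})

test_that("magnetization operators have the right diagonal action", {
  sp <- chain3()
  ops <- magnetization_operators(sp)
  all_down <- Re(unclass(pure_state(3)))
  expect_equal(vapply(ops, function(o) sum(all_down * (o %*% all_down)), 1),
               rep(-1, 3))
  up2 <- Re(unclass(pure_state(3, 2)))
  expect_equal(vapply(ops, function(o) sum(up2 * (o %*% up2)), 1),
               c(-1, 1, -1))
  # total magnetization on an N-up sector state is 2N - M
  up13 <- Re(unclass(pure_state(3, c(1, 3))))
  tot <- sum(vapply(ops, function(o) sum(up13 * (o %*% up13)), 1))
  expect_equal(tot, 2 * 2 - 3)
  expect_true(all(vapply(ops, function(o) all(abs(Matrix::diag(o)) == 1),
                         TRUE)))
})

test_that("network specs round-trip through JSON", {
  sp <- network_spec(4, "custom", J = 0.5, delta0 = 0.2, sigma_int = 1.5,
                     gamma_loss = 0.05,
                     adjacency = matrix(c(0,1,1,0, 1,0,0,0,
                                          1,0,0,1, 0,0,1,0), 4))
  sp2 <- spec_from_json(spec_to_json(sp))
  expect_equal(sp2, sp)
})
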