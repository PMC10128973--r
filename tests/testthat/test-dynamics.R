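test_that("stimulus rotations act as single-site x rotations", {
  s <- pure_state(3)
  expect_equal(unclass(apply_stimulus(s, stimulus_event(0, 2, 0))),
               unclass(s))                     # identity at theta = 0
  flipped <- apply_stimulus(s, stimulus_event(0, 2, pi))
  p <- Mod(unclass(flipped))^2
  expect_equal(sum(p), 1)
  zs <- numspin:::zsign_matrix(numspin:::full_basis(3), 3)
  expect_equal(as.vector(zs %*% p), c(-1, 1, -1))  # full flip
  half <- apply_stimulus(s, stimulus_event(0, 2, pi / 2))
  expect_equal(as.vector(zs %*% Mod(unclass(half))^2), c(-1, 0, -1),
               tolerance = 1e-12)              # cos(theta) law
  expect_error(apply_stimulus(s, stimulus_event(0, 2, 4)))
  expect_error(apply_stimulus(s, data.frame(time = 0, site = 9,
                                            angle = 1)), "range")
})

test_that("closed evolution conserves norm and total magnetization", {
  sp <- aa7(delta0 = 0.1)
  times <- seq(0, 6, by = 0.05)
  rec <- evolve_trajectory(sp, stimulus_event(0, 4, pi), times)
  expect_lt(max(abs(rec$norms - 1)), 1e-8)
  tot <- colSums(rec$mag)
  expect_lt(diff(range(tot)), 1e-8)            # excitation number conserved
  expect_true(all(abs(rec$mag) <= 1 + 1e-9))
})

test_that("all-to-all single flip oscillates at the collective gap J*M", {
  sp <- aa7(delta0 = 0)
  times <- seq(0, 4, by = 0.01)
  rec <- evolve_trajectory(sp, stimulus_event(0, 4, pi), times)
  z <- rec$mag[4, ]
  period <- 2 * pi / 7
  k <- which.min(abs(times - period))
  # the flipped site returns toward +1 after one period
  expect_gt(z[k], 0.9)
  # and non-stimulated sites carry identical traces (permutation symmetry)
  others <- rec$mag[-4, ]
  expect_lt(max(apply(others, 2, function(col) diff(range(col)))), 1e-9)
})

test_that("nearest-neighbour chain shows a light cone and revivals", {
  sp <- network_spec(7, "nearest_neighbour")
  times <- seq(0, 12, by = 0.05)
  rec <- evolve_trajectory(sp, stimulus_event(0, 4, pi), times)
  lc <- lightcone_check(rec, sp)
  expect_true(lc$monotone)
  expect_false(lc$degenerate)
  a <- lc$arrival
  expect_true(all(diff(a$arrival_time[order(a$distance)]) >= 0))
  expect_error(lightcone_check(rec, aa7()), "all-to-all")
  expect_true(lightcone_check(rec, sp, threshold = 0)$degenerate)
  # revival: after spreading away (z drops to ~-1), the excitation
  # partially returns to the origin site
  z <- rec$mag[4, ]
  spread <- min(z[times < 3])
  expect_lt(spread, -0.8)
  expect_gt(max(z[times > 3]), spread + 0.5)
})

test_that("sector evolution matches the full-space propagator", {
  sp <- aa7(delta0 = 0.1)
  times <- seq(0.5, 8, by = 0.25)
  full <- evolve_trajectory(sp, rbind(stimulus_event(0, 2, pi),
                                      stimulus_event(0, 5, pi)), times)
  sect <- sector_record(sp, c(2, 5), times)
  expect_equal(sect$mag, full$mag, tolerance = 1e-8)
  expect_error(sector_record(aa7(gamma_loss = 0.1), 1, times))
})

test_that("dense and Krylov closed propagators agree", {
  sp <- network_spec(6, "all_to_all", delta0 = 0.1)
  times <- seq(0, 8, by = 0.1)
  ev <- rbind(stimulus_event(0.5, 2, pi), stimulus_event(2.2, 5, 1.1),
              stimulus_event(3.7, 1, 2.4))
  r1 <- evolve_trajectory(sp, ev, times,
                          config = solver_config(method = "dense"))
  r2 <- evolve_trajectory(sp, ev, times,
                          config = solver_config(method = "krylov"))
  expect_lt(max(abs(r1$mag - r2$mag)), 1e-8)
})

test_that("master equation: closed limit and dissipative steady state", {
  sp3 <- chain3()
  tt <- seq(0, 5, by = 0.25)
  ev <- stimulus_event(0, 2, pi)
  rm <- evolve_master(sp3, ev, tt)
  rt <- evolve_trajectory(sp3, ev, tt)
  expect_lt(max(abs(rm$mag - rt$mag)), 1e-8)   # gamma = 0: pure-state limit
  # with loss, an initial excitation decays to the all-down state
  sp2 <- network_spec(2, "nearest_neighbour", gamma_loss = 0.5)
  rho0 <- matrix(0i, 4, 4); rho0[2, 2] <- 1 + 0i
  dec <- evolve_master(sp2, NULL, seq(0, 30, by = 5), rho0 = rho0)
  expect_equal(unname(dec$mag[, 7]), c(-1, -1), tolerance = 1e-5)
  n_exc <- colSums((dec$mag + 1) / 2)
  expect_true(all(diff(n_exc) < 0))            # monotone excitation loss
  expect_error(evolve_master(network_spec(9, "all_to_all"), NULL, 0:1),
               "capped")
})

test_that("trajectory average reproduces the master equation (small case)", {
  sp <- chain3(gamma_loss = 0.4)
  tt <- seq(0, 6, by = 1)
  ev <- stimulus_event(0, 2, pi)
  exact <- evolve_master(sp, ev, tt)$mag
  set.seed(42)
  n_traj <- 400
  acc <- 0; acc2 <- 0
  for (k in seq_len(n_traj)) {
    m <- evolve_trajectory(sp, ev, tt)$mag
    acc <- acc + m; acc2 <- acc2 + m^2
  }
  mbar <- acc / n_traj
  se <- sqrt(pmax(acc2 / n_traj - mbar^2, 0) / n_traj)
  z <- abs(mbar - exact) / pmax(se, 1e-9)
  z[se < 1e-8] <- 0
  expect_lt(max(z), 4.5)
  expect_lt(mean(abs(mbar - exact)), 0.03)
})

test_that("uniform damping reduces the magnetization signal", {
  tt <- seq(0, 8, by = 0.1)
  ev <- stimulus_event(0, 4, pi)
  closed <- evolve_master(network_spec(5, "nearest_neighbour"), ev, tt)
  set.seed(3)
  lossy <- evolve_master(network_spec(5, "nearest_neighbour",
                                      gamma_loss = 0.1), ev, tt)
  exc_c <- colSums(closed$mag + 1) / 2
  exc_l <- colSums(lossy$mag + 1) / 2
  expect_true(all(exc_l[-1] < exc_c[-1] + 1e-9))
  expect_lt(exc_l[length(tt)], 0.5)
})

test_that("dissipative trajectories are reproducible given a seed", {
  sp <- chain3(gamma_loss = 0.6)
  tt <- seq(0, 5, by = 0.5)
  ev <- stimulus_event(0, 1, pi)
  r1 <- evolve_trajectory(sp, ev, tt, config = solver_config(seed = 99))
  r2 <- evolve_trajectory(sp, ev, tt, config = solver_config(seed = 99))
  expect_identical(r1$mag, r2$mag)
  expect_identical(r1$n_jumps, r2$n_jumps)
})

test_that("event validation rejects malformed sequences", {
  sp <- chain3()
  tt <- seq(0, 1, by = 0.5)
  bad <- data.frame(time = c(2, 1), site = c(1, 2), angle = c(1, 1))
  expect_error(evolve_trajectory(sp, bad, tt), "sorted")
  expect_error(evolve_trajectory(sp, data.frame(time = 0, site = 5,
                                                angle = 1), tt), "range")
})
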