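single_morse_pair <- function(D = 100, a = 1, r_eq = 2, m = 10) {
  sys <- system_spec(list(entity("p", 1, masses = m),
                          entity("q", 2, masses = m)), d = 2)
  add_term(sys, c(1, 2), pot_morse(D, a, r_eq), lg_const(1))
}

test_that("a Morse pair at equilibrium with zero velocity stays put", {
  sys <- single_morse_pair()
  x0 <- rbind(c(0, 0), c(2, 0))
  tr <- run_verlet(sys, x0, dt = 0.002, n_steps = 500, stride = 50)
  expect_equal(frame_config(tr, n_frames(tr)), x0, tolerance = 1e-12)
})

test_that("small Morse oscillations match the harmonic-limit period", {
  D <- 100; a <- 1; m <- 10
  sys <- single_morse_pair(D, a, 2, m)
  tr <- run_verlet(sys, rbind(c(0, 0), c(2.05, 0)), dt = 0.001,
                   n_steps = 5000, stride = 1)
  r <- sqrt(rowSums((tr$positions[, 1, ] - tr$positions[, 2, ])^2))
  peaks <- which(diff(sign(diff(r))) < 0) + 1
  period <- mean(diff(tr$times[peaks]))
  mu <- m / 2
  expect_equal(period, 2 * pi / sqrt(2 * D * a^2 / mu), tolerance = 0.01)
})

test_that("velocity Verlet conserves energy and is time-reversible", {
  sys <- build_reaction(bias = 1)
  x0 <- reaction_scan_geometry(sys, 2, 6)
  set.seed(2)
  v0 <- matrix(rnorm(12, sd = sqrt(5 / 10)), 6, 2)
  tr <- run_verlet(sys, x0, v0, dt = sys$run_defaults$dt, n_steps = 2000,
                   stride = 10)
  E <- tr$E_pot + tr$E_kin
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
  # reverse: negate final velocities, integrate back, recover the start
  xe <- frame_config(tr, n_frames(tr))
  ve <- matrix(tr$velocities[n_frames(tr), , ], 6, 2)
  back <- run_verlet(sys, xe, -ve, dt = sys$run_defaults$dt, n_steps = 2000,
                     stride = 2000)
  expect_lt(max(abs(frame_config(back, n_frames(back)) - x0)), 1e-8)
})

test_that("Langevin runs are bitwise reproducible under a seed", {
  sys <- single_morse_pair()
  x0 <- rbind(c(0, 0), c(2.3, 0))
  t1 <- run_langevin(sys, x0, dt = 0.002, n_steps = 400, temperature = 5,
                     friction = 1, seed = 31, stride = 10)
  t2 <- run_langevin(sys, x0, dt = 0.002, n_steps = 400, temperature = 5,
                     friction = 1, seed = 31, stride = 10)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$velocities, t2$velocities)
  t3 <- run_langevin(sys, x0, dt = 0.002, n_steps = 400, temperature = 5,
                     friction = 1, seed = 32, stride = 10)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("the integrator reduces to Verlet in the deterministic limit", {
  # same BAOAB kernel with gamma = 0, kBT = 0 must reproduce Verlet exactly
  sys <- single_morse_pair()
  x0 <- rbind(c(0, 0), c(2.4, 0))
  v0 <- rbind(c(0.3, -0.1), c(-0.3, 0.1))
  tv <- run_verlet(sys, x0, v0, dt = 0.002, n_steps = 300, stride = 10)
  tl <- progpot:::run_engine(sys, x0, v0, dt = 0.002, n_steps = 300,
                             kBT = 0, gamma = 0, mode = "full", stride = 10,
                             integrator = "langevin-limit")
  expect_equal(tv$positions, tl$positions, tolerance = 1e-14)
})

test_that("free-particle velocities equilibrate to kT/m per component", {
  sys <- system_spec(list(entity("f", 1, masses = 10)), d = 2)
  tr <- run_langevin(sys, matrix(0, 1, 2), dt = 0.01, n_steps = 1.5e5,
                     temperature = 20, friction = 1, seed = 5, stride = 3)
  v <- tr$velocities[-(1:2000), 1, ]
  expect_equal(mean(v^2), 20 / 10, tolerance = 0.05)
})

test_that("a thermalized harmonic bond satisfies equipartition", {
  k <- 500; r0 <- 2; kT <- 5
  sys <- system_spec(list(entity("rod", 1:2, masses = 5,
                                 bonds = list(list(pair = c(1, 2), k = k,
                                                   r0 = r0)))), d = 2)
  tr <- run_langevin(sys, rbind(c(0, 0), c(r0, 0)), dt = 0.002,
                     n_steps = 4e5, temperature = kT, friction = 1, seed = 8,
                     stride = 5)
  r <- sqrt(rowSums((tr$positions[, 1, ] - tr$positions[, 2, ])^2))
  r <- r[-(1:5000)]
  # the bond length is one effective degree of freedom
  expect_equal(mean(0.5 * k * (r - r0)^2), 0.5 * kT, tolerance = 0.05 * kT)
})

test_that("a diverging step size aborts with a diagnostic", {
  sys <- system_spec(list(entity("p", 1, masses = 0.1),
                          entity("q", 2, masses = 0.1)), d = 2)
  sys <- add_term(sys, c(1, 2), pot_harmonic(1e6, 1), lg_const(1))
  expect_error(
    run_verlet(sys, rbind(c(0, 0), c(0.4, 0)), dt = 0.5, n_steps = 5000),
    "diverged")
})

test_that("trajectory accessors are shape-consistent", {
  sys <- build_inhibitor()
  tr <- run_fixture(sys, seed = 2, n_steps = 2000L, stride = 100L)
  expect_equal(n_frames(tr), 21)
  en <- trajectory_energies(tr)
  expect_equal(nrow(en), 21)
  expect_equal(en$E_total, tr$E_pot + tr$E_kin)
  tt <- trajectory_terms(tr)
  expect_equal(nrow(tt), 21 * 3)
  expect_true(all(tt$S >= 0 & tt$S <= 1))
  expect_true(all(diff(tr$times) > 0))
})
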