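# a hand-built trajectory with a scripted pair-distance history
scripted_trajectory <- function(r_series) {
  nf <- length(r_series)
  pos <- array(0, c(nf, 2, 2))
  pos[, 2, 1] <- r_series               # particle 2 moves along x
  sys <- system_spec(list(entity("p", 1), entity("q", 2)), d = 2)
  structure(list(
    times = seq_len(nf) - 1, positions = pos,
    velocities = array(0, c(nf, 2, 2)),
    E_pot = numeric(nf), E_kin = numeric(nf),
    S = matrix(numeric(0), nf, 0), r = matrix(numeric(0), nf, 0),
    phi = matrix(numeric(0), nf, 0),
    term_labels = character(0), term_pairs = list(),
    system = sys, params = list(integrator = "scripted", dt = 1,
                                mode = "full")),
    class = "pp_trajectory")
}

test_that("bond occupancy is the fraction of frames below the threshold", {
  tr <- scripted_trajectory(rep(2, 50))
  expect_equal(bond_occupancy(tr, c(1, 2), r_on = 2.4), 1)
  tr <- scripted_trajectory(rep(9, 50))
  expect_equal(bond_occupancy(tr, c(1, 2), r_on = 2.4), 0)
  tr <- scripted_trajectory(c(rep(2, 30), rep(9, 70)))
  expect_equal(bond_occupancy(tr, c(1, 2), r_on = 2.4), 0.3)
})

test_that("event detection debounces with two thresholds", {
  # approach, jitter around the on-threshold, retreat: exactly one
  # formed/broken pair despite the jitter
  r <- c(8, 6, 4, 2.3, 2.5, 2.2, 2.6, 2.1, 3, 5, 8)
  tr <- scripted_trajectory(r)
  ev <- event_sequence(tr, list(c(1, 2)), r_on = 2.4, r_off = 4.5)
  expect_equal(ev$kind, c("formed", "broken"))
  expect_equal(ev$frame, c(4, 10))
  # alternation is structural
  r2 <- rep(c(2, 8), 10)
  ev2 <- event_sequence(scripted_trajectory(r2), list(c(1, 2)),
                        r_on = 2.4, r_off = 4.5)
  expect_equal(ev2$kind, rep(c("formed", "broken"), length.out = nrow(ev2)))
  expect_error(event_sequence(tr, list(c(1, 2)), r_on = 3, r_off = 2),
               "r_off > r_on")
})

test_that("quasi-static approach work equals the dissociation energy", {
  sys <- build_reaction(bias = 1)
  x0 <- reaction_scan_geometry(sys, 2, 9.5)
  w <- dissociation_work(sys, x0, particle = 5, target = 2,
                         from = 9.5, to = 2)
  expect_equal(as.numeric(w), 100, tolerance = 0.02)
  # quadrature agrees with the closed-form energy difference
  expect_equal(as.numeric(w), attr(w, "delta_U"), tolerance = 1e-6)
})

test_that("without switching the approach does no net work", {
  # same geometry, but the bond carries an identity switch and there is no
  # competing term: dragging C in costs only the weak direct tail
  p <- progpot:::merge_params(list())
  ents <- list(
    entity("A", 1:2, masses = p$mass,
           bonds = list(list(pair = c(1, 2), k = p$rod_k, r0 = 2))),
    entity("B", 3:4, masses = p$mass,
           bonds = list(list(pair = c(3, 4), k = p$rod_k, r0 = 2))),
    entity("C", 5:6, masses = p$mass,
           bonds = list(list(pair = c(5, 6), k = p$rod_k, r0 = 2))))
  sys <- system_spec(ents, d = 2)
  sys <- add_term(sys, c(1, 3), pot_morse(100, 1, 2), lg_const(1))
  x0 <- reaction_scan_geometry(sys, 2, 9.5)
  w <- dissociation_work(sys, x0, particle = 5, target = 2,
                         from = 9.5, to = 2)
  expect_lt(abs(as.numeric(w)), 1)
})

test_that("dissociation work scales linearly with the bond depth", {
  x0 <- reaction_scan_geometry(build_reaction(1), 2, 9.5)
  w1 <- dissociation_work(build_reaction(1), x0, 5, 2, 9.5, 2)
  w2 <- dissociation_work(build_reaction(1, params = list(D = 200)), x0,
                          5, 2, 9.5, 2)
  expect_equal(as.numeric(w2) / as.numeric(w1), 2, tolerance = 1e-6)
})

test_that("dissociation work is independent of the approach direction", {
  sys <- build_reaction(bias = 1)
  x0 <- reaction_scan_geometry(sys, 2, 9.5)
  w_x <- dissociation_work(sys, x0, 5, 2, 9.5, 2)
  # approach from above instead: rotate C's start around atom 2
  x1 <- x0
  x1[5, ] <- x0[2, ] + c(0, 9.5)
  x1[6, ] <- x1[5, ] + c(0, 2)
  w_y <- dissociation_work(sys, x1, 5, 2, 9.5, 2)
  expect_equal(as.numeric(w_x), as.numeric(w_y), tolerance = 1e-4)
})

test_that("energy surface: bias deepens the product well about twofold", {
  g <- seq(1.4, 6, length.out = 40)
  sys2 <- build_reaction(bias = 2)
  s <- energy_surface(sys2, reaction_scan_geometry(sys2), c(1, 3), c(2, 5),
                      move = c(3, 5), g, g)
  # AB well: r13 near r_eq, C far; AC well: r25 near r_eq, B far
  ab_well <- min(s$U[, length(g)])
  ac_well <- min(s$U[length(g), ])
  expect_equal(ac_well / ab_well, 2, tolerance = 0.1)
  expect_error(energy_surface(sys2, reaction_scan_geometry(sys2), c(1, 3),
                              c(2, 5), move = c(3, 5), c(0, 2), g),
               "positive")
})

test_that("a permanently-off switch contributes nothing to the surface", {
  sys <- system_spec(list(entity("A", 1:2, masses = 1,
                                 bonds = list(list(pair = c(1, 2), k = 100,
                                                   r0 = 2))),
                          entity("B", 3:4, masses = 1),
                          entity("C", 5:6, masses = 1)), d = 2)
  sys <- add_term(sys, c(1, 3), pot_morse(50, 1, 2), lg_const(0))
  sys <- add_term(sys, c(2, 5), pot_morse(50, 1, 2), lg_const(0))
  g <- seq(1.5, 5, length.out = 12)
  s <- energy_surface(sys, reaction_scan_geometry(sys), c(1, 3), c(2, 5),
                      move = c(3, 5), g, g)
  expect_equal(max(abs(s$U - s$U[1, 1])), 0, tolerance = 1e-12)
})
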