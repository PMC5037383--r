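test_that("every fixture passes rule validation on every term", {
  fixtures <- list(build_signaling(), build_inhibitor(),
                   build_reaction(bias = 1), build_reaction(bias = 2),
                   build_dna())
  for (sys in fixtures) {
    for (tm in sys$terms) {
      expect_true(validate_logic(tm$logic, tm$pair)$ok,
                  label = paste("rule of term", tm$label, "in", sys$fixture))
    }
  }
})

test_that("signaling switch follows the arrival of the signaling site", {
  sys <- build_signaling()
  x <- matrix(0, 6, 2)
  x[1, ] <- c(-2, 0); x[2, ] <- c(0, 0)   # A
  x[3, ] <- c(2, 0);  x[4, ] <- c(4, 0)   # B bonded to A at r_eq
  x[5, ] <- c(0, 20); x[6, ] <- c(2, 20)  # C far
  en <- total_energy(sys, x)
  expect_gt(en$terms$S[1], 0.99)          # AB on while C is far
  x[5, ] <- c(0, 0.5); x[6, ] <- c(2, 0.5)
  en <- total_energy(sys, x)
  expect_lt(en$terms$S[1], 0.01)          # AB off when C arrives
  expect_equal(effective_dimension(sys)$reduced, 2 * 3)
})

test_that("inhibitor switch states realize the bond-logic table", {
  sys <- build_inhibitor()
  base <- function() {
    x <- matrix(0, 6, 2)
    x[1, ] <- c(-2, 0);  x[2, ] <- c(0, 0)
    x[3, ] <- c(15, 0);  x[4, ] <- c(17, 0)
    x[5, ] <- c(0, 15);  x[6, ] <- c(-2, 15)
    x
  }
  S_of <- function(x) {
    en <- total_energy(sys, x)
    setNames(en$terms$S, en$terms$label)
  }
  # all far apart: every switch on (> 3 alpha at n >= 4)
  S <- S_of(base())
  expect_true(all(S > 0.99))
  # inhibitor takes the receptor: (2,5) close
  x <- base(); x[5, ] <- c(0.5, 0); x[6, ] <- c(2.5, 0)
  S <- S_of(x)
  expect_lt(S["AB"], 0.01)
  expect_lt(S["BC"], 0.01)
  expect_gt(S["AC"], 0.99)
  # inhibitor takes the substrate: (3,6) close
  x <- base(); x[6, ] <- c(15.5, 0); x[5, ] <- c(13.5, 0)
  S <- S_of(x)
  expect_lt(S["AB"], 0.01)
  expect_lt(S["AC"], 0.01)
  expect_gt(S["BC"], 0.99)
})

test_that("reaction switch table: stable bond and repulsion are complementary", {
  sys <- build_reaction(bias = 1)
  S_at <- function(r13, r25) {
    en <- total_energy(sys, reaction_scan_geometry(sys, r13, r25))
    setNames(en$terms$S, en$terms$label)
  }
  # C far: AB stable bond on, AB repulsion off
  S <- S_at(2, 9)
  expect_gt(S["AB_bond"], 0.99); expect_lt(S["AB_rep"], 0.01)
  # r(1,3) = 2 < R_off: AC bond off, AC repulsion on
  expect_lt(S["AC_bond"], 0.01); expect_gt(S["AC_rep"], 0.99)
  # C inside the switch radius: AB bond off, AB repulsion on
  S <- S_at(9, 2)
  expect_lt(S["AB_bond"], 0.01); expect_gt(S["AB_rep"], 0.99)
  expect_gt(S["AC_bond"], 0.99); expect_lt(S["AC_rep"], 0.01)
  expect_equal(multiplicity(sys, c(1, 3)), 2)
  expect_equal(multiplicity(sys, c(2, 5)), 2)
  expect_error(build_reaction(bias = -1), "positive")
})

test_that("matched parameters make the unbiased reaction surface symmetric", {
  sys <- build_reaction(bias = 1)
  g <- seq(1.4, 5.5, length.out = 25)
  s <- energy_surface(sys, reaction_scan_geometry(sys), c(1, 3), c(2, 5),
                      move = c(3, 5), g, g)
  expect_lt(max(abs(s$U - t(s$U))), 1e-10)
})

test_that("DNA logic walks through the designed milestones", {
  sys <- build_dna()
  L <- function(x) {
    v <- vapply(sys$terms, function(tm) logic_eval(tm$logic, x), 0)
    setNames(v, vapply(sys$terms, `[[`, "", "label"))
  }
  # polymerase absent: nothing downstream may bind
  v <- L(dna_stage_config("apart"))
  expect_equal(unname(v[c("AU", "CG", "TA", "GC", "bb1", "bb2", "bb3")]),
               rep(0, 7))
  expect_equal(unname(v[c("pol1", "pol2")]), c(1, 1))
  # polymerase docked: only the first base pair is enabled
  v <- L(dna_stage_config("docked"))
  expect_equal(unname(v["AU"]), 1)
  expect_equal(unname(v[c("CG", "TA", "GC", "bb1", "bb2", "bb3")]), rep(0, 6))
  # A-U formed: the next base pair is enabled, later ones still vetoed
  v <- L(dna_stage_config("AU"))
  expect_equal(unname(v["CG"]), 1)
  expect_equal(unname(v["TA"]), 0)
  # A-U and C-G formed: the first backbone link opens
  v <- L(dna_stage_config("AUCG"))
  expect_equal(unname(v["bb1"]), 1)
  expect_equal(unname(v[c("TA", "GC", "bb3")]), rep(0, 3))
  # complete and attached: base pairs and polymerase switch off,
  # backbone links stay on
  v <- L(dna_stage_config("complete"))
  expect_equal(unname(v[c("AU", "CG", "TA", "GC", "pol1", "pol2")]), rep(0, 6))
  expect_equal(unname(v[c("bb1", "bb2", "bb3")]), rep(1, 3))
})

test_that("initial placement is deterministic, separated, and honors preformed pairs", {
  sys <- build_inhibitor()
  x1 <- random_initial_config(sys, seed = 9)
  x2 <- random_initial_config(sys, seed = 9)
  expect_identical(x1, x2)
  expect_false(identical(x1, random_initial_config(sys, seed = 10)))
  # the AB complex is pre-formed at the Morse equilibrium distance
  expect_equal(pair_distance(x1, 2, 3), 2, tolerance = 1e-12)
  # non-preformed entities keep their distance
  for (i in 1:4) for (j in 5:6) {
    expect_gte(pair_distance(x1, i, j), sys$start$min_sep)
  }
  expect_error(
    random_initial_config(sys, box = 0.5, min_sep = 50, seed = 1),
    "enlarge the box")
})

test_that("fixture systems expose run defaults and round-trip run_fixture", {
  sys <- build_signaling()
  tr <- run_fixture(sys, seed = 4, n_steps = 1000L, stride = 100L)
  expect_s3_class(tr, "pp_trajectory")
  expect_equal(n_frames(tr), 11)
})
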