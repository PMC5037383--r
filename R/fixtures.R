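# Worked example systems: signaling switch, inhibitor mechanism,
# bond-breaking reaction, DNA-transcription model.  All use the reduced unit
# preset (k_B = 1); lengths are in the same unit as the Morse r_eq.

fixture_defaults <- list(
  D = 100,        # Morse dissociation energy (energy units)
  a = 1,          # Morse width (1/length)
  r_eq = 2,       # Morse equilibrium distance (length units)
  R = 3,          # "close" proximity threshold (length units)
  n = 6L,         # smoothing sharpness
  mass = 10,      # per-site mass
  rod_k = 12500,  # constraint-bond stiffness: <2% length fluctuation at kT=20
  rod_r0 = 2,     # constraint-bond rest length
  dt = 0.002,     # integrator step (time units)
  temperature = 20,  # k_B T in energy units (reduced preset)
  friction = 0.5,    # Langevin gamma (1/time)
  conf_k = 50        # confinement stiffness
)

rod_entity <- function(name, ids, p, length = p$rod_r0) {
  entity(name, ids, masses = p$mass,
         bonds = list(list(pair = ids, k = p$rod_k, r0 = length)))
}

merge_params <- function(params) {
  p <- modifyList(fixture_defaults, params)
  stopifnot(p$D > 0, p$a > 0, p$r_eq > 0, p$R > 0, p$n >= 1)
  p
}

set_fixture_meta <- function(sys, name, run, start, ref) {
  sys$fixture <- name
  sys$run_defaults <- run
  sys$start <- start
  sys$ref_geometry <- ref
  sys
}

#' The inhibitor-mechanism logic functions
#'
#' The three switching rules of the inhibitor system over the two
#' elementary conditions "2 and 5 close" and "3 and 6 close": the
#' receptor--substrate bond (2,3) is off when either inhibitor bond is
#' formed, and each inhibitor bond excludes the other.
#'
#' @param R25,R36 Proximity thresholds for the two conditions.
#' @return A list with `exprs` (named rules `L23`, `L25`, `L36`) and
#'   `conditions` (named predicates `c25`, `c36`), ready for
#'   [truth_table()].
#' @export
inhibitor_logic <- function(R25 = 3, R36 = 3) {
  c25 <- lg_near(2, 5, R25)
  c36 <- lg_near(3, 6, R36)
  list(
    exprs = list(
      L23 = lg_not(lg_or(c25, c36)),
      L36 = lg_not(c25),
      L25 = lg_not(c36)),
    conditions = list(c25 = c25, c36 = c36))
}

#' Build the signaling-switch example
#'
#' Three two-site rods A(1,2), B(3,4), C(5,6) with a single switched bond:
#' the (2,3) potential is on exactly while the signaling site 5 is far from
#' site 2, so the arrival of C dissolves the AB complex.
#'
#' @param params Named list of overrides for the fixture defaults
#'   (`D`, `a`, `r_eq`, `R`, `n`, `mass`, `rod_k`, `rod_r0`, `dt`,
#'   `temperature`, `friction`, `conf_radius`, ...).
#' @return A `pp_system` with fixture metadata (`run_defaults`, `start`).
#' @export
build_signaling <- function(params = list()) {
  p <- merge_params(params)
  conf_radius <- if (is.null(p$conf_radius)) 6 else p$conf_radius
  ents <- list(rod_entity("A", c(1, 2), p), rod_entity("B", c(3, 4), p),
               rod_entity("C", c(5, 6), p))
  sys <- system_spec(ents, d = 2,
                     confinement = list(k = p$conf_k, radius = conf_radius))
  sys <- add_term(sys, c(2, 3), pot_morse(p$D, p$a, p$r_eq),
                  lg_not(lg_near(2, 5, p$R)), n = p$n, label = "AB")
  set_fixture_meta(sys, "signaling",
    run = list(dt = p$dt, temperature = p$temperature, friction = p$friction,
               mode = "frozen_switch", n_steps = 2e5L, stride = 100L),
    start = list(min_sep = 3, preformed = list(list(pair = c(2, 3), r = p$r_eq))),
    ref = default_ref_geometry(ents, p))
}

#' Build the inhibitor-mechanism example
#'
#' Three two-site rods in the plane: receptor A(1,2), active molecule
#' B(3,4), inhibitor C(5,6).  Morse bonds on pairs (2,3), (2,5), (3,6), each
#' switched by the inhibitor logic (see [inhibitor_logic()]); all pair
#' multiplicities are 1.  The effective dimension is 8 (four unique
#' particles in the pair set) against a 12-dimensional configuration space.
#'
#' @inheritParams build_signaling
#' @return A `pp_system` with fixture metadata.
#' @export
build_inhibitor <- function(params = list()) {
  p <- merge_params(params)
  R25 <- if (is.null(p$R25)) p$R else p$R25
  R36 <- if (is.null(p$R36)) p$R else p$R36
  conf_radius <- if (is.null(p$conf_radius)) 6 else p$conf_radius
  lg <- inhibitor_logic(R25, R36)
  ents <- list(rod_entity("A", c(1, 2), p), rod_entity("B", c(3, 4), p),
               rod_entity("C", c(5, 6), p))
  sys <- system_spec(ents, d = 2,
                     confinement = list(k = p$conf_k, radius = conf_radius))
  mp <- pot_morse(p$D, p$a, p$r_eq)
  sys <- add_term(sys, c(2, 3), mp, lg$exprs$L23, n = p$n, label = "AB")
  sys <- add_term(sys, c(2, 5), mp, lg$exprs$L25, n = p$n, label = "AC")
  sys <- add_term(sys, c(3, 6), mp, lg$exprs$L36, n = p$n, label = "BC")
  set_fixture_meta(sys, "inhibitor",
    run = list(dt = p$dt, temperature = p$temperature, friction = p$friction,
               mode = "frozen_switch", n_steps = 5e5L, stride = 100L),
    start = list(min_sep = 3, preformed = list(list(pair = c(2, 3), r = p$r_eq))),
    ref = default_ref_geometry(ents, p))
}

#' Build the bond-breaking reaction example
#'
#' Models the reversible exchange AB + C <-> AC + B with pair multiplicity 2:
#' each of the bonds (1,3) (the AB bond) and (2,5) (the AC bond) carries a
#' stable Morse term switched off when the competing partner comes within
#' the switch-off radius, plus a transition-state electron-repulsion term
#' (the repulsive Morse branch with the same parameters) switched on in
#' exactly the complementary condition.  The switch-off radii default to 1.5
#' times the partner bond's equilibrium distance, so a bond turns off before
#' the incoming molecule reaches its own equilibrium separation.  The `bias`
#' parameter sets D_AC / D_AB; `bias = 1` gives a perfectly symmetric
#' exchange, `bias = 2` makes AC twice as stable as AB.  This fixture runs
#' with full (exact-gradient) forces: the encoding-function gradients are
#' the mechanism by which the incoming molecule must supply the dissociation
#' energy of the bond it breaks.
#'
#' @param bias Well-depth ratio D_AC / D_AB, `> 0`.
#' @inheritParams build_signaling
#' @return A `pp_system` with fixture metadata.
#' @export
build_reaction <- function(bias = 1, params = list()) {
  if (!(length(bias) == 1 && is.finite(bias) && bias > 0)) {
    stop("build_reaction(): bias = D_AC/D_AB must be a positive number",
         call. = FALSE)
  }
  p <- merge_params(params)
  D_AB <- p$D
  D_AC <- bias * D_AB
  R_off13 <- if (is.null(p$R_off13)) 1.5 * p$r_eq else p$R_off13  # AC partner r_eq
  R_off25 <- if (is.null(p$R_off25)) 1.5 * p$r_eq else p$R_off25
  conf_radius <- if (is.null(p$conf_radius)) 6 else p$conf_radius
  ents <- list(rod_entity("A", c(1, 2), p), rod_entity("B", c(3, 4), p),
               rod_entity("C", c(5, 6), p))
  sys <- system_spec(ents, d = 2,
                     confinement = list(k = p$conf_k, radius = conf_radius))
  mAB <- pot_morse(D_AB, p$a, p$r_eq)
  mAC <- pot_morse(D_AC, p$a, p$r_eq)
  sys <- add_term(sys, c(1, 3), mAB, lg_not(lg_near(2, 5, R_off13)),
                  n = p$n, label = "AB_bond")
  sys <- add_term(sys, c(1, 3), repulsive_part(mAB), lg_near(2, 5, R_off13),
                  n = p$n, label = "AB_rep")
  sys <- add_term(sys, c(2, 5), mAC, lg_not(lg_near(1, 3, R_off25)),
                  n = p$n, label = "AC_bond")
  sys <- add_term(sys, c(2, 5), repulsive_part(mAC), lg_near(1, 3, R_off25),
                  n = p$n, label = "AC_rep")
  set_fixture_meta(sys, "reaction",
    run = list(dt = p$dt / 2, temperature = p$temperature, friction = p$friction,
               mode = "full", n_steps = 2e6L, stride = 400L),
    start = list(min_sep = 3, preformed = list(list(pair = c(1, 3), r = p$r_eq))),
    ref = default_ref_geometry(ents, p))
}

#' Build the DNA-transcription example
#'
#' A rule-programmed model of transcription initiation on a four-base
#' template.  Particles: template strand with promoter sites (1,2) and bases
#' A=5, C=6, T=7, G=8; RNA polymerase rod (3,4); and four free nucleotides,
#' each a base--sugar--phosphate chain: U=(9,10,11), G=(12,13,14),
#' A=(15,16,17), C=(18,19,20).  Switched Morse bonds: polymerase--promoter
#' (1,3) and (2,4); base pairs (5,9), (6,12), (7,15), (8,18); backbone
#' sugar--phosphate links (11,13), (14,16), (17,19).
#'
#' The rules gate the bonds so that transcription proceeds strictly in
#' order: nothing binds before the polymerase docks on the promoter; each
#' base pair requires all previous base pairs (and the backbone links
#' between them) to be formed and the backbone not yet complete; each
#' backbone link requires the flanking base pairs; and once the
#' complementary strand is complete, the base pairs and the
#' polymerase--promoter bonds switch off (so polymerase and transcript
#' release) while the backbone links persist (so the transcript holds
#' together).  The polymerase-docked predicate is
#' `near(1,3) AND near(2,4)`; "backbone complete" is the conjunction of the
#' three backbone proximity predicates, always excluding a rule's own pair;
#' the final backbone link additionally requires the polymerase to have
#' released before its persistence clause applies, which preserves the
#' designed binding order.
#'
#' @inheritParams build_signaling
#' @return A `pp_system` with fixture metadata.
#' @export
build_dna <- function(params = list()) {
  p <- merge_params(params)
  # bond-formed predicates: in this fixture every rule condition means "that
  # bond has actually formed", so the proximity radius sits just above the
  # bond length and the transition is sharp; the Morse wells are narrowed
  # (a = 2) so a formed bond fluctuates well inside its predicate.
  R <- if (is.null(params$R)) 2.4 else p$R
  a <- if (is.null(params$a)) 2 else p$a
  n <- if (is.null(params$n)) 8L else p$n
  # deep wells: a formed bond must persist over the whole cascade; bonds are
  # released by their switches turning off, never by thermal escape
  D <- if (is.null(params$D)) 200 else p$D
  p$a <- a; p$n <- n; p$D <- D
  conf_radius <- if (is.null(p$conf_radius)) 8 else p$conf_radius
  chain_bonds <- function(ids, r0) {
    lapply(seq_len(length(ids) - 1L), function(k) {
      list(pair = c(ids[k], ids[k + 1]), k = p$rod_k, r0 = r0)
    })
  }
  template <- entity("template", c(1, 2, 5, 6, 7, 8), masses = p$mass,
                     bonds = chain_bonds(c(1, 2, 5, 6, 7, 8), p$rod_r0))
  pol <- rod_entity("polymerase", c(3, 4), p)
  nucs <- list(
    entity("U", c(9, 10, 11), masses = p$mass, bonds = chain_bonds(c(9, 10, 11), 1)),
    entity("G", c(12, 13, 14), masses = p$mass, bonds = chain_bonds(c(12, 13, 14), 1)),
    entity("A", c(15, 16, 17), masses = p$mass, bonds = chain_bonds(c(15, 16, 17), 1)),
    entity("C", c(18, 19, 20), masses = p$mass, bonds = chain_bonds(c(18, 19, 20), 1)))
  ents <- c(list(template, pol), nucs)
  sys <- system_spec(ents, d = 2,
                     confinement = list(k = p$conf_k, radius = conf_radius))

  # elementary predicates.  The polymerase-docked predicate gets a generous
  # radius: it asks "is the polymerase on station", and a docked polymerase
  # bond fluctuating around its equilibrium length must read as docked with
  # certainty, else its complement leaks into the persistence guards.
  R_pol <- if (is.null(params$R_pol)) 3 else params$R_pol
  pr1 <- lg_near(1, 3, R_pol); pr2 <- lg_near(2, 4, R_pol)
  Pr <- lg_and(pr1, pr2)                       # polymerase docked
  bAU <- lg_near(5, 9, R);  bCG <- lg_near(6, 12, R)
  bTA <- lg_near(7, 15, R); bGC <- lg_near(8, 18, R)
  k1 <- lg_near(11, 13, R); k2 <- lg_near(14, 16, R); k3 <- lg_near(17, 19, R)
  backbone <- lg_and(k1, k2, k3)
  attached <- lg_or(bAU, bCG, bTA, bGC)

  mp <- pot_morse(p$D, p$a, p$r_eq)

  # polymerase--promoter: on except when the transcript is complete and
  # still attached.  (Neither rule may mention its own pair: Pr is not used.)
  L_pol <- lg_not(lg_and(backbone, attached))
  sys <- add_term(sys, c(1, 3), mp, L_pol, n = p$n, label = "pol1")
  sys <- add_term(sys, c(2, 4), mp, L_pol, n = p$n, label = "pol2")

  # base pairs, strictly sequential, all vetoed once the backbone completes
  sys <- add_term(sys, c(5, 9), mp,
                  lg_and(Pr, lg_not(backbone)), n = p$n, label = "AU")
  sys <- add_term(sys, c(6, 12), mp,
                  lg_and(Pr, bAU, lg_not(backbone)), n = p$n, label = "CG")
  sys <- add_term(sys, c(7, 15), mp,
                  lg_and(Pr, bAU, bCG, k1, lg_not(backbone)), n = p$n, label = "TA")
  sys <- add_term(sys, c(8, 18), mp,
                  lg_and(Pr, bAU, bCG, bTA, k1, k2, lg_not(backbone)),
                  n = p$n, label = "GC")

  # backbone links: enabled by the flanking base pairs; persistent once the
  # rest of the backbone holds AND the transcript has detached (polymerase
  # released, base pairs broken).  The detached-state guard is essential: a
  # bare backbone conjunction can be triggered mid-transcription by a
  # transient sugar--phosphate contact, scrambling the designed order (see
  # the methods vignette).  Own pairs are excluded throughout.
  detached <- lg_and(lg_not(Pr), lg_not(attached))
  sys <- add_term(sys, c(11, 13), mp,
                  lg_or(lg_and(Pr, bAU, bCG), lg_and(k2, k3, detached)),
                  n = p$n, label = "bb1")
  sys <- add_term(sys, c(14, 16), mp,
                  lg_or(lg_and(Pr, bAU, bCG, bTA, k1), lg_and(k1, k3, detached)),
                  n = p$n, label = "bb2")
  sys <- add_term(sys, c(17, 19), mp,
                  lg_or(lg_and(Pr, bAU, bCG, bTA, bGC, k1, k2),
                        lg_and(k1, k2, detached)),
                  n = p$n, label = "bb3")

  set_fixture_meta(sys, "dna",
    run = list(dt = p$dt, temperature = p$temperature, friction = 2,
               mode = "frozen_switch", n_steps = 1e6L, stride = 50L),
    start = list(min_sep = 3.5, anchor_first = TRUE,
                 preformed = list(list(pair = c(1, 3), r = 3))),
    ref = default_ref_geometry(ents, p))
}

# rest-geometry template per entity: chain ids laid out along x with the
# rest lengths of consecutive internal bonds (used for initial placement)
default_ref_geometry <- function(entities, p) {
  lapply(entities, function(e) {
    k <- length(e$ids)
    xs <- numeric(k)
    if (k > 1) {
      for (m in 2:k) {
        r0 <- p$rod_r0
        for (b in e$bonds) {
          bp <- canonical_pair(b$pair[1], b$pair[2])
          cp <- canonical_pair(e$ids[m - 1], e$ids[m])
          if (all(bp == cp)) r0 <- b$r0
        }
        xs[m] <- xs[m - 1] + r0
      }
    }
    ref <- matrix(0, k, 2)
    ref[, 1] <- xs - mean(xs)
    rownames(ref) <- e$ids
    ref
  })
}

rotation_2d <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Random initial configuration for a fixture system
#'
#' Places every entity with its internal bonds at rest length (chain laid
#' out straight), a uniformly random orientation and a center drawn
#' uniformly in a box, rejection-sampling until all inter-entity site
#' distances exceed `min_sep`.  Pairs listed in `preformed` are then brought
#' to a prescribed separation (e.g. "the AB complex is formed at t = 0") by
#' translating the second entity.  Deterministic under `seed`.
#'
#' @param system A fixture `pp_system` (needs the stored reference
#'   geometry; any system built by a `build_*()` function qualifies).
#' @param box Half-width of the square placement box; defaults to the
#'   confinement radius minus 1 (or 8 without confinement).
#' @param min_sep Minimum allowed distance between sites of different
#'   entities.
#' @param seed Integer seed.
#' @param preformed List of `list(pair = c(i, j), r = distance)` to impose
#'   after placement; defaults to the fixture's own start specification.
#' @param max_attempts Rejection-sampling budget per entity.
#' @return An `N x d` configuration matrix.
#' @export
random_initial_config <- function(system, box = NULL, min_sep = 2.5, seed,
                                  preformed = NULL, max_attempts = 2000L) {
  stopifnot(is_system(system))
  if (is.null(system$ref_geometry)) {
    stop("random_initial_config(): system carries no reference geometry; ",
         "use a fixture built by build_*()", call. = FALSE)
  }
  if (system$d != 2) stop("placement is implemented for d = 2 fixtures", call. = FALSE)
  if (is.null(box)) {
    box <- if (!is.null(system$confinement)) system$confinement$radius - 1 else 8
  }
  if (is.null(preformed)) {
    preformed <- if (!is.null(system$start)) system$start$preformed else list()
  }
  set.seed(as.integer(seed))
  anchor_first <- isTRUE(system$start$anchor_first)
  x <- matrix(NA_real_, system$n_particles, system$d)
  placed_ids <- integer(0)
  for (k in seq_along(system$entities)) {
    e <- system$entities[[k]]
    ref <- system$ref_geometry[[k]]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      rot <- rotation_2d(runif(1, 0, 2 * pi))
      center <- if (k == 1 && anchor_first) c(0, 0) else runif(2, -box, box)
      cand <- sweep(ref %*% t(rot), 2, center, `+`)
      if (length(placed_ids) == 0 ||
          min_cross_dist(cand, x[placed_ids, , drop = FALSE]) >= min_sep) {
        x[e$ids, ] <- cand
        placed_ids <- c(placed_ids, e$ids)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("random_initial_config(): could not place entity '", e$name,
           "' at min_sep = ", min_sep, " after ", max_attempts,
           " attempts; enlarge the box", call. = FALSE)
    }
  }
  # impose pre-formed pairs by translating the entity of the second
  # particle; the translated entity must stay clear of every entity not
  # involved in the pair
  for (pf in preformed) {
    i <- pf$pair[1]; j <- pf$pair[2]
    ent_i <- which(vapply(system$entities, function(e) i %in% e$ids, TRUE))
    ent_j <- which(vapply(system$entities, function(e) j %in% e$ids, TRUE))
    ids <- system$entities[[ent_j]]$ids
    other_ids <- setdiff(seq_len(system$n_particles),
                         c(ids, system$entities[[ent_i]]$ids))
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      theta <- runif(1, 0, 2 * pi)
      shift <- (x[i, ] + pf$r * c(cos(theta), sin(theta))) - x[j, ]
      cand <- sweep(x[ids, , drop = FALSE], 2, shift, `+`)
      if (length(other_ids) == 0 ||
          min_cross_dist(cand, x[other_ids, , drop = FALSE]) >= min_sep) {
        x[ids, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("random_initial_config(): could not realize the pre-formed pair (",
           i, ",", j, ") at min_sep = ", min_sep, "; enlarge the box",
           call. = FALSE)
    }
  }
  x
}

min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

#' Run a fixture with its stored defaults
#'
#' Convenience wrapper: draws the fixture's initial configuration (with its
#' pre-formed pairs) and integrates with the fixture's stored integrator
#' defaults, all from one seed.
#'
#' @param system A fixture `pp_system` (from a `build_*()` function).
#' @param seed Integer seed for placement and dynamics.
#' @param n_steps,stride Optional overrides of the stored defaults.
#' @return A `pp_trajectory`.
#' @export
run_fixture <- function(system, seed, n_steps = NULL, stride = NULL) {
  stopifnot(is_system(system), !is.null(system$run_defaults))
  rd <- system$run_defaults
  if (!is.null(n_steps)) rd$n_steps <- n_steps
  if (!is.null(stride)) rd$stride <- stride
  x0 <- random_initial_config(system, min_sep = system$start$min_sep,
                              seed = seed)
  run_langevin(system, x0, dt = rd$dt, n_steps = rd$n_steps,
               temperature = rd$temperature, friction = rd$friction,
               seed = seed + 1L, mode = rd$mode, stride = rd$stride)
}
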