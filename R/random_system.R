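# Randomized switched systems, used by the gradient/energy audits.

#' Generate a random switched system for validation audits
#'
#' Draws a small system with random entities (1--2 site chains with harmonic
#' constraint bonds), random pairwise potentials (Morse, repulsive Morse
#' branch, or harmonic) on random cross-entity pairs -- occasionally two
#' terms on the same pair, exercising non-unit multiplicity -- and random
#' switching rules (expression trees of proximity predicates over other
#' pairs, random thresholds and sharpness).  Used by the finite-difference
#' force audit and the independent energy-oracle tests.
#'
#' @param seed Integer seed (the generator is deterministic given it).
#' @param d Spatial dimension.
#' @return A `pp_system`.
#' @export
random_system <- function(seed, d = 2) {
  set.seed(as.integer(seed))
  n_ent <- sample(2:4, 1)
  ents <- list()
  next_id <- 1L
  for (k in seq_len(n_ent)) {
    sz <- sample(1:2, 1)
    ids <- seq.int(next_id, length.out = sz)
    next_id <- next_id + sz
    bonds <- if (sz == 2) {
      list(list(pair = ids, k = runif(1, 50, 500), r0 = runif(1, 1, 2)))
    } else list()
    ents[[k]] <- entity(paste0("E", k), ids, masses = runif(sz, 1, 10),
                        bonds = bonds)
  }
  conf <- if (runif(1) < 0.3) {
    list(k = runif(1, 10, 100), radius = runif(1, 5, 10))
  } else NULL
  sys <- system_spec(ents, d = d, confinement = conf)

  ent_of <- integer(sys$n_particles)
  for (k in seq_along(ents)) ent_of[ents[[k]]$ids] <- k
  all_pairs <- utils::combn(sys$n_particles, 2)
  cross <- all_pairs[, ent_of[all_pairs[1, ]] != ent_of[all_pairs[2, ]], drop = FALSE]

  rand_pot <- function() {
    switch(sample(3, 1),
      pot_morse(runif(1, 1, 50), runif(1, 0.5, 2), runif(1, 1, 3)),
      pot_repulsive_morse(runif(1, 1, 50), runif(1, 0.5, 2), runif(1, 1, 3)),
      pot_harmonic(runif(1, 5, 100), runif(1, 1, 3)))
  }
  rand_logic <- function(own, depth) {
    roll <- runif(1)
    if (depth <= 0 || roll < 0.45) {
      usable <- which(cross[1, ] != own[1] | cross[2, ] != own[2])
      if (length(usable) == 0) return(lg_const(sample(0:1, 1)))
      p <- cross[, usable[sample(length(usable), 1)]]
      return(lg_near(p[1], p[2], runif(1, 1, 5)))
    }
    if (roll < 0.55) return(lg_const(sample(0:1, 1)))
    if (roll < 0.70) return(lg_not(rand_logic(own, depth - 1)))
    kids <- lapply(seq_len(sample(2:3, 1)), function(i) rand_logic(own, depth - 1))
    if (roll < 0.85) do.call(lg_and, kids) else do.call(lg_or, kids)
  }

  n_terms <- sample(1:4, 1)
  pick <- cross[, sample(ncol(cross), n_terms, replace = TRUE), drop = FALSE]
  for (t in seq_len(n_terms)) {
    own <- pick[, t]
    sys <- add_term(sys, own, rand_pot(), rand_logic(own, 3),
                    n = sample(2:8, 1))
  }
  sys
}

#' Random configuration for a system
#'
#' Positions drawn uniformly in a cube of half-width `box`; coincidences are
#' astronomically unlikely and not excluded.
#'
#' @param system A `pp_system`.
#' @param seed Integer seed.
#' @param box Half-width of the sampling box.
#' @return An `N x d` configuration matrix.
#' @export
random_config <- function(system, seed, box = 4) {
  set.seed(as.integer(seed))
  matrix(runif(system$n_particles * system$d, -box, box),
         system$n_particles, system$d)
}
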