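# System assembly: entities with permanent constraint bonds, plus a registry
# of switched pairwise terms S_(p,j) * phi_(p,j) forming the approximate
# N-body potential.

#' Define an interacting entity
#'
#' An entity (a molecule, rod, strand, ...) is a set of particle sites held
#' together by permanent stiff harmonic bonds; those constraint bonds are
#' always on (never switched), which keeps the assembled system Hamiltonian.
#'
#' @param name Entity label.
#' @param ids Integer vector of particle ids (globally unique across
#'   entities).
#' @param masses Site masses (recycled to `length(ids)`).
#' @param bonds List of internal bonds; each element is
#'   `list(pair = c(i, j), k = stiffness, r0 = rest length)` with both ids
#'   belonging to this entity.
#' @return An object of class `pp_entity`.
#' @export
entity <- function(name, ids, masses = 1, bonds = list()) {
  ids <- as.integer(ids)
  stopifnot(length(ids) >= 1, !anyDuplicated(ids), all(ids >= 1))
  masses <- rep_len(as.numeric(masses), length(ids))
  stopifnot(all(masses > 0))
  for (b in bonds) {
    p <- canonical_pair(b$pair[1], b$pair[2])
    if (!all(p %in% ids)) {
      stop("entity '", name, "': internal bond (", p[1], ",", p[2],
           ") references a particle outside the entity", call. = FALSE)
    }
    stopifnot(b$k > 0, b$r0 >= 0)
  }
  structure(list(name = name, ids = ids, masses = masses, bonds = bonds),
            class = "pp_entity")
}

#' Create an empty system
#'
#' The container for the approximate N-body potential: a set of entities and
#' a registry of switched pairwise terms, each an
#' (atom pair, multiplicity index, potential, rule) quadruple added with
#' [add_term()].  Optionally a flat-bottom harmonic confinement keeps the
#' entities in a finite region (off unless `confinement` is given).
#'
#' @param entities List of [entity()] objects with disjoint particle ids
#'   covering `1..N` (ids may be declared in any order).
#' @param d Spatial dimension, 2 or 3.
#' @param units Unit preset: `"reduced"` (k_B = 1; the fixture default) or
#'   `"real"` (lengths in Angstrom, energies in kcal/mol, masses in g/mol,
#'   k_B = 0.0019872041 kcal/mol/K; the matching time unit is ~48.89 fs).
#' @param confinement `NULL`, or `list(k, radius, center)`: beyond `radius`
#'   from `center` every particle feels a radial spring `k` (flat-bottom
#'   spherical well, C1 at the rim).
#' @return An object of class `pp_system`.
#' @export
system_spec <- function(entities, d = 2, units = c("reduced", "real"),
                        confinement = NULL) {
  units <- match.arg(units)
  stopifnot(d %in% c(2, 3), length(entities) >= 1)
  stopifnot(all(vapply(entities, inherits, TRUE, what = "pp_entity")))
  ids <- unlist(lapply(entities, `[[`, "ids"))
  if (anyDuplicated(ids)) {
    stop("system_spec(): particle ids must be disjoint across entities", call. = FALSE)
  }
  n <- max(ids)
  if (!setequal(ids, seq_len(n))) {
    stop("system_spec(): particle ids must cover 1..N without gaps", call. = FALSE)
  }
  masses <- numeric(n)
  for (e in entities) masses[e$ids] <- e$masses
  if (!is.null(confinement)) {
    stopifnot(confinement$k > 0, confinement$radius > 0)
    if (is.null(confinement$center)) confinement$center <- rep(0, d)
    stopifnot(length(confinement$center) == d)
  }
  structure(list(
    entities = entities, d = as.integer(d), n_particles = n,
    masses = masses, terms = list(), confinement = confinement,
    units = units,
    k_B = if (units == "reduced") 1 else 0.0019872041
  ), class = "pp_system")
}

is_system <- function(x) inherits(x, "pp_system")

#' @export
print.pp_system <- function(x, ...) {
  cat(sprintf("<system> %d particles in d=%d (%s units), %d entities, %d switched terms\n",
              x$n_particles, x$d, x$units, length(x$entities), length(x$terms)))
  for (tm in x$terms) {
    cat(sprintf("  %-14s (%d,%d) j=%d  %-16s  L = %s\n", tm$label,
                tm$pair[1], tm$pair[2], tm$j, tm$potential$kind,
                deparse_logic(tm$logic)))
  }
  if (!is.null(x$confinement)) {
    cat(sprintf("  confinement: flat-bottom well, radius %g, k = %g\n",
                x$confinement$radius, x$confinement$k))
  }
  invisible(x)
}

#' Add a switched pairwise term to a system
#'
#' Registers one summand `S * phi(r_pair)` of the approximate potential.  The
#' rule is validated against the self-reference ban (a term's rule may not
#' depend on its own pair distance) and compiled to its smooth encoding
#' function.  Adding a second term on the same pair raises that pair's
#' multiplicity (e.g. stable bond + transition-state repulsion).
#'
#' @param system A `pp_system`.
#' @param pair The interacting pair, `c(i, j)`.
#' @param potential A `pp_potential`.
#' @param logic A `pp_logic` rule (use `lg_const(1)` for an unswitched
#'   term).
#' @param n Smoothing sharpness passed to [smooth_logic()].
#' @param overrides Per-leaf smoothing overrides, see [smooth_logic()].
#' @param label Optional term label (defaults to `"(i,j),j_index"`).
#' @return The system with the term appended.
#' @export
add_term <- function(system, pair, potential, logic, n = 6L,
                     overrides = list(), label = NULL) {
  stopifnot(is_system(system), is_potential(potential), is_logic(logic))
  pair <- canonical_pair(pair[1], pair[2])
  if (any(pair > system$n_particles)) {
    stop("add_term(): pair (", pair[1], ",", pair[2],
         ") references an undeclared particle", call. = FALSE)
  }
  v <- validate_logic(logic, pair)
  if (!v$ok) {
    stop("add_term(): the rule for pair (", pair[1], ",", pair[2],
         ") references its own pair distance ", nrow(v$violations),
         " time(s); a switching rule may not depend on the distance of the ",
         "pair it switches", call. = FALSE)
  }
  j <- multiplicity(system, pair) + 1L
  if (is.null(label)) label <- sprintf("(%d,%d),%d", pair[1], pair[2], j)
  term <- list(pair = pair, j = j, potential = potential, logic = logic,
               encoding = smooth_logic(logic, n = n, overrides = overrides),
               n = as.integer(n), overrides = overrides, label = label)
  system$terms <- c(system$terms, list(term))
  system
}

#' Multiplicity of a pair
#'
#' Number of switched terms registered on an atom pair.
#'
#' @param system A `pp_system`.
#' @param pair `c(i, j)`.
#' @return Integer count.
#' @export
multiplicity <- function(system, pair) {
  pair <- canonical_pair(pair[1], pair[2])
  sum(vapply(system$terms, function(tm) all(tm$pair == pair), TRUE))
}

#' Effective vs full configuration-space dimension
#'
#' The assembled potential depends only on the particles that appear in its
#' switched terms -- as interacting pairs or inside the switching rules --
#' so its effective dimension can be far below the full configuration-space
#' dimension `d * N`.
#'
#' @param system A `pp_system`.
#' @return `list(reduced = d * #unique particles the switched terms depend
#'   on, full = d * N)`.
#' @export
effective_dimension <- function(system) {
  stopifnot(is_system(system))
  ids <- unique(c(
    unlist(lapply(system$terms, `[[`, "pair")),
    unlist(lapply(system$terms, function(tm) {
      lv <- logic_leaves(tm$logic)
      c(lv$i, lv$j)
    }))))
  list(reduced = system$d * length(ids),
       full = system$d * system$n_particles)
}

# ---- flat compiled representation for the engine ---------------------------

# opcodes: 0 = push const, 1 = push leaf, 2 = NOT, 3 = AND (binary),
# 4 = OR (binary).  n-ary connectives are folded left at compile time.
compile_encoding <- function(enc) {
  leaves <- list()
  code <- integer(0)
  arg <- numeric(0)
  emit <- function(op, a = 0) {
    code[[length(code) + 1L]] <<- op
    arg[[length(arg) + 1L]] <<- a
  }
  walk <- function(e) {
    switch(e$kind,
      const = emit(0L, e$value),
      near  = {
        leaves[[length(leaves) + 1L]] <<- c(e$pair[1], e$pair[2], e$alpha, e$n)
        emit(1L, length(leaves) - 1L)  # zero-based leaf index
      },
      not   = { walk(e$arg); emit(2L) },
      and   = { walk(e$args[[1]]); for (a in e$args[-1]) { walk(a); emit(3L) } },
      or    = { walk(e$args[[1]]); for (a in e$args[-1]) { walk(a); emit(4L) } },
      stop("malformed encoding node", call. = FALSE)
    )
  }
  walk(enc)
  lv <- if (length(leaves)) do.call(rbind, leaves) else matrix(0, 0, 4)
  list(code = as.integer(code), arg = as.numeric(arg), leaves = lv)
}

pot_code <- function(pot) {
  p <- pot$params
  switch(pot$kind,
    morse           = list(kind = 1L, par = c(p$D, p$a, p$r_eq)),
    repulsive_morse = list(kind = 2L, par = c(p$D, p$a, p$r_eq)),
    harmonic        = list(kind = 3L, par = c(p$k, p$r0, 0)),
    tabulated       = stop("tabulated potentials are evaluated in R only; ",
                           "the compiled engine supports the closed forms ",
                           "(morse, repulsive_morse, harmonic)", call. = FALSE)
  )
}

compile_system <- function(system) {
  stopifnot(is_system(system))
  bonds <- list()
  for (e in system$entities) {
    for (b in e$bonds) {
      p <- canonical_pair(b$pair[1], b$pair[2])
      bonds[[length(bonds) + 1L]] <- c(p[1] - 1, p[2] - 1, b$k, b$r0)
    }
  }
  terms <- lapply(system$terms, function(tm) {
    pc <- pot_code(tm$potential)
    prog <- compile_encoding(tm$encoding)
    list(pi = tm$pair[1] - 1L, pj = tm$pair[2] - 1L,
         kind = pc$kind, par = pc$par,
         code = prog$code, arg = prog$arg, leaves = prog$leaves)
  })
  conf <- if (is.null(system$confinement)) {
    list(on = FALSE, k = 0, radius = 0, center = rep(0, system$d))
  } else {
    list(on = TRUE, k = system$confinement$k,
         radius = system$confinement$radius,
         center = as.numeric(system$confinement$center))
  }
  list(n = system$n_particles, d = system$d, masses = system$masses,
       bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 4),
       terms = terms, conf = conf)
}

has_tabulated <- function(system) {
  any(vapply(system$terms, function(tm) tm$potential$kind == "tabulated", TRUE))
}

check_config_dims <- function(system, x) {
  x <- as_config(x)
  if (nrow(x) != system$n_particles || ncol(x) != system$d) {
    stop("configuration must be ", system$n_particles, " x ", system$d,
         " for this system (got ", nrow(x), " x ", ncol(x), ")", call. = FALSE)
  }
  x
}

# ---- energies and forces ---------------------------------------------------

#' Total potential energy with per-term breakdown
#'
#' Evaluates the assembled potential: the permanent harmonic constraint
#' bonds of every entity plus every switched term `S * phi(r_pair)` (plus the
#' confinement well if enabled).
#'
#' @param system A `pp_system`.
#' @param x Configuration matrix (`N x d`).
#' @param breakdown If `TRUE` (default) also return a per-term table.
#' @return If `breakdown`, a list with `total`, `bond_energy`,
#'   `confinement_energy` and `terms` (data.frame with columns `label`, `i`,
#'   `j`, `j_index`, `r`, `S`, `phi`, `energy = S * phi`); otherwise the
#'   total as a single number.
#' @export
total_energy <- function(system, x, breakdown = TRUE) {
  x <- check_config_dims(system, x)
  if (has_tabulated(system)) {
    res <- total_energy_r(system, x)
  } else {
    res <- engine_energy(compile_system(system), x)
  }
  if (!breakdown) return(res$total)
  tm <- system$terms
  res$terms <- data.frame(
    label = vapply(tm, `[[`, "", "label"),
    i = vapply(tm, function(t) t$pair[1], 0),
    j = vapply(tm, function(t) t$pair[2], 0),
    j_index = vapply(tm, `[[`, 0L, "j"),
    r = res$r, S = res$S, phi = res$phi, energy = res$S * res$phi)
  res[c("total", "bond_energy", "confinement_energy", "terms")]
}

# pure-R evaluation path (also used for systems with tabulated potentials)
total_energy_r <- function(system, x) {
  bond_e <- 0
  for (e in system$entities) {
    for (b in e$bonds) {
      r <- pair_distance(x, b$pair[1], b$pair[2])
      bond_e <- bond_e + 0.5 * b$k * (r - b$r0)^2
    }
  }
  S <- phi <- rr <- numeric(length(system$terms))
  for (k in seq_along(system$terms)) {
    tm <- system$terms[[k]]
    rr[k] <- pair_distance(x, tm$pair[1], tm$pair[2])
    S[k] <- encoding_eval(tm$encoding, x)
    phi[k] <- pair_energy(rr[k], tm$potential)
  }
  conf_e <- confinement_energy(system, x)
  list(total = bond_e + sum(S * phi) + conf_e, bond_energy = bond_e,
       confinement_energy = conf_e, S = S, phi = phi, r = rr)
}

confinement_energy <- function(system, x) {
  cf <- system$confinement
  if (is.null(cf)) return(0)
  dx <- sweep(x, 2, cf$center)
  rad <- sqrt(rowSums(dx^2))
  exc <- pmax(rad - cf$radius, 0)
  0.5 * cf$k * sum(exc^2)
}

#' Forces on every particle
#'
#' `mode = "full"` returns the exact negative gradient of [total_energy()],
#' including the encoding-function gradients; these chain-rule contributions
#' are what generate the transition-state repulsion when a switch turns a
#' deep bond off.  `mode = "frozen_switch"` treats every encoding function as
#' locally constant (gradients of `S` dropped), keeping only terms of the
#' form `-S * grad(phi)` -- the qualitative approximation under which the
#' switch gradients vanish almost everywhere.  Both modes include the
#' permanent bonds and confinement, and absent the (external) confining well
#' both conserve total momentum (net force is the zero vector).
#'
#' @param system A `pp_system`.
#' @param x Configuration matrix (`N x d`).
#' @param mode `"full"` or `"frozen_switch"`.
#' @return An `N x d` matrix of forces.
#' @export
forces <- function(system, x, mode = c("full", "frozen_switch")) {
  mode <- match.arg(mode)
  x <- check_config_dims(system, x)
  if (has_tabulated(system)) {
    return(forces_r(system, x, mode))
  }
  engine_forces(compile_system(system), x, mode == "frozen_switch")
}

forces_r <- function(system, x, mode) {
  f <- matrix(0, nrow(x), ncol(x))
  addpair <- function(f, i, j, fmag) {
    dx <- x[i, ] - x[j, ]
    r <- sqrt(sum(dx * dx))
    if (r > 0) {
      u <- dx / r
      f[i, ] <- f[i, ] + fmag * u
      f[j, ] <- f[j, ] - fmag * u
    }
    f
  }
  for (e in system$entities) {
    for (b in e$bonds) {
      r <- pair_distance(x, b$pair[1], b$pair[2])
      f <- addpair(f, b$pair[1], b$pair[2], -b$k * (r - b$r0))
    }
  }
  for (tm in system$terms) {
    r <- pair_distance(x, tm$pair[1], tm$pair[2])
    S <- encoding_eval(tm$encoding, x)
    f <- addpair(f, tm$pair[1], tm$pair[2], S * pair_force(r, tm$potential))
    if (mode == "full") {
      f <- f - pair_energy(r, tm$potential) * encoding_grad(tm$encoding, x)
    }
  }
  cf <- system$confinement
  if (!is.null(cf)) {
    dx <- sweep(x, 2, cf$center)
    rad <- sqrt(rowSums(dx^2))
    exc <- pmax(rad - cf$radius, 0)
    pull <- ifelse(rad > 0, cf$k * exc / pmax(rad, 1e-300), 0)
    f <- f - dx * pull
  }
  f
}
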