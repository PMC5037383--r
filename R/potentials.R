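# 1-D pairwise interaction potentials phi(r) and derivatives.

new_potential <- function(kind, params, label = kind) {
  structure(list(kind = kind, params = params, label = label),
            class = "pp_potential")
}

is_potential <- function(x) inherits(x, "pp_potential")

#' Pairwise potential constructors
#'
#' `pot_morse(D, a, r_eq)` is the Morse bond potential in the convention
#' \deqn{\phi(r) = D\,(1 - e^{-a (r - r_{eq})})^2 - D,}
#' with minimum `-D` at the equilibrium distance and limit 0 at infinity, so the
#' dissociation energy `D` is literally the energy needed to separate a
#' bonded pair.  `pot_harmonic(k, r0)` is `k/2 (r - r0)^2`, used for the
#' permanent intra-entity constraint bonds.  `pot_repulsive_morse(D, a, r_eq)`
#' is the repulsive branch of the Morse potential, spliced to exactly zero
#' beyond `r_eq` (value and slope both vanish there, so it is C1); it models
#' the short-range electron-electron repulsion active in a transition state.
#' `pot_tabulated(r, phi)` interpolates a sampled potential with a monotone
#' cubic spline and clamps flat beyond the table ends.
#'
#' @param D Dissociation energy (energy units), `> 0`.
#' @param a Width parameter (inverse length), `> 0`.
#' @param r_eq Equilibrium bond distance (length units), `> 0`.
#' @param k Harmonic stiffness (energy / length^2), `> 0`.
#' @param r0 Harmonic rest length, `>= 0`.
#' @param r,phi Sample grid (strictly increasing, positive) and values.
#' @return An object of class `pp_potential`.
#' @examples
#' m <- pot_morse(D = 100, a = 1, r_eq = 2)
#' pair_energy(2, m)    # -100 at the bottom of the well
#' @name potential-constructors
NULL

#' @rdname potential-constructors
#' @export
pot_morse <- function(D, a, r_eq) {
  stopifnot(D > 0, a > 0, r_eq > 0)
  new_potential("morse", list(D = D, a = a, r_eq = r_eq))
}

#' @rdname potential-constructors
#' @export
pot_repulsive_morse <- function(D, a, r_eq) {
  stopifnot(D > 0, a > 0, r_eq > 0)
  new_potential("repulsive_morse", list(D = D, a = a, r_eq = r_eq))
}

#' @rdname potential-constructors
#' @export
pot_harmonic <- function(k, r0) {
  stopifnot(k > 0, r0 >= 0)
  new_potential("harmonic", list(k = k, r0 = r0))
}

#' @rdname potential-constructors
#' @export
pot_tabulated <- function(r, phi) {
  stopifnot(length(r) == length(phi), length(r) >= 4,
            all(diff(r) > 0), all(r > 0), all(is.finite(phi)))
  new_potential("tabulated", list(r = as.numeric(r), phi = as.numeric(phi)))
}

#' @export
print.pp_potential <- function(x, ...) {
  p <- x$params
  desc <- switch(x$kind,
    morse = sprintf("Morse(D=%g, a=%g, r_eq=%g)", p$D, p$a, p$r_eq),
    repulsive_morse = sprintf("repulsive Morse branch(D=%g, a=%g, r_eq=%g)", p$D, p$a, p$r_eq),
    harmonic = sprintf("harmonic(k=%g, r0=%g)", p$k, p$r0),
    tabulated = sprintf("tabulated(%d points on [%g, %g])",
                        length(p$r), min(p$r), max(p$r)))
  cat("<potential> ", desc, "\n", sep = "")
  invisible(x)
}

#' Repulsive part of a Morse bond
#'
#' Builds the transition-state repulsion associated with a Morse bond: the
#' repulsive branch of the *same* Morse potential (same `D`, `a`, `r_eq`),
#' shifted up by `D` so it is `>= 0`, and spliced to exactly zero at and
#' beyond `r_eq`.
#'
#' @param pot A Morse `pp_potential`.
#' @return A `pp_potential` of kind `repulsive_morse`.
#' @export
repulsive_part <- function(pot) {
  stopifnot(is_potential(pot), pot$kind == "morse")
  pot_repulsive_morse(pot$params$D, pot$params$a, pot$params$r_eq)
}

tab_spline <- function(p) {
  splinefun(p$r, p$phi, method = "monoH.FC")
}

#' Pairwise potential energy at a distance
#'
#' @param r Distance(s), `> 0`.
#' @param pot A `pp_potential`.
#' @return Energy value(s).
#' @export
pair_energy <- function(r, pot) {
  stopifnot(is_potential(pot))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair_energy(): distances must be positive and finite", call. = FALSE)
  }
  p <- pot$params
  switch(pot$kind,
    morse = {
      e <- exp(-p$a * (r - p$r_eq))
      p$D * (1 - e)^2 - p$D
    },
    repulsive_morse = {
      e <- exp(-p$a * (r - p$r_eq))
      ifelse(r < p$r_eq, p$D * (1 - e)^2, 0)
    },
    harmonic = 0.5 * p$k * (r - p$r0)^2,
    tabulated = {
      f <- tab_spline(p)
      rc <- pmin(pmax(r, p$r[1]), p$r[length(p$r)])
      f(rc)
    }
  )
}

#' Pairwise force magnitude -dphi/dr
#'
#' The (signed) radial force: positive values push the pair apart
#' (repulsion), negative values pull it together.  Analytic for the closed
#' forms, spline derivative for tabulated potentials (zero outside the
#' table, matching the clamped extrapolation).
#'
#' @inheritParams pair_energy
#' @return Force value(s), `-dphi/dr`.
#' @export
pair_force <- function(r, pot) {
  stopifnot(is_potential(pot))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair_force(): distances must be positive and finite", call. = FALSE)
  }
  p <- pot$params
  switch(pot$kind,
    morse = {
      e <- exp(-p$a * (r - p$r_eq))
      -2 * p$D * p$a * e * (1 - e)
    },
    repulsive_morse = {
      e <- exp(-p$a * (r - p$r_eq))
      ifelse(r < p$r_eq, -2 * p$D * p$a * e * (1 - e), 0)
    },
    harmonic = -p$k * (r - p$r0),
    tabulated = {
      f <- tab_spline(p)
      inside <- r >= p$r[1] & r <= p$r[length(p$r)]
      ifelse(inside, -f(pmax(pmin(r, p$r[length(p$r)]), p$r[1]), deriv = 1), 0)
    }
  )
}
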