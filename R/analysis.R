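# Trajectory post-processing: occupancies, bond events, quasi-static
# dissociation work, energy-surface scans.

pair_distance_series <- function(traj, pair) {
  pair <- canonical_pair(pair[1], pair[2])
  hit <- which(vapply(traj$term_pairs, function(p) all(p == pair), TRUE))
  if (length(hit) > 0) return(traj$r[, hit[1]])
  n <- dim(traj$positions)[2]
  if (any(pair > n)) stop("pair not present in trajectory", call. = FALSE)
  nf <- dim(traj$positions)[1]
  d <- dim(traj$positions)[3]
  a <- matrix(traj$positions[, pair[1], ], nf, d)
  b <- matrix(traj$positions[, pair[2], ], nf, d)
  sqrt(rowSums((a - b)^2))
}

#' Fraction of time a pair is bonded
#'
#' Occupancy of the bound state, read directly off the recorded distance
#' trace: the fraction of frames whose pair distance lies below `r_on`.  The criterion is purely
#' geometric (not based on encoding values), matching how distance traces of
#' realizations are conventionally read.
#'
#' @param traj A `pp_trajectory`.
#' @param pair `c(i, j)`.
#' @param r_on Bonding distance threshold.
#' @return A fraction in `[0, 1]`.
#' @export
bond_occupancy <- function(traj, pair, r_on) {
  stopifnot(inherits(traj, "pp_trajectory"), r_on > 0)
  if (length(traj$times) == 0) stop("empty trajectory", call. = FALSE)
  r <- pair_distance_series(traj, pair)
  mean(r < r_on)
}

#' Bond formation/breaking events with hysteresis
#'
#' Two-threshold (Schmitt-trigger) event detection per pair: an unbound pair
#' becomes bound when its distance first drops below `r_on`, and a bound
#' pair becomes unbound when the distance exceeds `r_off > r_on`.  The gap
#' between the thresholds debounces the thermal jitter of Langevin
#' trajectories, so events per pair strictly alternate formed/broken.
#'
#' @param traj A `pp_trajectory`.
#' @param pairs List of pairs `c(i, j)` (default: every switched-term pair).
#' @param r_on Formation threshold.
#' @param r_off Breaking threshold, `> r_on`.
#' @return A data.frame with columns `i`, `j`, `kind` ("formed"/"broken"),
#'   `time`, `frame`, in chronological order.
#' @export
event_sequence <- function(traj, pairs = NULL, r_on, r_off) {
  stopifnot(inherits(traj, "pp_trajectory"))
  if (!(r_off > r_on)) {
    stop("event_sequence(): hysteresis requires r_off > r_on", call. = FALSE)
  }
  if (is.null(pairs)) pairs <- unique(traj$term_pairs)
  out <- list()
  for (p in pairs) {
    r <- pair_distance_series(traj, p)
    bound <- FALSE
    for (f in seq_along(r)) {
      if (!bound && r[f] < r_on) {
        bound <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          i = p[1], j = p[2], kind = "formed", time = traj$times[f], frame = f)
      } else if (bound && r[f] > r_off) {
        bound <- FALSE
        out[[length(out) + 1L]] <- data.frame(
          i = p[1], j = p[2], kind = "broken", time = traj$times[f], frame = f)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), kind = character(),
                      time = numeric(), frame = integer()))
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$time, ev$i, ev$j), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Quasi-static dissociation-work probe
#'
#' Measures the energy an approaching molecule must supply to drive a
#' switched bond's encoding function from 1 to 0.  The entity containing
#' `particle` is dragged rigidly (so its internal constraint bonds do no
#' work), quasi-statically, along the straight ray through `target`
#' (direction taken from `config`) until `particle` sits at distance `to`
#' from `target`; every other particle stays fixed.  The opposing force on
#' the dragged entity (full-gradient mode) is integrated along the path
#' with adaptive quadrature.  For a bond of depth `D` held at its equilibrium length, the
#' returned work equals `D` up to the smoothing tails: the switched term's
#' energy rises from `-D` to about zero as the switch closes.
#'
#' The probe is evaluated with any confinement well removed, so the result
#' is the switched-bond work alone.
#'
#' @param system A `pp_system`.
#' @param config Reference configuration; all particles except `particle`
#'   stay exactly here.
#' @param particle Index of the dragged particle.
#' @param target Index of the particle toward which it is dragged.
#' @param from,to Start/end distances of the path (`from > to > 0`);
#'   typically `from` well outside every switch radius.
#' @param rel.tol Quadrature relative tolerance.
#' @return The work (energy units), with attributes `delta_U` (end-to-start
#'   potential-energy difference, the closed-form cross-check) and
#'   `abs.error` (quadrature error estimate).
#' @export
dissociation_work <- function(system, config, particle, target, from, to,
                              rel.tol = 1e-8) {
  stopifnot(is_system(system), from > to, to > 0)
  sys <- system
  sys$confinement <- NULL
  x <- check_config_dims(sys, config)
  u <- x[particle, ] - x[target, ]
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("particle and target coincide in config", call. = FALSE)
  u <- u / nu
  ent <- which(vapply(sys$entities, function(e) particle %in% e$ids, TRUE))
  ids <- if (length(ent)) sys$entities[[ent[1]]]$ids else particle
  if (target %in% ids) {
    stop("dissociation_work(): target belongs to the dragged entity", call. = FALSE)
  }
  place <- function(s) {
    xc <- x
    shift <- (x[target, ] + s * u) - x[particle, ]
    xc[ids, ] <- sweep(x[ids, , drop = FALSE], 2, shift, `+`)
    xc
  }
  integrand <- function(s) {
    vapply(s, function(si) {
      f <- forces(sys, place(si), mode = "full")
      -sum(f[ids, , drop = FALSE] %*% u)   # dU/ds along the rigid drag
    }, 0)
  }
  q <- integrate(integrand, lower = from, upper = to, rel.tol = rel.tol,
                 subdivisions = 400L)
  work <- q$value
  dU <- total_energy(sys, place(to), breakdown = FALSE) -
        total_energy(sys, place(from), breakdown = FALSE)
  structure(work, delta_U = dU, abs.error = q$abs.error)
}

#' Potential-energy surface over two pair distances
#'
#' Scans the assembled potential on a grid of two pair distances, with every
#' other coordinate frozen at the reference geometry.  For each grid point
#' the particle `move[k]` of `pair_x`/`pair_y` is placed on the ray from its
#' fixed partner through its reference position at the prescribed distance;
#' the rest of `config` is untouched.
#'
#' @param system A `pp_system`.
#' @param config Reference configuration.
#' @param pair_x,pair_y The two scanned pairs `c(i, j)`.
#' @param move Length-2 vector: which particle of each pair is moved.
#' @param rx,ry Strictly positive grid vectors of pair distances.
#' @param include_confinement Whether the optional confinement well
#'   contributes.  Off by default: the scan characterizes the interaction
#'   potential, and a container term would only encode the arbitrary
#'   placement of the frozen geometry.
#' @return An object of class `pp_surface`: `list(rx, ry, U)` with
#'   `U[a, b] = U(rx[a], ry[b])`.
#' @export
energy_surface <- function(system, config, pair_x, pair_y, move, rx, ry,
                           include_confinement = FALSE) {
  stopifnot(is_system(system), length(move) == 2)
  if (!include_confinement) system$confinement <- NULL
  if (any(rx <= 0) || any(ry <= 0)) {
    stop("energy_surface(): grid distances must be positive", call. = FALSE)
  }
  x <- check_config_dims(system, config)
  anchor <- function(pair, mv) {
    stopifnot(mv %in% pair)
    setdiff(pair, mv)
  }
  ax <- anchor(pair_x, move[1]); ay <- anchor(pair_y, move[2])
  ux <- x[move[1], ] - x[ax, ]; ux <- ux / sqrt(sum(ux^2))
  uy <- x[move[2], ] - x[ay, ]; uy <- uy / sqrt(sum(uy^2))
  U <- matrix(NA_real_, length(rx), length(ry))
  for (a in seq_along(rx)) {
    for (b in seq_along(ry)) {
      xc <- x
      xc[move[1], ] <- x[ax, ] + rx[a] * ux
      xc[move[2], ] <- x[ay, ] + ry[b] * uy
      U[a, b] <- total_energy(system, xc, breakdown = FALSE)
    }
  }
  structure(list(rx = rx, ry = ry, U = U,
                 pair_x = pair_x, pair_y = pair_y), class = "pp_surface")
}

#' @export
print.pp_surface <- function(x, ...) {
  cat(sprintf("<energy surface> %d x %d grid, U in [%.4g, %.4g]\n",
              length(x$rx), length(x$ry), min(x$U), max(x$U)))
  invisible(x)
}

#' Contour plot of an energy surface
#'
#' @param x A `pp_surface`.
#' @param nlevels Number of contour levels.
#' @param ... Passed to [graphics::contour()].
#' @importFrom graphics contour image
#' @importFrom grDevices hcl.colors
#' @export
plot.pp_surface <- function(x, nlevels = 20, ...) {
  image(x$rx, x$ry, x$U, col = hcl.colors(64, "viridis"),
        xlab = sprintf("r(%d,%d)", x$pair_x[1], x$pair_x[2]),
        ylab = sprintf("r(%d,%d)", x$pair_y[1], x$pair_y[2]))
  contour(x$rx, x$ry, x$U, nlevels = nlevels, add = TRUE, ...)
  invisible(x)
}

#' Reference geometry for the reaction energy-surface scan
#'
#' Lays the reaction fixture out on a line so that the two scanned bond
#' distances are independent coordinates: rod A spans the origin, B's
#' active site extends on one side (the (1,3) distance), C's on the other
#' (the (2,5) distance); passive sites trail outward.
#'
#' @param system A reaction fixture system.
#' @param r13,r25 Initial values of the two scanned distances.
#' @return A configuration matrix suitable for [energy_surface()] with
#'   `pair_x = c(1,3)`, `pair_y = c(2,5)`, `move = c(3,5)`.
#' @export
reaction_scan_geometry <- function(system, r13 = 2, r25 = 2) {
  stopifnot(is_system(system), system$n_particles >= 6)
  rod <- 2
  x <- matrix(0, system$n_particles, 2)
  x[1, ] <- c(0, 0)
  x[2, ] <- c(rod, 0)
  x[3, ] <- c(-r13, 0)          # B active site, left of atom 1
  x[4, ] <- c(-r13 - rod, 0)    # B passive site
  x[5, ] <- c(rod + r25, 0)     # C active site, right of atom 2
  x[6, ] <- c(2 * rod + r25, 0) # C passive site
  x
}
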