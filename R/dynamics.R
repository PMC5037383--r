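# Time integration: deterministic velocity-Verlet and Langevin (BAOAB).

new_trajectory <- function(raw, system, params) {
  nt <- length(system$terms)
  labels <- vapply(system$terms, `[[`, "", "label")
  for (nm in c("S", "r", "phi")) {
    m <- raw[[nm]]
    if (nt > 0) colnames(m) <- labels
    raw[[nm]] <- m
  }
  structure(list(
    times = raw$times, positions = raw$positions, velocities = raw$velocities,
    E_pot = raw$E_pot, E_kin = raw$E_kin,
    S = raw$S, r = raw$r, phi = raw$phi,
    term_labels = labels, term_pairs = lapply(system$terms, `[[`, "pair"),
    system = system, params = params
  ), class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  nf <- length(x$times)
  cat(sprintf("<trajectory> %d frames over t = [%g, %g], %d particles (d=%d)\n",
              nf, x$times[1], x$times[nf], dim(x$positions)[2], dim(x$positions)[3]))
  cat(sprintf("  integrator: %s, dt = %g, mode = %s\n",
              x$params$integrator, x$params$dt, x$params$mode))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one recorded configuration
#'
#' @param traj A `pp_trajectory`.
#' @param frame Frame index (1-based; `n_frames(traj)` for the last).
#' @return An `N x d` position matrix.
#' @export
frame_config <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= length(traj$times))
  n <- dim(traj$positions)[2]; d <- dim(traj$positions)[3]
  matrix(traj$positions[frame, , ], n, d)
}

#' Per-frame energy summary of a trajectory
#'
#' @param traj A `pp_trajectory`.
#' @return A data.frame with columns `frame`, `time`, `E_pot`, `E_kin`,
#'   `E_total`.
#' @export
trajectory_energies <- function(traj) {
  data.frame(frame = seq_along(traj$times), time = traj$times,
             E_pot = traj$E_pot, E_kin = traj$E_kin,
             E_total = traj$E_pot + traj$E_kin)
}

#' Per-term switch/energy records of a trajectory
#'
#' Long-format bookkeeping of every switched term at every recorded frame.
#'
#' @param traj A `pp_trajectory`.
#' @return A data.frame with columns `frame`, `time`, `term`, `i`, `j`, `r`,
#'   `S`, `phi`, `energy`.
#' @export
trajectory_terms <- function(traj) {
  nt <- length(traj$term_labels)
  if (nt == 0) {
    return(data.frame(frame = integer(), time = numeric(), term = character(),
                      i = integer(), j = integer(), r = numeric(),
                      S = numeric(), phi = numeric(), energy = numeric()))
  }
  nf <- length(traj$times)
  data.frame(
    frame = rep(seq_len(nf), nt),
    time = rep(traj$times, nt),
    term = rep(traj$term_labels, each = nf),
    i = rep(vapply(traj$term_pairs, `[`, 0, 1), each = nf),
    j = rep(vapply(traj$term_pairs, `[`, 0, 2), each = nf),
    r = as.vector(traj$r), S = as.vector(traj$S), phi = as.vector(traj$phi),
    energy = as.vector(traj$S * traj$phi))
}

run_engine <- function(system, x0, v0, dt, n_steps, kBT, gamma, mode, stride,
                       integrator) {
  stopifnot(dt > 0, n_steps >= 1, stride >= 1)
  x0 <- check_config_dims(system, x0)
  v0 <- check_config_dims(system, v0)
  if (has_tabulated(system)) {
    stop("the compiled integrator supports closed-form potentials only ",
         "(morse, repulsive_morse, harmonic); tabulated terms cannot be ",
         "integrated", call. = FALSE)
  }
  raw <- engine_run(compile_system(system), x0, v0, dt, as.integer(n_steps),
                    kBT, gamma, mode == "frozen_switch", as.integer(stride))
  new_trajectory(raw, system,
                 list(integrator = integrator, dt = dt, n_steps = n_steps,
                      kBT = kBT, gamma = gamma, mode = mode, stride = stride))
}

#' Deterministic velocity-Verlet integration (NVE)
#'
#' Symplectic velocity-Verlet on the assembled potential with no thermostat:
#' total energy is conserved up to a bounded oscillation provided the forces
#' are exact gradients, which requires `mode = "full"` (the default here).
#' Useful for Hamiltonian checks; the production simulation mode is
#' [run_langevin()].
#'
#' @param system A `pp_system`.
#' @param x0 Initial configuration (`N x d`).
#' @param v0 Initial velocities (`N x d`); defaults to rest.
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param mode Force mode; energy conservation holds for `"full"`.
#' @param stride Record every `stride`-th step (frame 0 always recorded).
#' @return A `pp_trajectory`.
#' @export
run_verlet <- function(system, x0, v0 = NULL, dt, n_steps,
                       mode = c("full", "frozen_switch"), stride = 10L) {
  mode <- match.arg(mode)
  if (is.null(v0)) v0 <- matrix(0, system$n_particles, system$d)
  run_engine(system, x0, v0, dt, n_steps, kBT = 0, gamma = 0, mode = mode,
             stride = stride, integrator = "verlet")
}

#' Langevin dynamics at constant temperature (BAOAB)
#'
#' Integrates the underdamped Langevin equations with the BAOAB splitting
#' (exact Ornstein-Uhlenbeck solve for the friction/noise part), the
#' discretization with the best configurational accuracy at large time steps
#' among the standard splittings.  Initial velocities, unless supplied, are
#' drawn from the Maxwell-Boltzmann distribution at `temperature`.  All
#' randomness (initialization and thermostat noise) is derived from `seed`
#' through two deterministically split streams, so identical inputs give
#' bitwise-identical trajectories.
#'
#' @param system A `pp_system`.
#' @param x0 Initial configuration (`N x d`).
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param temperature Temperature; multiplied by the system's `k_B`
#'   (`k_B = 1` under the reduced preset, so this is k_B*T in energy units).
#' @param friction Langevin friction gamma (1/time), `> 0`.
#' @param seed Integer seed; required for reproducibility.
#' @param v0 Optional initial velocities (overrides Maxwell-Boltzmann draw).
#' @param mode Force mode, `"full"` or `"frozen_switch"`.
#' @param stride Record every `stride`-th step.
#' @return A `pp_trajectory`.
#' @export
run_langevin <- function(system, x0, dt, n_steps, temperature, friction,
                         seed, v0 = NULL, mode = c("full", "frozen_switch"),
                         stride = 10L) {
  mode <- match.arg(mode)
  stopifnot(temperature > 0, friction > 0)
  kBT <- system$k_B * temperature
  streams <- split_seed(seed)
  if (is.null(v0)) {
    set.seed(streams$init)
    sd <- sqrt(kBT / system$masses)
    v0 <- matrix(rnorm(system$n_particles * system$d), system$n_particles,
                 system$d) * sd
  }
  set.seed(streams$noise)
  run_engine(system, x0, v0, dt, n_steps, kBT = kBT, gamma = friction,
             mode = mode, stride = stride, integrator = "langevin")
}

# one config seed -> independent init / thermostat streams
split_seed <- function(seed) {
  stopifnot(length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 2L)
  list(init = s[1], noise = s[2])
}

#' Base-graphics overview plot of a trajectory
#'
#' Two stacked panels: pair distances of every switched term over time, and
#' the corresponding encoding-function values.
#'
#' @param x A `pp_trajectory`.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @importFrom graphics abline legend lines matplot par
#' @export
plot.pp_trajectory <- function(x, ...) {
  nt <- length(x$term_labels)
  if (nt == 0) stop("trajectory has no switched terms to plot", call. = FALSE)
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(old))
  matplot(x$times, x$r, type = "l", lty = 1, xlab = "time",
          ylab = "pair distance")
  legend("topright", legend = x$term_labels, col = seq_len(nt), lty = 1,
         cex = 0.7, bg = "white")
  matplot(x$times, x$S, type = "l", lty = 1, ylim = c(0, 1), xlab = "time",
          ylab = "encoding S")
  invisible(x)
}
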