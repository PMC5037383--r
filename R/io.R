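# Run-config (YAML) serialization, trajectory export, command-line front end.

#' Serialize a system and its run settings to a run-config file
#'
#' Writes a YAML document with the full system definition (entities,
#' switched terms with their rule text and smoothing parameters,
#' confinement, unit preset) plus the integrator defaults and start
#' specification carried by fixture systems.  [read_run_config()] restores
#' an equivalent system; the round trip is lossless.
#'
#' @param system A `pp_system`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(system, path) {
  stopifnot(is_system(system))
  ents <- lapply(system$entities, function(e) {
    list(name = e$name, ids = as.integer(e$ids), masses = as.numeric(e$masses),
         bonds = lapply(e$bonds, function(b) {
           list(pair = as.integer(b$pair), k = b$k, r0 = b$r0)
         }))
  })
  terms <- lapply(system$terms, function(tm) {
    list(pair = as.integer(tm$pair), label = tm$label,
         potential = c(list(kind = tm$potential$kind), tm$potential$params),
         logic = deparse_logic(tm$logic),
         smoothing = list(n = tm$n, overrides = lapply(tm$overrides, function(ov) {
           out <- list(pair = as.integer(ov$pair))
           if (!is.null(ov$alpha)) out$alpha <- ov$alpha
           if (!is.null(ov$n)) out$n <- as.integer(ov$n)
           out
         })))
  })
  doc <- list(
    units = system$units, d = system$d,
    entities = ents, terms = terms,
    confinement = if (is.null(system$confinement)) NULL else
      list(k = system$confinement$k, radius = system$confinement$radius,
           center = as.numeric(system$confinement$center)),
    fixture = system$fixture,
    run = system$run_defaults,
    start = system$start)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a run-config file
#'
#' Parses and validates a YAML run-config written by [write_run_config()]
#' (or by hand in the same schema).  Every rule is re-parsed and
#' re-validated, so a config whose rule references its own pair is rejected
#' here with a message naming the offending term.
#'
#' @param path Config file path.
#' @return A `pp_system` (with `run_defaults`/`start` metadata if present).
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  required <- c("units", "d", "entities", "terms")
  miss <- setdiff(required, names(doc))
  if (length(miss)) {
    stop("run config ", path, ": missing section(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  known <- c(required, "confinement", "fixture", "run", "start")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("run config ", path, ": unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(doc$entities) == 0) {
    stop("run config ", path, ": empty entities section", call. = FALSE)
  }
  ents <- lapply(doc$entities, function(e) {
    entity(e$name, unlist(e$ids), masses = unlist(e$masses),
           bonds = lapply(e$bonds, function(b) {
             list(pair = unlist(b$pair), k = b$k, r0 = b$r0)
           }))
  })
  conf <- doc$confinement
  if (!is.null(conf)) {
    conf <- list(k = conf$k, radius = conf$radius,
                 center = unlist(conf$center))
  }
  sys <- system_spec(ents, d = doc$d, units = doc$units, confinement = conf)
  for (tm in doc$terms) {
    pot <- rebuild_potential(tm$potential, path)
    logic <- parse_logic(tm$logic)
    n <- if (is.null(tm$smoothing$n)) 6L else tm$smoothing$n
    ov <- lapply(tm$smoothing$overrides, function(o) {
      out <- list(pair = unlist(o$pair))
      if (!is.null(o$alpha)) out$alpha <- o$alpha
      if (!is.null(o$n)) out$n <- o$n
      out
    })
    sys <- add_term(sys, unlist(tm$pair), pot, logic, n = n, overrides = ov,
                    label = tm$label)
  }
  sys$fixture <- doc$fixture
  sys$run_defaults <- doc$run
  if (!is.null(doc$start)) {
    sys$start <- list(
      min_sep = doc$start$min_sep,
      preformed = lapply(doc$start$preformed, function(pf) {
        list(pair = unlist(pf$pair), r = pf$r)
      }))
  }
  # fixtures rebuilt from config need a placement geometry again
  p <- merge_params(list())
  sys$ref_geometry <- default_ref_geometry(sys$entities, p)
  sys
}

rebuild_potential <- function(spec, path) {
  kind <- spec$kind
  if (is.null(kind)) stop("run config ", path, ": term without potential kind",
                          call. = FALSE)
  switch(kind,
    morse = pot_morse(spec$D, spec$a, spec$r_eq),
    repulsive_morse = pot_repulsive_morse(spec$D, spec$a, spec$r_eq),
    harmonic = pot_harmonic(spec$k, spec$r0),
    tabulated = pot_tabulated(unlist(spec$r), unlist(spec$phi)),
    stop("run config ", path, ": unknown potential kind '", kind, "'",
         call. = FALSE))
}

# ---- trajectory serialization ---------------------------------------------

site_labels <- function(system) {
  out <- character(system$n_particles)
  for (e in system$entities) {
    out[e$ids] <- sprintf("%s%d", e$name, seq_along(e$ids))
  }
  out
}

#' Write a trajectory in XYZ format
#'
#' Standard multi-frame XYZ: per frame an atom-count line, a comment line
#' carrying the time and total energy, then one `label x y z` row per site
#' (planar systems are written with `z = 0`).  Site labels are
#' `<entity><site index>`.
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @param digits Coordinate precision.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(traj, path, digits = 8) {
  stopifnot(inherits(traj, "pp_trajectory"))
  if (length(traj$times) == 0) stop("empty trajectory", call. = FALSE)
  n <- dim(traj$positions)[2]; d <- dim(traj$positions)[3]
  labels <- site_labels(traj$system)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t=%.6f E=%.8f", traj$times[f],
                       traj$E_pot[f] + traj$E_kin[f]), con)
    xs <- matrix(traj$positions[f, , ], n, d)
    z <- if (d == 3) xs[, 3] else rep(0, n)
    writeLines(sprintf(fmt, labels, xs[, 1], xs[, 2], z), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory file
#'
#' @param path XYZ file path.
#' @return A list with `times` and `frames` (list of `N x 3` coordinate
#'   matrices with site labels as rownames).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0)
  k <- 1L
  while (k <= length(lines)) {
    n <- as.integer(lines[k])
    if (is.na(n)) stop("malformed XYZ at line ", k, call. = FALSE)
    comment <- lines[k + 1L]
    t <- as.numeric(sub("^t=([-0-9.eE+]+).*", "\\1", comment))
    rows <- strsplit(trimws(lines[(k + 2L):(k + 1L + n)]), "\\s+")
    xs <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    rownames(xs) <- vapply(rows, `[`, "", 1)
    frames[[length(frames) + 1L]] <- xs
    times <- c(times, t)
    k <- k + 2L + n
  }
  list(times = times, frames = frames)
}

#' Write per-frame energies to CSV
#'
#' One row per recorded frame: `frame`, `time`, `E_pot`, `E_kin`,
#' `E_total`.
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_energies_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pp_trajectory"))
  if (length(traj$times) == 0) stop("empty trajectory", call. = FALSE)
  write.csv(trajectory_energies(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write the per-term switch records to CSV
#'
#' Long format, one row per (frame, switched term): `frame`, `time`,
#' `term`, `i`, `j`, `r`, `S`, `phi`, `energy`.
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_terms_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pp_trajectory"))
  write.csv(trajectory_terms(traj), path, row.names = FALSE)
  invisible(path)
}

# ---- command-line front end ------------------------------------------------

#' Command-line entry point
#'
#' Dispatcher behind the `progpot` script (installed under
#' `inst/scripts/`).  Subcommands:
#' \describe{
#'   \item{`build <fixture> -o <config.yaml>`}{emit a fixture run config
#'     (`signaling`, `inhibitor`, `reaction`, `reaction2`, `dna`).}
#'   \item{`run <config.yaml> -o <prefix> [--seed S] [--steps N]`}{simulate
#'     and write `<prefix>.xyz`, `<prefix>_energies.csv`,
#'     `<prefix>_terms.csv`.}
#'   \item{`analyze <terms.csv> [--r-on A] [--r-off B]`}{occupancies and
#'     bond events from a terms CSV; writes `<terms>_events.csv` and prints
#'     occupancies.}
#'   \item{`check <config.yaml> [--seed S]`}{validate the config and audit
#'     the analytic forces against central finite differences; prints the
#'     maximum relative error and the per-term leaf values at a random
#'     configuration.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
pp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      cat("usage: progpot <build|run|analyze|check> ...\n")
      return(invisible(1L))
    }
    cmd <- args[1]
    rest <- args[-1]
    switch(cmd,
      build = cli_build(rest),
      run = cli_run(rest),
      analyze = cli_analyze(rest),
      check = cli_check(rest),
      { message("unknown subcommand: ", cmd); 1L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_opt <- function(args, flag, default = NULL) {
  k <- which(args == flag)
  if (length(k) == 0) return(default)
  if (k[1] == length(args)) stop("flag ", flag, " needs a value", call. = FALSE)
  args[k[1] + 1L]
}

cli_positional <- function(args) {
  flags <- grepl("^-", args)
  vals <- c(flags[-1], FALSE)  # value slots following a flag
  args[!flags & !c(FALSE, flags[-length(flags)])]
}

cli_build <- function(args) {
  pos <- cli_positional(args)
  if (length(pos) < 1) stop("build: which fixture?", call. = FALSE)
  out <- cli_opt(args, "-o", paste0(pos[1], ".yaml"))
  sys <- switch(pos[1],
    signaling = build_signaling(),
    inhibitor = build_inhibitor(),
    reaction = build_reaction(bias = 1),
    reaction2 = build_reaction(bias = 2),
    dna = build_dna(),
    stop("unknown fixture '", pos[1], "'", call. = FALSE))
  write_run_config(sys, out)
  message("wrote ", out)
  0L
}

cli_run <- function(args) {
  pos <- cli_positional(args)
  if (length(pos) < 1) stop("run: which config?", call. = FALSE)
  sys <- read_run_config(pos[1])
  if (is.null(sys$run_defaults)) {
    stop("config has no run section", call. = FALSE)
  }
  seed <- as.integer(cli_opt(args, "--seed", "1"))
  steps <- cli_opt(args, "--steps")
  prefix <- cli_opt(args, "-o", sub("\\.ya?ml$", "", pos[1]))
  message("seed: ", seed)
  traj <- run_fixture(sys, seed = seed,
                      n_steps = if (is.null(steps)) NULL else as.integer(steps))
  write_xyz(traj, paste0(prefix, ".xyz"))
  write_energies_csv(traj, paste0(prefix, "_energies.csv"))
  write_terms_csv(traj, paste0(prefix, "_terms.csv"))
  message("wrote ", prefix, ".xyz / _energies.csv / _terms.csv")
  0L
}

cli_analyze <- function(args) {
  pos <- cli_positional(args)
  if (length(pos) < 1) stop("analyze: which terms CSV?", call. = FALSE)
  tab <- read.csv(pos[1])
  need <- c("frame", "time", "term", "i", "j", "r")
  if (!all(need %in% names(tab))) {
    stop("analyze: not a terms CSV (need columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  }
  r_on <- as.numeric(cli_opt(args, "--r-on", "2.4"))
  r_off <- as.numeric(cli_opt(args, "--r-off", "4"))
  if (!(r_off > r_on)) stop("analyze: need r_off > r_on", call. = FALSE)
  ev_all <- list()
  for (tm in unique(tab$term)) {
    sub <- tab[tab$term == tm, ]
    sub <- sub[order(sub$frame), ]
    bound <- FALSE
    for (f in seq_len(nrow(sub))) {
      if (!bound && sub$r[f] < r_on) {
        bound <- TRUE
        ev_all[[length(ev_all) + 1L]] <- data.frame(
          term = tm, i = sub$i[f], j = sub$j[f], kind = "formed",
          time = sub$time[f], frame = sub$frame[f])
      } else if (bound && sub$r[f] > r_off) {
        bound <- FALSE
        ev_all[[length(ev_all) + 1L]] <- data.frame(
          term = tm, i = sub$i[f], j = sub$j[f], kind = "broken",
          time = sub$time[f], frame = sub$frame[f])
      }
    }
    occ <- mean(sub$r < r_on)
    cat(sprintf("occupancy %-12s (r < %g): %.4f\n", tm, r_on, occ))
  }
  out <- sub("\\.csv$", "_events.csv", pos[1])
  ev <- if (length(ev_all)) do.call(rbind, ev_all) else
    data.frame(term = character(), i = integer(), j = integer(),
               kind = character(), time = numeric(), frame = integer())
  ev <- ev[order(ev$time), ]
  write.csv(ev, out, row.names = FALSE)
  message("wrote ", out, " (", nrow(ev), " events)")
  0L
}

cli_check <- function(args) {
  pos <- cli_positional(args)
  if (length(pos) < 1) stop("check: which config?", call. = FALSE)
  sys <- read_run_config(pos[1])
  seed <- as.integer(cli_opt(args, "--seed", "1"))
  x <- random_initial_config(sys, seed = seed)
  err <- force_fd_error(sys, x)
  en <- total_energy(sys, x)
  cat(sprintf("particles: %d  terms: %d  total U at start: %.6f\n",
              sys$n_particles, length(sys$terms), en$total))
  cat("per-term switch values at the random start:\n")
  print(en$terms[, c("label", "r", "S", "phi", "energy")], digits = 4)
  cat(sprintf("max relative force error vs finite differences: %.3g\n", err))
  if (err < 1e-6) {
    cat("gradient audit: PASS\n"); 0L
  } else {
    cat("gradient audit: FAIL\n"); 1L
  }
}

#' Relative error of analytic forces against central finite differences
#'
#' Audit utility used by the `check` subcommand and the test suite:
#' compares full-mode forces with a central finite-difference gradient of
#' the total energy.
#'
#' @param system A `pp_system`.
#' @param x Configuration.
#' @param h Finite-difference step.
#' @return Maximum elementwise error scaled by the force magnitude.
#' @export
force_fd_error <- function(system, x, h = 1e-5) {
  f <- forces(system, x, mode = "full")
  fd <- matrix(0, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) {
    for (k in seq_len(ncol(f))) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      fd[i, k] <- -(total_energy(system, xp, breakdown = FALSE) -
                    total_energy(system, xm, breakdown = FALSE)) / (2 * h)
    }
  }
  scale <- max(abs(f), 1)
  max(abs(f - fd)) / scale
}
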