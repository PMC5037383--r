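# Independent brute-force oracle for the switched N-body potential: written
# from scratch against the definitions, sharing no code with the package's
# evaluation paths (closed forms re-derived, recursion re-implemented).

oracle_h <- function(r, alpha, n) {
  if (alpha == 0) return(0)
  if (is.infinite(alpha)) return(1)
  1 / (1 + (r / alpha)^(2 * n))
}

oracle_dist <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))

# evaluates either a pp_logic (crisp) or pp_encoding (smooth) tree
oracle_tree <- function(e, x, smooth) {
  k <- e$kind
  if (k == "const") return(e$value)
  if (k == "near") {
    r <- oracle_dist(x, e$pair[1], e$pair[2])
    if (smooth) return(oracle_h(r, e$alpha, e$n))
    return(as.numeric(r < e$R))
  }
  if (k == "not") return(1 - oracle_tree(e$arg, x, smooth))
  vals <- vapply(e$args, oracle_tree, 0, x = x, smooth = smooth)
  if (k == "and") return(prod(vals))
  if (k == "or") return(1 - prod(1 - vals))
  stop("bad node")
}

oracle_phi <- function(pot, r) {
  p <- pot$params
  if (pot$kind == "morse") {
    u <- 1 - exp(-p$a * (r - p$r_eq))
    return(p$D * u^2 - p$D)
  }
  if (pot$kind == "repulsive_morse") {
    if (r >= p$r_eq) return(0)
    u <- 1 - exp(-p$a * (r - p$r_eq))
    return(p$D * u^2)
  }
  if (pot$kind == "harmonic") return(p$k / 2 * (r - p$r0)^2)
  stop("oracle only covers closed-form potentials")
}

# literal re-summation of the approximate potential
oracle_energy <- function(system, x) {
  u <- 0
  for (e in system$entities) {
    for (b in e$bonds) {
      u <- u + b$k / 2 * (oracle_dist(x, b$pair[1], b$pair[2]) - b$r0)^2
    }
  }
  for (tm in system$terms) {
    S <- oracle_tree(tm$encoding, x, smooth = TRUE)
    r <- oracle_dist(x, tm$pair[1], tm$pair[2])
    u <- u + S * oracle_phi(tm$potential, r)
  }
  cf <- system$confinement
  if (!is.null(cf)) {
    for (i in seq_len(nrow(x))) {
      rad <- sqrt(sum((x[i, ] - cf$center)^2))
      if (rad > cf$radius) u <- u + cf$k / 2 * (rad - cf$radius)^2
    }
  }
  u
}

# central finite differences of a scalar field over configurations
fd_gradient <- function(f, x, h = 1e-5) {
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (k in seq_len(ncol(x))) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      g[i, k] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  g
}
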