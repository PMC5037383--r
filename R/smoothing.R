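# Smoothing of proximity indicators: the replacement procedure turning
# {0,1}-valued interaction logic into smooth [0,1]-valued encoding functions.

#' Smoothed proximity function h
#'
#' The smooth stand-in for the proximity indicator `chi_[0,R)`:
#' \deqn{h_{\alpha,n}(r) = \frac{1}{1 + (r^2/\alpha^2)^n}}
#' for `0 < alpha < Inf`, with the degenerate members `h_{0,n} == 0` and
#' `h_{Inf,n} == 1`.  `alpha` sets the transition point and `n` the sharpness:
#' `h(0) = 1`, `h(alpha) = 1/2` for every `n >= 1`, the function is strictly
#' decreasing and tends to 0 at infinity, and the 1-to-0 transition sharpens
#' as `n` grows.  Because it depends on `r` only through `r^2`, it is a
#' smooth function of Cartesian coordinates even at coincidence (zero distance).
#' To smooth a predicate with threshold `R`, take `alpha = R`.
#'
#' @param r Non-negative distance(s).
#' @param alpha Transition point, `0 <= alpha <= Inf` (length units).
#' @param n Sharpness exponent, integer `>= 1`.
#' @return Value(s) in `[0, 1]`.
#' @examples
#' smooth_h(0, alpha = 2, n = 3)   # 1
#' smooth_h(2, alpha = 2, n = 7)   # 1/2 at the transition point, any n
#' smooth_h(4, alpha = 2, n = 1)   # 1/(1 + 2^2) = 0.2
#' @export
smooth_h <- function(r, alpha, n) {
  check_smooth_args(r, alpha, n)
  if (alpha == 0) return(rep(0, length(r)))
  if (is.infinite(alpha)) return(rep(1, length(r)))
  s <- (r * r) / (alpha * alpha)
  1 / (1 + s^n)
}

#' Derivative of the smoothed proximity function
#'
#' `dh/dr` for [smooth_h()]: non-positive everywhere, zero at the origin and for
#' the degenerate `alpha` values.  Needed by the force evaluation, where the
#' chain rule pulls this factor through every smoothed leaf.
#'
#' @inheritParams smooth_h
#' @return Derivative value(s), `<= 0`.
#' @export
smooth_h_grad <- function(r, alpha, n) {
  check_smooth_args(r, alpha, n)
  if (alpha == 0 || is.infinite(alpha)) return(rep(0, length(r)))
  s <- (r * r) / (alpha * alpha)
  t <- s^n
  # d/dr [1/(1+s^n)] with s = r^2/alpha^2; s^(n-1) is finite at r = 0 for n >= 1
  -(2 * n * r / (alpha * alpha)) * s^(n - 1) / (1 + t)^2
}

check_smooth_args <- function(r, alpha, n) {
  if (any(is.na(r)) || any(r < 0)) {
    stop("smooth_h(): distances must be non-negative", call. = FALSE)
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("smooth_h(): alpha must be a single value in [0, Inf]", call. = FALSE)
  }
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("smooth_h(): n must be an integer >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- encoding expressions --------------------------------------------------

new_encoding <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "pp_encoding")
}

is_encoding <- function(x) inherits(x, "pp_encoding")

#' Compile a logic expression into a smooth encoding function
#'
#' The replacement procedure: every elementary predicate `near(i, j, R)` in
#' the rule becomes a smoothed leaf `h_{alpha,n}(r_ij)` with `alpha = R`
#' (optionally overridden), while constants and the tree shape are preserved
#' and the connectives keep their algebraic forms (`a*b`, `a+b-a*b`, `1-a`),
#' which map smooth leaves to a smooth whole.  The result takes values in
#' `[0, 1]` on every configuration and converges pointwise to the original
#' logic as `n -> Inf` (away from the threshold surfaces, where it takes the
#' regularizing value 1/2).
#'
#' @param expr A `pp_logic` expression.
#' @param n Default sharpness exponent for every leaf (integer `>= 1`).
#' @param overrides Optional list of per-leaf overrides; each element is a
#'   list with `pair = c(i, j)` and any of `n`, `alpha`, applied to all
#'   leaves on that pair.
#' @return An object of class `pp_encoding` with the same tree shape.
#' @examples
#' S <- smooth_logic(lg_not(lg_near(2, 5, 3)), n = 6)
#' @export
smooth_logic <- function(expr, n = 6L, overrides = list()) {
  stopifnot(is_logic(expr))
  walk <- function(e) {
    switch(e$kind,
      const = new_encoding("const", value = e$value),
      near  = {
        alpha <- e$R; nn <- n
        for (ov in overrides) {
          p <- canonical_pair(ov$pair[1], ov$pair[2])
          if (all(p == e$pair)) {
            if (!is.null(ov$alpha)) alpha <- ov$alpha
            if (!is.null(ov$n)) nn <- ov$n
          }
        }
        check_smooth_args(0, alpha, nn)
        new_encoding("near", pair = e$pair, alpha = alpha, n = as.integer(nn))
      },
      not   = new_encoding("not", arg = walk(e$arg)),
      and   = new_encoding("and", args = lapply(e$args, walk)),
      or    = new_encoding("or",  args = lapply(e$args, walk)),
      stop("malformed logic node", call. = FALSE)
    )
  }
  walk(expr)
}

#' @export
print.pp_encoding <- function(x, ...) {
  dp <- function(e) {
    switch(e$kind,
      const = format(e$value),
      near  = sprintf("h(%d,%d; alpha=%g, n=%d)", e$pair[1], e$pair[2], e$alpha, e$n),
      not   = sprintf("not(%s)", dp(e$arg)),
      and   = sprintf("and(%s)", paste(vapply(e$args, dp, ""), collapse = ", ")),
      or    = sprintf("or(%s)",  paste(vapply(e$args, dp, ""), collapse = ", "))
    )
  }
  cat("<encoding> ", dp(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate an encoding function on a configuration
#'
#' Recursive evaluation with each smoothed leaf at `h_{alpha,n}(r_ij)` and the
#' algebraic connectives on real values.  Because each connective maps
#' `[0,1] x [0,1]` into `[0,1]`, the result is guaranteed to lie in `[0,1]`.
#'
#' @param enc A `pp_encoding` expression.
#' @param x Configuration matrix (`N x d`).
#' @return A value in `[0, 1]`.
#' @export
encoding_eval <- function(enc, x) {
  stopifnot(is_encoding(enc))
  x <- as_config(x)
  ev <- function(e) {
    switch(e$kind,
      const = e$value,
      near  = smooth_h(pair_distance(x, e$pair[1], e$pair[2]), e$alpha, e$n),
      not   = 1 - ev(e$arg),
      and   = Reduce(function(a, b) a * b, vapply(e$args, ev, 0)),
      or    = Reduce(function(a, b) a + b - a * b, vapply(e$args, ev, 0)),
      stop("malformed encoding node", call. = FALSE)
    )
  }
  ev(enc)
}

#' Gradient of an encoding function with respect to particle positions
#'
#' Chain rule through the expression tree: a reverse sweep accumulates the
#' sensitivity of the root to each smoothed leaf, and each leaf contributes
#' `dh/dr` times the unit separation vector to its two particles.  Particles
#' not referenced by any leaf get zero rows, and the rows always sum to the
#' zero vector (the encoding depends on relative distances only).  Exactly
#' coincident leaf particles have a vanishing `dh/dr` under this leaf form,
#' so their contribution is zero without special-casing.
#'
#' @param enc A `pp_encoding` expression.
#' @param x Configuration matrix (`N x d`).
#' @return An `N x d` matrix of partial derivatives.
#' @export
encoding_grad <- function(enc, x) {
  stopifnot(is_encoding(enc))
  x <- as_config(x)
  g <- matrix(0, nrow(x), ncol(x))
  # returns the node value; 'adj' is d(root)/d(node)
  sweep <- function(e, adj) {
    switch(e$kind,
      const = e$value,
      near  = {
        dx <- x[e$pair[1], ] - x[e$pair[2], ]
        r <- sqrt(sum(dx * dx))
        h <- smooth_h(r, e$alpha, e$n)
        dh <- smooth_h_grad(r, e$alpha, e$n)
        if (r > 0 && dh != 0) {
          u <- dx / r
          g[e$pair[1], ] <<- g[e$pair[1], ] + adj * dh * u
          g[e$pair[2], ] <<- g[e$pair[2], ] - adj * dh * u
        }
        h
      },
      not   = 1 - sweep(e$arg, -adj),
      and   = {
        vals <- vapply(e$args, function(a) encoding_eval_node(a, x), 0)
        prod_all <- prod(vals)
        for (k in seq_along(e$args)) {
          others <- prod(vals[-k])
          sweep(e$args[[k]], adj * others)
        }
        prod_all
      },
      or    = {
        # a OR b = 1 - prod(1 - v_k); d/dv_k = prod_{m != k} (1 - v_m)
        vals <- vapply(e$args, function(a) encoding_eval_node(a, x), 0)
        compl <- 1 - vals
        for (k in seq_along(e$args)) {
          others <- prod(compl[-k])
          sweep(e$args[[k]], adj * others)
        }
        1 - prod(compl)
      },
      stop("malformed encoding node", call. = FALSE)
    )
  }
  sweep(enc, 1)
  g
}

encoding_eval_node <- function(e, x) {
  switch(e$kind,
    const = e$value,
    near  = smooth_h(pair_distance(x, e$pair[1], e$pair[2]), e$alpha, e$n),
    not   = 1 - encoding_eval_node(e$arg, x),
    and   = prod(vapply(e$args, encoding_eval_node, 0, x = x)),
    or    = 1 - prod(1 - vapply(e$args, encoding_eval_node, 0, x = x))
  )
}
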