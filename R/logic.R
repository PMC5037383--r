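#' @useDynLib progpot, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats integrate rnorm runif setNames splinefun
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

# ---- proximity predicates -------------------------------------------------

#' Proximity indicator chi_[0,R)
#'
#' The elementary building block of all interaction logic: the indicator of
#' the half-open interval `[0, R)`.  Returns 1 when `0 <= r < R` and 0
#' otherwise; the comparison is strict, so a distance exactly equal to `R` gives 0.  The degenerate
#' thresholds are honoured exactly: `R = 0` is identically 0 and `R = Inf`
#' identically 1.
#'
#' @param r Non-negative distance(s).
#' @param R Threshold, `0 <= R <= Inf`.
#' @return Integer vector of 0/1 values, same length as `r`.
#' @examples
#' proximity(c(0.5, 1, 7.3), R = 1)
#' proximity(2, R = Inf)
#' @export
proximity <- function(r, R) {
  if (any(!is.finite(r) | r < 0)) {
    stop("proximity(): distances must be finite and non-negative", call. = FALSE)
  }
  if (length(R) != 1L || is.na(R) || R < 0) {
    stop("proximity(): threshold R must be a single value in [0, Inf]", call. = FALSE)
  }
  as.integer(r < R)
}

# ---- logic expression trees -----------------------------------------------

canonical_pair <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != 1L || length(j) != 1L || is.na(i) || is.na(j)) {
    stop("a pair needs exactly two particle indices", call. = FALSE)
  }
  if (i == j) stop("a pair must join two distinct particles", call. = FALSE)
  if (i < 1L || j < 1L) stop("particle indices start at 1", call. = FALSE)
  c(min(i, j), max(i, j))
}

new_logic <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "pp_logic")
}

#' Logic expression constructors
#'
#' Interaction rules are finite expression trees over elementary proximity
#' predicates.  `lg_near(i, j, R)` is the predicate "particles `i` and `j`
#' are closer than `R`"; `lg_and`/`lg_or` take any number of sub-expressions
#' (folded left over the binary forms, which are associative); `lg_not`
#' negates; `lg_const` is the constant 0 or 1.  On 0/1 values the connectives
#' are the algebraic forms `a AND b = a*b`, `a OR b = a + b - a*b`,
#' `NOT a = 1 - a`, chosen because they stay smooth after the replacement
#' procedure (see [smooth_logic()]).
#'
#' Pairs are stored unordered (sorted), so `lg_near(5, 2, R)` and
#' `lg_near(2, 5, R)` are the same predicate.
#'
#' @param i,j Particle indices (1-based, distinct).
#' @param R Proximity threshold, `0 <= R <= Inf`.
#' @param x For `lg_const`, 0 or 1; for `lg_not`, a logic expression.
#' @param ... Logic expressions (at least one).
#' @return An object of class `pp_logic`.
#' @examples
#' L23 <- lg_not(lg_or(lg_near(2, 5, 3), lg_near(3, 6, 3)))
#' @name logic-constructors
NULL

#' @rdname logic-constructors
#' @export
lg_near <- function(i, j, R) {
  if (length(R) != 1L || is.na(R) || R < 0) {
    stop("lg_near(): threshold R must be a single value in [0, Inf]", call. = FALSE)
  }
  new_logic("near", pair = canonical_pair(i, j), R = as.numeric(R))
}

#' @rdname logic-constructors
#' @export
lg_const <- function(x) {
  if (!x %in% c(0, 1)) stop("lg_const(): value must be 0 or 1", call. = FALSE)
  new_logic("const", value = as.numeric(x))
}

#' @rdname logic-constructors
#' @export
lg_and <- function(...) {
  args <- check_logic_args(list(...), "lg_and")
  new_logic("and", args = args)
}

#' @rdname logic-constructors
#' @export
lg_or <- function(...) {
  args <- check_logic_args(list(...), "lg_or")
  new_logic("or", args = args)
}

#' @rdname logic-constructors
#' @export
lg_not <- function(x) {
  if (!inherits(x, "pp_logic")) stop("lg_not(): argument must be a logic expression", call. = FALSE)
  new_logic("not", arg = x)
}

check_logic_args <- function(args, fn) {
  if (length(args) < 1L) stop(fn, "(): needs at least one argument", call. = FALSE)
  ok <- vapply(args, inherits, logical(1), what = "pp_logic")
  if (!all(ok)) stop(fn, "(): all arguments must be logic expressions", call. = FALSE)
  args
}

is_logic <- function(x) inherits(x, "pp_logic")

#' @export
print.pp_logic <- function(x, ...) {
  cat("<logic> ", deparse_logic(x), "\n", sep = "")
  invisible(x)
}

#' Render a logic expression as prefix text
#'
#' Produces the textual form used in run-config files, e.g.
#' `not(or(near(2,5,3), near(3,6,3)))`.  Inverse of [parse_logic()].
#'
#' @param expr A `pp_logic` expression.
#' @return A character scalar.
#' @export
deparse_logic <- function(expr) {
  stopifnot(is_logic(expr))
  switch(expr$kind,
    const = format(expr$value),
    near  = sprintf("near(%d,%d,%s)", expr$pair[1], expr$pair[2],
                    format(expr$R, digits = 15)),
    not   = sprintf("not(%s)", deparse_logic(expr$arg)),
    and   = sprintf("and(%s)", paste(vapply(expr$args, deparse_logic, ""), collapse = ", ")),
    or    = sprintf("or(%s)",  paste(vapply(expr$args, deparse_logic, ""), collapse = ", ")),
    stop("malformed logic node", call. = FALSE)
  )
}

#' Parse a prefix logic expression
#'
#' Reads the textual rule format of run-config files: `near(i,j,R)` for an
#' elementary proximity predicate, `and(...)`, `or(...)`, `not(...)` for the
#' connectives and `0`/`1` for constants.  `Inf` is accepted as a threshold.
#'
#' @param text A character scalar.
#' @return A `pp_logic` expression.
#' @examples
#' parse_logic("not(or(near(2,5,3), near(3,6,3)))")
#' @export
parse_logic <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ast <- tryCatch(str2lang(text), error = function(e) {
    stop("parse_logic(): cannot parse '", text, "': ", conditionMessage(e), call. = FALSE)
  })
  build_logic_ast(ast)
}

build_logic_ast <- function(node) {
  if (is.numeric(node)) return(lg_const(node))
  if (!is.call(node)) stop("parse_logic(): unexpected token '", deparse(node), "'", call. = FALSE)
  head <- as.character(node[[1]])
  args <- as.list(node)[-1]
  switch(head,
    near = {
      if (length(args) != 3L) stop("near() takes (i, j, R)", call. = FALSE)
      vals <- lapply(args, function(a) eval(a, baseenv()))
      lg_near(vals[[1]], vals[[2]], vals[[3]])
    },
    and = do.call(lg_and, lapply(args, build_logic_ast)),
    or  = do.call(lg_or,  lapply(args, build_logic_ast)),
    not = {
      if (length(args) != 1L) stop("not() takes one argument", call. = FALSE)
      lg_not(build_logic_ast(args[[1]]))
    },
    stop("parse_logic(): unknown operator '", head, "'", call. = FALSE)
  )
}

# ---- evaluation ------------------------------------------------------------

#' Distance between two particles of a configuration
#'
#' @param x Configuration: an `N x d` numeric matrix of positions.
#' @param i,j Particle indices.
#' @return Euclidean distance.
#' @export
pair_distance <- function(x, i, j) {
  x <- as_config(x)
  n <- nrow(x)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) {
    stop("pair_distance(): particle index out of range [1, ", n, "]", call. = FALSE)
  }
  sqrt(sum((x[i, ] - x[j, ])^2))
}

as_config <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("configuration must be a finite numeric matrix (N x d)", call. = FALSE)
  }
  x
}

#' Evaluate a logic expression on a configuration
#'
#' Recursively evaluates the Boolean expression: each `near(i, j, R)` leaf is
#' the proximity indicator of the Euclidean distance between particles `i`
#' and `j`, and the connectives use the algebraic 0/1 forms.  The result is
#' exactly 0 or 1.
#'
#' @param expr A `pp_logic` expression.
#' @param x Configuration matrix (`N x d`).
#' @return 0 or 1.
#' @examples
#' x <- rbind(c(0, 0), c(0.4, 0))
#' logic_eval(lg_near(1, 2, 1), x)
#' @export
logic_eval <- function(expr, x) {
  stopifnot(is_logic(expr))
  x <- as_config(x)
  ev <- function(e) {
    switch(e$kind,
      const = e$value,
      near  = as.numeric(proximity(pair_distance(x, e$pair[1], e$pair[2]), e$R)),
      not   = 1 - ev(e$arg),
      and   = Reduce(function(a, b) a * b, vapply(e$args, ev, 0)),
      or    = Reduce(function(a, b) a + b - a * b, vapply(e$args, ev, 0)),
      stop("malformed logic node", call. = FALSE)
    )
  }
  ev(expr)
}

#' Collect the elementary leaves of a logic or encoding expression
#'
#' @param expr A `pp_logic` or `pp_encoding` expression.
#' @return A data.frame with columns `i`, `j` and `R` (threshold, or the
#'   smoothing transition point `alpha` for encoding trees), one row per
#'   elementary leaf in depth-first order.
#' @export
logic_leaves <- function(expr) {
  rows <- list()
  walk <- function(e) {
    switch(e$kind,
      const = NULL,
      near  = rows[[length(rows) + 1L]] <<- data.frame(
        i = e$pair[1], j = e$pair[2],
        R = if (!is.null(e$R)) e$R else e$alpha),
      not   = walk(e$arg),
      and   = ,
      or    = lapply(e$args, walk),
      stop("malformed logic node", call. = FALSE)
    )
    invisible(NULL)
  }
  walk(expr)
  if (length(rows) == 0L) {
    return(data.frame(i = integer(), j = integer(), R = numeric()))
  }
  do.call(rbind, rows)
}

#' Check that a rule does not reference its own pair
#'
#' The switching rule attached to a pairwise potential must not depend on the
#' distance of the very pair it switches: the rule for the potential between
#' particles 2 and 3 cannot contain `near(2, 3, .)`.  This validator returns
#' a report rather than throwing, so callers can present all violations.
#'
#' @param expr A `pp_logic` (or `pp_encoding`) expression.
#' @param owner The pair owning the potential, as `c(i, j)`.
#' @return A list with class `pp_validation`: `ok` (logical) and
#'   `violations`, a data.frame of offending leaves (columns `i`, `j`, `R`).
#' @examples
#' validate_logic(lg_not(lg_near(2, 5, 3)), owner = c(2, 3))$ok
#' @export
validate_logic <- function(expr, owner) {
  stopifnot(is_logic(expr) || inherits(expr, "pp_encoding"))
  owner <- canonical_pair(owner[1], owner[2])
  leaves <- logic_leaves(expr)
  bad <- leaves[leaves$i == owner[1] & leaves$j == owner[2], , drop = FALSE]
  structure(list(ok = nrow(bad) == 0L, owner = owner, violations = bad),
            class = "pp_validation")
}

#' @export
print.pp_validation <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("rule for pair (%d,%d): ok\n", x$owner[1], x$owner[2]))
  } else {
    cat(sprintf("rule for pair (%d,%d): %d self-referential leaf/leaves:\n",
                x$owner[1], x$owner[2], nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

# ---- truth tables ----------------------------------------------------------

leaf_key <- function(i, j, R) sprintf("%d:%d:%.12g", i, j, R)

#' Truth table of logic expressions over named conditions
#'
#' Enumerates all `2^k` assignments of the given elementary conditions and
#' evaluates each expression symbolically by substituting the condition bits
#' for the matching `near()` leaves.  Rows are ordered by binary counting on
#' the condition columns (first condition is the most significant bit), the
#' order in which such tables are conventionally printed.
#'
#' @param exprs Named list of `pp_logic` expressions.
#' @param conditions Named list of elementary predicates (`lg_near` leaves);
#'   every leaf of every expression must match one of them (same pair and
#'   threshold).
#' @return A data.frame: one 0/1 column per condition, then one 0/1 column
#'   per expression.
#' @examples
#' tt <- truth_table(
#'   list(L23 = lg_not(lg_or(lg_near(2, 5, 3), lg_near(3, 6, 3)))),
#'   list(c25 = lg_near(2, 5, 3), c36 = lg_near(3, 6, 3)))
#' @export
truth_table <- function(exprs, conditions) {
  stopifnot(is.list(exprs), is.list(conditions),
            length(exprs) > 0L, length(conditions) > 0L)
  if (is.null(names(exprs)) || any(names(exprs) == "")) {
    stop("truth_table(): exprs must be a named list", call. = FALSE)
  }
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("truth_table(): conditions must be a named list", call. = FALSE)
  }
  cond_ok <- vapply(conditions, function(c) is_logic(c) && c$kind == "near", TRUE)
  if (!all(cond_ok)) stop("truth_table(): conditions must be lg_near() leaves", call. = FALSE)
  keys <- vapply(conditions, function(c) leaf_key(c$pair[1], c$pair[2], c$R), "")
  if (anyDuplicated(keys)) stop("truth_table(): duplicate conditions", call. = FALSE)

  for (nm in names(exprs)) {
    lv <- logic_leaves(exprs[[nm]])
    if (nrow(lv)) {
      lk <- leaf_key(lv$i, lv$j, lv$R)
      miss <- setdiff(lk, keys)
      if (length(miss)) {
        stop("truth_table(): expression '", nm,
             "' references predicates absent from the conditions: ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
  }

  k <- length(conditions)
  n_rows <- 2L^k
  sub_eval <- function(e, bits) {
    switch(e$kind,
      const = e$value,
      near  = bits[[leaf_key(e$pair[1], e$pair[2], e$R)]],
      not   = 1 - sub_eval(e$arg, bits),
      and   = Reduce(function(a, b) a * b,
                     vapply(e$args, sub_eval, 0, bits = bits)),
      or    = Reduce(function(a, b) a + b - a * b,
                     vapply(e$args, sub_eval, 0, bits = bits))
    )
  }
  out <- matrix(0L, n_rows, k + length(exprs),
                dimnames = list(NULL, c(names(conditions), names(exprs))))
  for (row in seq_len(n_rows)) {
    # binary counting: first condition = most significant bit
    bits_vec <- as.integer(intToBits(row - 1L))[k:1]
    bits <- setNames(as.list(as.numeric(bits_vec)), keys)
    out[row, seq_len(k)] <- bits_vec
    for (m in seq_along(exprs)) {
      out[row, k + m] <- as.integer(sub_eval(exprs[[m]], bits))
    }
  }
  as.data.frame(out)
}
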