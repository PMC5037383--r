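test_that("proximity indicator is the half-open interval [0, R)", {
  expect_identical(proximity(0.5, 1), 1L)
  expect_identical(proximity(1, 1), 0L)       # tie is outside, strictly
  expect_identical(proximity(7.3, Inf), 1L)
  expect_identical(proximity(c(0, 2.999, 3), 3), c(1L, 1L, 0L))
  expect_identical(proximity(5, 0), 0L)       # R = 0 is identically 0
  expect_error(proximity(-0.1, 1), "non-negative")
  expect_error(proximity(1, -2), "R must be")
})

test_that("elementary predicates use Euclidean distance and index checks", {
  x <- matrix(0, 6, 2)
  x[2, ] <- c(0, 0); x[5, ] <- c(0.4, 0)
  expect_equal(logic_eval(lg_near(2, 5, 1), x), 1)
  expect_equal(logic_eval(lg_near(2, 5, 0.3), x), 0)
  expect_equal(logic_eval(lg_near(2, 5, Inf), x), 1)
  expect_error(logic_eval(lg_near(2, 9, 1), x), "out of range")
  expect_error(lg_near(3, 3, 1), "distinct")
})

test_that("pairs are canonicalized: order of indices never matters", {
  x <- matrix(rnorm(12), 6, 2)
  expect_identical(lg_near(5, 2, 1.5), lg_near(2, 5, 1.5))
  expect_equal(logic_eval(lg_near(5, 2, 1.5), x),
               logic_eval(lg_near(2, 5, 1.5), x))
})

test_that("connectives obey the Boolean truth tables on constants", {
  x <- matrix(0, 2, 2)
  expect_equal(logic_eval(lg_not(lg_const(1)), x), 0)
  tt <- expand.grid(a = 0:1, b = 0:1)
  for (k in seq_len(nrow(tt))) {
    a <- lg_const(tt$a[k]); b <- lg_const(tt$b[k])
    expect_equal(logic_eval(lg_and(a, b), x), as.numeric(tt$a[k] & tt$b[k]))
    expect_equal(logic_eval(lg_or(a, b), x), as.numeric(tt$a[k] | tt$b[k]))
  }
})

test_that("idempotence, commutativity and De Morgan hold on all assignments", {
  x_for <- function(bits) {
    # realize predicate values: pair (1,2) close iff bits[1], (3,4) iff bits[2]
    x <- matrix(0, 4, 2)
    x[2, ] <- c(if (bits[1]) 0.5 else 5, 0)
    x[3, ] <- c(0, 10); x[4, ] <- c(if (bits[2]) 0.2 else 8, 10)
    x
  }
  p <- lg_near(1, 2, 1); q <- lg_near(3, 4, 1)
  for (a in 0:1) for (b in 0:1) {
    x <- x_for(c(a, b))
    expect_equal(logic_eval(lg_and(p, p), x), logic_eval(p, x))
    expect_equal(logic_eval(lg_or(p, p), x), logic_eval(p, x))
    expect_equal(logic_eval(lg_and(p, q), x), logic_eval(lg_and(q, p), x))
    expect_equal(logic_eval(lg_or(p, q), x), logic_eval(lg_or(q, p), x))
    expect_equal(logic_eval(lg_not(lg_and(p, q)), x),
                 logic_eval(lg_or(lg_not(p), lg_not(q)), x))
    expect_equal(logic_eval(lg_not(lg_or(p, q)), x),
                 logic_eval(lg_and(lg_not(p), lg_not(q)), x))
    # algebraic forms coincide with min/max on {0,1}
    expect_equal(logic_eval(lg_and(p, q), x),
                 min(logic_eval(p, x), logic_eval(q, x)))
    expect_equal(logic_eval(lg_or(p, q), x),
                 max(logic_eval(p, x), logic_eval(q, x)))
  }
})

test_that("logic value is constant between threshold crossings", {
  set.seed(41)
  expr <- lg_not(lg_or(lg_near(1, 3, 2), lg_and(lg_near(2, 4, 3),
                                                lg_near(1, 4, 1.5))))
  for (rep in 1:50) {
    x <- matrix(runif(8, -4, 4), 4, 2)
    v0 <- logic_eval(expr, x)
    # margin to the nearest threshold surface over the expression's leaves
    lv <- logic_leaves(expr)
    margin <- min(abs(mapply(function(i, j, R) {
      sqrt(sum((x[i, ] - x[j, ])^2)) - R
    }, lv$i, lv$j, lv$R)))
    eps <- 0.4 * margin / (2 * sqrt(2))  # displacement bound per coordinate
    x2 <- x + matrix(runif(8, -eps, eps), 4, 2)
    expect_equal(logic_eval(expr, x2), v0)
  }
})

test_that("self-reference validation reports the offending leaves", {
  good <- lg_not(lg_or(lg_near(2, 5, 3), lg_near(3, 6, 3)))
  expect_true(validate_logic(good, c(2, 3))$ok)
  bad <- lg_and(lg_near(2, 3, 2), lg_near(2, 5, 3))
  v <- validate_logic(bad, c(2, 3))
  expect_false(v$ok)
  expect_equal(nrow(v$violations), 1)
  expect_equal(v$violations$i, 2)
  expect_equal(v$violations$j, 3)
  expect_true(validate_logic(lg_const(1), c(1, 2))$ok)
  # order of the owner pair irrelevant
  expect_false(validate_logic(bad, c(3, 2))$ok)
})

test_that("truth_table enumerates assignments in binary counting order", {
  lg <- inhibitor_logic()
  tt <- truth_table(lg$exprs, lg$conditions)
  expect_equal(tt$c25, c(0, 0, 1, 1))
  expect_equal(tt$c36, c(0, 1, 0, 1))
  # the inhibitor bond logic table
  expect_equal(tt$L23, c(1, 0, 0, 0))
  expect_equal(tt$L36, c(1, 1, 0, 0))
  expect_equal(tt$L25, c(1, 0, 1, 0))
})

test_that("truth_table rejects expressions over unknown conditions", {
  lg <- inhibitor_logic()
  expect_error(
    truth_table(list(L = lg_near(1, 4, 2)), lg$conditions),
    "absent from the conditions")
})

test_that("the rule parser round-trips through deparse", {
  txts <- c("not(or(near(2,5,3), near(3,6,3)))",
            "and(near(1,2,1.5), not(near(3,4,2)), 1)",
            "or(0, near(1,3,Inf))")
  x <- matrix(runif(12, -3, 3), 6, 2)
  for (txt in txts) {
    e1 <- parse_logic(txt)
    e2 <- parse_logic(deparse_logic(e1))
    expect_equal(logic_eval(e1, x), logic_eval(e2, x))
  }
  expect_error(parse_logic("xor(near(1,2,1), 0)"), "unknown operator")
  expect_error(parse_logic("near(1,2)"), "takes")
})
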