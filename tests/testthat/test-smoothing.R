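test_that("smoothed proximity function satisfies its defining identities", {
  for (alpha in c(0.1, 1, 2, 50, 100)) {
    for (n in 1:10) {
      expect_equal(smooth_h(0, alpha, n), 1)
      expect_equal(smooth_h(alpha, alpha, n), 0.5)
    }
  }
  # degenerate members
  for (r in c(0, 0.7, 3, 1e6)) {
    expect_equal(smooth_h(r, 0, 4), 0)
    expect_equal(smooth_h(r, Inf, 4), 1)
  }
  # monotone decrease (strict where resolvable in double precision;
  # at large n the function is flat to machine epsilon near the origin)
  r <- seq(0, 30, by = 0.05)
  for (n in c(1, 3, 8)) {
    v <- smooth_h(r, 2, n)
    expect_true(all(diff(v) <= 0))
    win <- r >= 0.7 & r <= 6
    expect_true(all(diff(v[win]) < 0))
    # algebraic tail: h ~ (alpha/r)^(2n)
    expect_lt(smooth_h(1e4, 2, n), 1.01 * (2 / 1e4)^(2 * n))
  }
  # direct closed-form evaluation: one transition-width out, n = 1
  expect_equal(smooth_h(4, 2, 1), 0.2)
  expect_error(smooth_h(-1, 2, 3), "non-negative")
  expect_error(smooth_h(1, 2, 0), "n must be")
})

test_that("sharpness n steepens the transition on both sides of alpha", {
  alpha <- 2
  ns <- c(1, 2, 4, 8, 16)
  below <- sapply(ns, function(n) smooth_h(1.5, alpha, n))
  above <- sapply(ns, function(n) smooth_h(2.5, alpha, n))
  expect_true(all(diff(below) > 0))   # closer to 1 below alpha
  expect_true(all(diff(above) < 0))   # closer to 0 above alpha
})

test_that("h derivative matches finite differences and is non-positive", {
  rs <- c(0.3, 1, 1.9, 2, 2.1, 4, 9)
  for (n in c(1, 2, 6)) {
    for (r in rs) {
      fd <- (smooth_h(r + 1e-6, 2, n) - smooth_h(r - 1e-6, 2, n)) / 2e-6
      expect_equal(smooth_h_grad(r, 2, n), fd, tolerance = 1e-6)
    }
  }
  expect_equal(smooth_h_grad(0, 2, 2), 0)
  expect_equal(smooth_h_grad(0, 2, 1), 0)
  expect_true(all(smooth_h_grad(rs, 3, 5) <= 0))
  expect_equal(smooth_h_grad(c(1, 5), Inf, 3), c(0, 0))
})

test_that("smooth_logic preserves tree shape and maps thresholds to alpha", {
  expr <- lg_not(lg_or(lg_near(2, 5, 3), lg_near(3, 6, 2.5)))
  enc <- smooth_logic(expr, n = 4)
  lv <- logic_leaves(enc)
  expect_equal(lv$R, c(3, 2.5))        # alpha = R
  # closed form of the compiled encoding: not(or(a,b)) = (1-a)(1-b)
  x <- matrix(runif(12, -4, 4), 6, 2)
  a <- smooth_h(pair_distance(x, 2, 5), 3, 4)
  b <- smooth_h(pair_distance(x, 3, 6), 2.5, 4)
  expect_equal(encoding_eval(enc, x), (1 - a) * (1 - b))
  # constants survive unchanged
  expect_equal(encoding_eval(smooth_logic(lg_const(1)), x), 1)
  # per-pair overrides
  enc2 <- smooth_logic(expr, n = 4,
                       overrides = list(list(pair = c(2, 5), n = 9, alpha = 1)))
  lv2 <- logic_leaves(enc2)
  expect_equal(lv2$R, c(1, 2.5))
})

test_that("encoding values stay in [0,1] on randomized configurations", {
  set.seed(7)
  for (rep in 1:20) {
    sys <- random_system(seed = 1000 + rep)
    encs <- lapply(sys$terms, `[[`, "encoding")
    for (draw in 1:25) {
      x <- random_config(sys, seed = 5000 + 100 * rep + draw)
      for (enc in encs) {
        v <- encoding_eval(enc, x)
        expect_gte(v, 0)
        expect_lte(v, 1)
      }
    }
  }
})

test_that("encoding converges pointwise to the logic as n grows", {
  expr <- lg_not(lg_or(lg_near(1, 3, 2), lg_and(lg_near(2, 4, 3),
                                                lg_near(1, 4, 1.5))))
  set.seed(12)
  # at n = 1 a compound encoding can sit well away from its sharp limit at
  # 10% distance margin; the point of the ladder is the monotone shrink
  tols <- c(`1` = 0.8, `4` = 0.4, `16` = 0.12, `64` = 0.02)
  for (rep in 1:40) {
    x <- matrix(runif(8, -4, 4), 4, 2)
    lv <- logic_leaves(expr)
    margin <- min(abs(mapply(function(i, j, R) {
      sqrt(sum((x[i, ] - x[j, ])^2)) / R - 1
    }, lv$i, lv$j, lv$R)))
    if (margin < 0.1) next  # configurations near a threshold surface excluded
    target <- logic_eval(expr, x)
    prev_err <- Inf
    for (n in c(1, 4, 16, 64)) {
      err <- abs(encoding_eval(smooth_logic(expr, n = n), x) - target)
      expect_lte(err, tols[[as.character(n)]])
      expect_lte(err, prev_err + 1e-12)
      prev_err <- err
    }
  }
})

test_that("a single smoothed leaf evaluates to 1/2 exactly at r = alpha", {
  for (n in c(1, 2, 5, 9)) {
    enc <- smooth_logic(lg_near(1, 2, 2.5), n = n)
    x <- rbind(c(0, 0), c(2.5, 0))
    expect_equal(encoding_eval(enc, x), 0.5)
  }
})

test_that("encoding gradient matches finite differences on random trees", {
  set.seed(99)
  for (rep in 1:30) {
    sys <- random_system(seed = 4000 + rep)
    x <- random_config(sys, seed = 8000 + rep)
    for (tm in sys$terms) {
      g <- encoding_grad(tm$encoding, x)
      fd <- fd_gradient(function(xx) encoding_eval(tm$encoding, xx), x)
      # relative to the gradient scale, with a floor where the gradient is
      # numerically zero and the FD oracle is pure round-off
      expect_lt(max(abs(g - fd)), 1e-6 * max(max(abs(fd)), 1e-2))
      # translation invariance: rows sum to zero
      expect_equal(colSums(g), rep(0, ncol(x)), tolerance = 1e-12)
    }
  }
})

test_that("particles outside an encoding's leaves get zero gradient rows", {
  enc <- smooth_logic(lg_near(2, 5, 3), n = 6)
  x <- matrix(runif(12, -3, 3), 6, 2)
  g <- encoding_grad(enc, x)
  for (i in c(1, 3, 4, 6)) expect_equal(g[i, ], c(0, 0))
})

test_that("coincident leaf particles give a finite zero gradient", {
  enc <- smooth_logic(lg_near(1, 2, 3), n = 6)
  x <- rbind(c(1, 1), c(1, 1), c(0, 5))
  expect_equal(encoding_eval(enc, x), 1)    # h(0) = 1
  expect_true(all(is.finite(encoding_grad(enc, x))))
  expect_equal(encoding_grad(enc, x), matrix(0, 3, 2))
})
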