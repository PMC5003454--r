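test_that("expit is correct, symmetric and saturation-safe", {
  expect_equal(expit(0), 0.5)
  expect_equal(expit(1), exp(1) / (1 + exp(1)))
  expect_equal(expit(1), 0.7310585786, tolerance = 1e-9)
  expect_equal(expit(800), 1)
  expect_equal(expit(-800), 0)
  x <- seq(-30, 30, length.out = 101)
  expect_equal(expit(x) + expit(-x), rep(1, 101))
})

test_that("parameter counts follow the parsimony ordering", {
  expect_identical(n_params("flat"), 1L)
  expect_identical(n_params("linear"), 2L)
  expect_identical(n_params("sigmoid"), 4L)
  expect_identical(n_params("double_sigmoid"), 6L)
  expect_identical(n_params("gen_double_sigmoid"), 7L)
  expect_identical(n_params("poly3"), 4L)
  expect_identical(n_params("poly7"), 8L)
  counts <- vapply(c("flat", "linear", "sigmoid", "double_sigmoid",
                     "gen_double_sigmoid"), n_params, 1L)
  expect_true(all(diff(counts) > 0))
})

test_that("curve_eval validates arity and the beta != 0 precondition", {
  expect_error(curve_eval("sigmoid", c(1, 2), 1:3), "4 parameters")
  expect_error(curve_eval("double_sigmoid", c(1, 0, 2, 3, 1, 9), 1:3),
               "beta != 0")
  expect_error(curve_eval("flat", numeric(0), 1), "1 parameter")
})

test_that("simple families evaluate as written", {
  expect_equal(curve_eval("flat", 3.5, c(-1, 0, 100)), rep(3.5, 3))
  expect_equal(curve_eval("linear", c(1, 2), c(0, 3)), c(1, 7))
  expect_equal(curve_eval("poly3", c(1, 0, 0, 2), 2), 1 + 2 * 8)
  # sigmoid midpoint: halfway between the steady-state levels at delta
  expect_equal(curve_eval("sigmoid", c(0, 1, 1, 5), 5), 0.5)
  expect_equal(curve_eval("sigmoid", c(2, 1.5, 8, 7), 7), 5)
})

test_that("sigmoid's beta parameter is its maximum slope", {
  p <- c(2, 1.5, 8, 7)
  grid <- seq(0, 14, length.out = 2001)
  expect_equal(max(curve_deriv <- curvecomp:::curve_deriv("sigmoid", p, grid)),
               1.5, tolerance = 1e-6)
  expect_equal(grid[which.max(curve_deriv)], 7, tolerance = 0.01)
})

test_that("double sigmoid attains its printed asymptote levels", {
  set.seed(101)
  for (i in 1:50) {
    a <- runif(1, 0, 10); g <- runif(1, 0, 10)
    b <- runif(1, 0.5, 15) * sample(c(-1, 1), 1)
    d <- runif(1, 2, 6); ph <- d + runif(1, 2, 6)
    e <- runif(1, 0.5, 3)
    p <- c(a, b, g, d, e, ph)
    expect_equal(curve_eval("double_sigmoid", p, d - 50 / e), a,
                 tolerance = 1e-6)
    expect_equal(curve_eval("double_sigmoid", p, ph + 50 / e), g,
                 tolerance = 1e-6)
  }
})

test_that("generalized double sigmoid with lambda = 1 equals double sigmoid", {
  set.seed(102)
  for (i in 1:100) {
    p <- c(runif(1, 0, 10), runif(1, 0.5, 15), runif(1, 0, 10),
           runif(1, 0, 14), runif(1, -3, 3), runif(1, 0, 14))
    xx <- runif(100, -10, 25)
    expect_equal(curve_eval("gen_double_sigmoid", c(p, 1), xx),
                 curve_eval("double_sigmoid", p, xx), tolerance = 1e-12)
  }
})

test_that("the sigmoid curve is monotone in x", {
  set.seed(103)
  for (i in 1:50) {
    p <- c(runif(1, 0, 10), runif(1, -3, 3), runif(1, 0, 10), runif(1, 0, 14))
    if (p[3] == p[1] || p[2] == 0) next
    d <- curvecomp:::curve_deriv("sigmoid", p, seq(-5, 20, length.out = 500))
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
  }
})

test_that("double-sigmoid gauge symmetries describe identical curves", {
  set.seed(104)
  xx <- seq(-5, 20, length.out = 80)
  for (i in 1:50) {
    p <- c(runif(1, 0, 10), runif(1, 0.5, 15), runif(1, 0, 10),
           runif(1, 2, 8), runif(1, 0.3, 3) * sample(c(-1, 1), 1),
           runif(1, 6, 12))
    l <- runif(1, 0.3, 3)
    f_ds <- curve_eval("double_sigmoid", p, xx)
    for (q in dbs_orbit(p)) {
      expect_equal(curve_eval("double_sigmoid", q, xx), f_ds,
                   tolerance = 1e-9)
    }
    f_gds <- curve_eval("gen_double_sigmoid", c(p, l), xx)
    for (q in dbs_orbit(c(p, l))) {
      expect_equal(curve_eval("gen_double_sigmoid", q, xx), f_gds,
                   tolerance = 1e-9)
    }
    can <- canonical_dbs(c(p, l))
    expect_gt(can[["epsilon"]], 0)
    expect_lte(can[["delta"]], can[["phi"]])
  }
})
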