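ctl <- curve_control()

test_that("flat and linear fits classify by slope sign", {
  xr <- c(1, 14)
  expect_equal(classify_fit(exact_fit("flat", 3), xr, ctl)$label, "flat")
  expect_equal(classify_fit(exact_fit("linear", c(1, 2)), xr, ctl)$label, "lineU")
  expect_equal(classify_fit(exact_fit("linear", c(9, -0.5)), xr, ctl)$label, "lineD")
})

test_that("sigmoid fits split into sigmoid/hockey/transition by boundary slopes", {
  xr <- c(1, 14)
  # steep central transition: both boundary slopes ~ 0 -> two steady states
  lab <- classify_fit(exact_fit("sigmoid", c(2, 2, 8, 7)), xr, ctl)
  expect_equal(lab$label, "sigmoidU")
  # transition at the right edge: only the left steady state remains
  lab <- classify_fit(exact_fit("sigmoid", c(2, 2, 8, 13)), xr, ctl)
  expect_equal(lab$label, "hockeyU")
  # slow drift across the whole range: no steady state
  lab <- classify_fit(exact_fit("sigmoid", c(10, -0.4, 0, 7.5)), xr, ctl)
  expect_equal(lab$label, "transitionD")
  # boundary-slope threshold is a knob
  slopes <- abs(curvecomp:::curve_deriv("sigmoid", c(2, 2, 8, 13), xr))
  expect_true(slopes[1] <= 0.10 && slopes[2] > 0.10)  # the hockey pattern
})

test_that("double-sigmoid fits split into impulse and step by interior extrema", {
  xr <- c(1, 14)
  lab <- classify_fit(exact_fit("double_sigmoid", c(2, 9, 3, 4.5, 1.5, 10)), xr, ctl)
  expect_equal(lab$label, "impulseU")
  expect_equal(lab$extremum_x, 7.25, tolerance = 0.5)
  lab <- classify_fit(exact_fit("double_sigmoid", c(9, 2, 8, 4.5, 1.5, 10)), xr, ctl)
  expect_equal(lab$label, "impulseD")
  lab <- classify_fit(exact_fit("double_sigmoid", c(2, 5, 9, 4.5, 1.5, 10)), xr, ctl)
  expect_equal(lab$label, "stepU")
  lab <- classify_fit(exact_fit("gen_double_sigmoid", c(2, 9, 3, 4.5, 1.5, 10, 0.6)), xr, ctl)
  expect_equal(lab$label, "impulse+U")
  lab <- classify_fit(exact_fit("gen_double_sigmoid", c(9, 5, 2, 4.5, 1.5, 10, 1.6)), xr, ctl)
  expect_equal(lab$label, "step+D")
})

test_that("non-converged fits are not classifiable", {
  f <- exact_fit("sigmoid", c(2, 2, 8, 7))
  f$converged <- FALSE
  expect_error(classify_fit(f, c(1, 14), ctl), "converge")
})

test_that("the leeway cutoff is best RPE plus the leeway", {
  expect_equal(leeway_threshold(8, 5), 13)
  expect_equal(leeway_threshold(10.5, 5), 15.5)
  expect_equal(leeway_threshold(7, 0), 7)
  expect_error(leeway_threshold(-1, 5))
})

worked_example <- function(rpes) {
  data.frame(
    label = c("flat", "lineU", "sigmoidU", "impulseU", "impulse+U"),
    shape = c("flat", "line", "sigmoid", "impulse", "impulse+"),
    direction = c("none", "U", "U", "U", "U"),
    n_params = c(1, 2, 4, 6, 7),
    rpe = rpes, stringsAsFactors = FALSE)
}

test_that("selection reproduces both worked examples", {
  # leeway admits lineU and sigmoidU; the fewest-parameter one is reported
  s1 <- select_curves(worked_example(c(30, 12, 11, 8, 9)))
  expect_equal(s1$curve_A$label, "impulseU")
  expect_equal(s1$reported$label, "lineU")
  expect_equal(s1$curve_B$label, "lineU")
  expect_equal(s1$leeway_cutoff, 13)
  # no simpler curve within the leeway; impulseU reported, sigmoidU kept
  # for comparison
  s2 <- select_curves(worked_example(c(30, 22, 14, 8, 9)))
  expect_equal(s2$curve_A$label, "impulseU")
  expect_equal(s2$reported$label, "impulseU")
  expect_null(s2$curve_B)
  expect_equal(s2$comparison$label, "sigmoidU")
})

test_that("no curve is reported when the best RPE exceeds the threshold", {
  s <- select_curves(worked_example(c(30, 25, 18, 12, 16)))
  expect_null(s$reported)
  expect_equal(s$curve_A$label, "impulseU")
  # boundary: RPE exactly at the threshold still counts as a good fit
  s10 <- select_curves(worked_example(c(30, 25, 18, 10, 16)))
  expect_equal(s10$reported$label, "impulseU")
})

test_that("selection agrees with the brute-force algorithm on random tables", {
  set.seed(401)
  for (i in 1:3000) {
    cand <- random_candidates()
    got <- select_curves(cand)
    want <- select_oracle(cand)
    if (is.na(want$reported)) {
      expect_null(got$reported)
    } else {
      expect_equal(got$reported$label, want$reported)
    }
    expect_equal(got$curve_A$label, want$A)
  }
})

test_that("high-degree polynomial controls never pay off at held-out points", {
  syn <- synth_expression(40, noise_sd = 0.12, seed = 405)
  ctl_poly <- curve_control(include_polynomials = TRUE)
  for (i in seq_len(40)) {
    g <- fit_gene_curves(syn$x, syn$mat_1[i, ], control = ctl_poly)
    rep <- g$selection$reported
    if (!is.null(rep)) expect_false(grepl("poly[57]", rep$label))
  }
})

test_that("the reported curve obeys the selection invariants", {
  set.seed(402)
  for (i in 1:500) {
    cand <- random_candidates()
    s <- select_curves(cand)
    if (min(cand$rpe) <= 10) {
      expect_false(is.null(s$reported))
      expect_lte(s$reported$rpe, min(cand$rpe) + 5)
      if (!is.null(s$curve_B)) {
        expect_lt(s$curve_B$n_params, s$curve_A$n_params)
      }
    } else {
      expect_null(s$reported)
    }
  }
})
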