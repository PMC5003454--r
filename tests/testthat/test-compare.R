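ctl <- curve_control()
xr <- c(1, 14)

lab_of <- function(fit) classify_fit(fit, xr, ctl)

test_that("characteristic points follow the shape taxonomy", {
  flat <- exact_fit("flat", 3)
  expect_equal(characteristic_points(lab_of(flat), xr), 1)
  sig <- exact_fit("sigmoid", c(2, 2, 8, 7))
  expect_equal(characteristic_points(lab_of(sig), xr), c(1, 14))
  imp <- exact_fit("double_sigmoid", c(2, 9, 2, 4.5, 1.5, 9.5))
  pts <- characteristic_points(lab_of(imp), xr)
  expect_length(pts, 3)
  expect_equal(pts[1:2], c(1, 14))
  expect_equal(pts[3], 7, tolerance = 0.2)
})

test_that("transition points sit at maximum slope or the extremum", {
  sig <- exact_fit("sigmoid", c(2, 2, 8, 7))
  expect_equal(transition_point(lab_of(sig), sig, xr), 7, tolerance = 0.02)
  imp <- exact_fit("double_sigmoid", c(2, 9, 2, 4.5, 1.5, 9.5))
  l <- lab_of(imp)
  expect_equal(transition_point(l, imp, xr), l$extremum_x)
  lin <- exact_fit("linear", c(1, 1))
  expect_true(is.na(transition_point(lab_of(lin), lin, xr)))
})

test_that("HM is the mean vertical difference over the vertical range", {
  # identical curves
  s <- exact_fit("sigmoid", c(2, 2, 8, 7))
  expect_equal(hm(s, lab_of(s), s, lab_of(s), xr), 0)
  # two flat curves at distinct levels: the difference is the whole range
  f3 <- exact_fit("flat", 3); f5 <- exact_fit("flat", 5)
  expect_equal(hm(f3, lab_of(f3), f5, lab_of(f5), xr), 100)
  expect_equal(hm(f3, lab_of(f3), f3, lab_of(f3), xr), 0)
  # two parallel lines on [0, 10]: diffs 1, range 11
  l1 <- exact_fit("linear", c(0, 1)); l2 <- exact_fit("linear", c(1, 1))
  expect_equal(hm(l1, lab_of(l1), l2, lab_of(l2), c(0, 10)), 100 / 11,
               tolerance = 1e-9)
})

test_that("HC is the transition-point gap as a percent of the range", {
  s1 <- exact_fit("sigmoid", c(2, 2, 8, 6))
  s2 <- exact_fit("sigmoid", c(2, 2, 8, 7.3))
  expect_equal(hc(s1, lab_of(s1), s2, lab_of(s2), xr), 100 * 1.3 / 13,
               tolerance = 0.05)
  expect_equal(hc(s1, lab_of(s1), s1, lab_of(s1), xr), 0)
  lin <- exact_fit("linear", c(1, 1))
  expect_true(is.na(hc(s1, lab_of(s1), lin, lab_of(lin), xr)))
})

test_that("HM and HC are symmetric and affine-invariant", {
  set.seed(501)
  for (i in 1:20) {
    p1 <- c(runif(1, 1, 3), runif(1, 1, 2), runif(1, 6, 9), runif(1, 5, 7))
    p2 <- c(runif(1, 1, 3), runif(1, 1, 2), runif(1, 6, 9), runif(1, 6, 9))
    f1 <- exact_fit("sigmoid", p1); f2 <- exact_fit("sigmoid", p2)
    l1 <- lab_of(f1); l2 <- lab_of(f2)
    expect_equal(hm(f1, l1, f2, l2, xr), hm(f2, l2, f1, l1, xr))
    expect_equal(hc(f1, l1, f2, l2, xr), hc(f2, l2, f1, l1, xr))
    # common affine transform of the response axis leaves HM unchanged
    cc <- runif(1, 0.5, 4); dd <- runif(1, -10, 10)
    t1 <- exact_fit("sigmoid", c(cc * p1[1] + dd, cc * p1[2], cc * p1[3] + dd, p1[4]))
    t2 <- exact_fit("sigmoid", c(cc * p2[1] + dd, cc * p2[2], cc * p2[3] + dd, p2[4]))
    expect_equal(hm(t1, lab_of(t1), t2, lab_of(t2), xr),
                 hm(f1, l1, f2, l2, xr), tolerance = 1e-9)
    # common affine transform of the condition axis leaves HC unchanged
    aa <- runif(1, 0.5, 3); bb <- runif(1, -5, 5)
    u1 <- exact_fit("sigmoid", c(p1[1], p1[2] / aa, p1[3], aa * p1[4] + bb))
    u2 <- exact_fit("sigmoid", c(p2[1], p2[2] / aa, p2[3], aa * p2[4] + bb))
    xr2 <- aa * xr + bb
    expect_equal(hc(u1, lab_of(u1), u2, lab_of(u2), xr2),
                 hc(f1, l1, f2, l2, xr), tolerance = 0.1)
  }
})

test_that("a planted transition shift is recovered as HC", {
  for (shift in c(0, 0.05, 0.1, 0.2)) {
    p <- c(2, 1.8, 8, 5.5)
    f1 <- exact_fit("sigmoid", p)
    f2 <- exact_fit("sigmoid", p + c(0, 0, 0, shift * 13))
    got <- hc(f1, lab_of(f1), f2, lab_of(f2), xr)
    expect_equal(got, 100 * shift, tolerance = 0.2)
  }
})

test_that("compare_pair flags heteromorphy and threshold exceedances", {
  x <- 1:14
  y1 <- curve_eval("sigmoid", c(2, 1.8, 8, 5.5), x)
  y2 <- curve_eval("sigmoid", c(2, 1.8, 8, 7.5), x)  # shifted by 2/13 ~ 15.4%
  g1 <- fit_gene_curves(x, y1, "g1")
  g2 <- fit_gene_curves(x, y2, "g1")
  cmp <- compare_pair(g1, g2)
  expect_false(cmp$heteromorphy)
  expect_equal(cmp$hc, 100 * 2 / 13, tolerance = 0.5)
  expect_true(cmp$heterochrony_flag)
  expect_false(cmp$heterometry_flag)
  # vertical offset only: heterometry, no heterochrony
  y3 <- curve_eval("sigmoid", c(4, 1.8, 10, 5.5), x)
  g3 <- fit_gene_curves(x, y3, "g1")
  cmp2 <- compare_pair(g1, g3)
  expect_true(cmp2$heterometry_flag)
  expect_false(cmp2$heterochrony_flag)
  expect_error(compare_pair(g1, fit_gene_curves(x + 1, y2, "g1")),
               "same condition values")
})

test_that("HC is undefined when one reported curve is linear", {
  x <- 1:14
  g1 <- fit_gene_curves(x, curve_eval("sigmoid", c(2, 1.8, 8, 6), x), "g")
  g2 <- fit_gene_curves(x, curve_eval("linear", c(1, 0.5), x), "g")
  cmp <- compare_pair(g1, g2)
  expect_true(is.na(cmp$hc))
  expect_false(cmp$heterochrony_flag)
  expect_true(cmp$heteromorphy)
})
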