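test_that("an empty pair list gives an all-zero crosstab", {
  ct <- curve_crosstab(list(), "U", "U")
  expect_equal(ct$total, 0)
  expect_true(all(ct$counts == 0))
  expect_identical(dim(ct$counts), c(9L, 9L))
})

test_that("crosstab counts are permutation-invariant and direction-stratified", {
  cells <- rbind(cell("sigmoid", "U", "sigmoid", "U", 5),
                 cell("sigmoid", "D", "sigmoid", "D", 3),
                 cell("line", "U", "hockey", "U", 2),
                 cell("flat", "none", "sigmoid", "U", 2, trend_1 = "D"))
  pairs <- pairs_fixture(cells)
  uu <- curve_crosstab(pairs, "U", "U")
  expect_equal(uu$total, 7)
  expect_equal(uu$counts["sigmoid", "sigmoid"], 5L)
  expect_equal(uu$counts["line", "hockey"], 2L)
  dd <- curve_crosstab(pairs, "D", "D")
  expect_equal(dd$total, 3)
  # the flat curve's own trend (D) decides its stratum
  du <- curve_crosstab(pairs, "D", "U")
  expect_equal(du$total, 2)
  expect_equal(du$counts["flat", "sigmoid"], 2L)
  perm <- pairs[sample(nrow(pairs)), ]
  expect_identical(curve_crosstab(perm, "U", "U")$counts, uu$counts)
})

test_that("summary_table aggregates, filters and orders pair rows", {
  cells <- rbind(cell("sigmoid", "U", "sigmoid", "U", 8),
                 cell("line", "U", "line", "U", 4))
  tab <- summary_table(pairs_fixture(cells), min_count = 5)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$label_1, "sigmoidU")
  expect_identical(tab$total, 8L)
  expect_identical(tab$hc_only + tab$hm_only + tab$hc_and_hm, 0L)
  # flag counting
  p <- pairs_fixture(cell("sigmoid", "U", "sigmoid", "U", 10))
  p$heterochrony_flag <- rep(c(TRUE, FALSE), 5)
  p$heterometry_flag <- c(rep(TRUE, 4), rep(FALSE, 6))
  tab2 <- summary_table(p)
  expect_identical(tab2$hc_only, sum(p$heterochrony_flag & !p$heterometry_flag))
  expect_identical(tab2$hm_only, sum(p$heterometry_flag & !p$heterochrony_flag))
  expect_identical(tab2$hc_and_hm, sum(p$heterometry_flag & p$heterochrony_flag))
})

make_gene_pair <- function() {
  x <- 1:14
  g1 <- fit_gene_curves(x, curve_eval("sigmoid", c(2, 1.8, 8, 6), x), "gX")
  g2 <- fit_gene_curves(x, curve_eval("sigmoid", c(2, 1.8, 8, 7.5), x), "gX")
  list(g1 = g1, g2 = g2, cmp = compare_pair(g1, g2))
}

test_that("gene-pair plots emit a figure and a faithful JSON sidecar", {
  gp <- make_gene_pair()
  dir <- withr::local_tempdir()
  file <- file.path(dir, "gX.svg")
  out <- plot_gene_pair(gp$g1, gp$g2, gp$cmp, file)
  expect_identical(out, file)
  expect_true(file.exists(file) && file.size(file) > 0)
  side <- jsonlite::read_json(file.path(dir, "gX.json"), simplifyVector = TRUE)
  expect_identical(side$label_1, gp$g1$selection$reported$label)
  expect_identical(side$label_2, gp$g2$selection$reported$label)
  expect_equal(side$hm, gp$cmp$hm)
  expect_equal(side$hc, gp$cmp$hc)
})

test_that("genes without a reported curve are skipped with a message", {
  x <- 1:14
  set.seed(601)
  g_noise <- fit_gene_curves(x, rnorm(14), "gN")   # pure noise: nothing reported
  gp <- make_gene_pair()
  dir <- withr::local_tempdir()
  file <- file.path(dir, "gN.svg")
  expect_message(out <- plot_gene_pair(gp$g1, g_noise, NULL, file), "skipping")
  expect_null(out)
  expect_false(file.exists(file))
})

test_that("write_report lays down the full result bundle", {
  syn <- synth_expression(12, noise_sd = 0.12, seed = 16)
  comp <- compare_scenarios(syn$mat_1, syn$mat_2, syn$x)
  dir <- withr::local_tempdir()
  write_report(comp, dir, plots = FALSE)
  expect_true(all(file.exists(file.path(dir, c(
    "crosstab_DD.tsv", "crosstab_DU.tsv", "crosstab_UD.tsv", "crosstab_UU.tsv",
    "summary.tsv", "selections_1.tsv", "selections_2.tsv")))))
  expect_true(dir.exists(file.path(dir, "gene_lists")))
  # stratified totals partition the pairs
  tot <- 0
  for (d1 in c("D", "U")) for (d2 in c("D", "U")) {
    tot <- tot + curve_crosstab(comp$pairs, d1, d2)$total
  }
  expect_equal(tot, nrow(comp$pairs))
  expect_equal(tot, comp$n_both)
})
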