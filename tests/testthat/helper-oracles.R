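# Independent oracles and fixture builders shared across test files.

# Brute-force held-out RPE, written directly from its definition.
rpe_oracle <- function(y, f) {
  100 * sqrt(sum((y - f)^2) / length(y)) / (max(f) - min(f))
}

# Brute-force two-step curve selection, written literally from the algorithm
# statement and independent of select_curves() internals.
select_oracle <- function(cand, threshold = 10, leeway = 5) {
  ord <- order(cand$rpe, cand$n_params, curvecomp:::label_order(cand$shape))
  A <- cand[ord[1], ]
  if (A$rpe > threshold) return(list(reported = NA_character_, A = A$label))
  setB <- cand[cand$n_params < A$n_params, ]
  subB <- setB[setB$rpe <= A$rpe + leeway, ]
  if (nrow(subB) == 0) {
    cmp <- if (nrow(setB) == 0) NA_character_ else {
      o <- order(-setB$n_params, curvecomp:::label_order(setB$shape), setB$rpe)
      setB$label[o[1]]
    }
    return(list(reported = A$label, A = A$label, comparison = cmp))
  }
  o <- order(subB$n_params, curvecomp:::label_order(subB$shape), subB$rpe)
  list(reported = subB$label[o[1]], A = A$label, comparison = A$label)
}

# Random candidate tables over the biological taxonomy (one label per source
# family, as produced by the pipeline).
random_candidates <- function() {
  dir <- sample(c("U", "D"), 4, replace = TRUE)
  shapes <- c("flat", "line",
              sample(c("transition", "hockey", "sigmoid"), 1),
              sample(c("impulse", "step"), 1),
              sample(c("impulse+", "step+"), 1))
  keep <- sample(c(TRUE, TRUE, TRUE, runif(1) < 0.8, runif(1) < 0.6))
  dirs <- c("none", dir)
  np <- c(1, 2, 4, 6, 7)
  d <- data.frame(
    label = ifelse(shapes == "flat", shapes, paste0(shapes, dirs)),
    shape = shapes, direction = dirs, n_params = np,
    rpe = round(runif(5, 0, 35), 2),
    stringsAsFactors = FALSE)
  d[keep, , drop = FALSE]
}

# l2 relative error between parameter vectors; for the double-sigmoid
# families, measured against the closest gauge-orbit member.
rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
orbit_rel_l2 <- function(fit_params, true_params) {
  if (length(true_params) >= 6) {
    min(vapply(dbs_orbit(fit_params), rel_l2, 0, b = true_params))
  } else rel_l2(as.numeric(fit_params), true_params)
}
orbit_rel_max <- function(fit_params, true_params) {
  relmax <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-6))
  if (length(true_params) >= 6) {
    min(vapply(dbs_orbit(fit_params), relmax, 0, b = true_params))
  } else relmax(as.numeric(fit_params), true_params)
}

# Identifiable parameter draws for the recovery oracle: transitions inside
# the condition range, logistic rates resolvable from 7 fitted points.
draw_recovery_params <- function(family) {
  switch(family,
    flat = stats::runif(1, 2, 10),
    linear = c(stats::runif(1, 1, 4), stats::runif(1, 0.3, 0.7)),
    sigmoid = c(stats::runif(1, 1, 3), stats::runif(1, 1, 2),
                stats::runif(1, 7, 10), stats::runif(1, 6, 8)),
    double_sigmoid = c(stats::runif(1, 1, 3), stats::runif(1, 8, 11),
                       stats::runif(1, 2, 4), stats::runif(1, 4, 4.8),
                       stats::runif(1, 0.9, 1.5), stats::runif(1, 9.6, 10.4)),
    gen_double_sigmoid = c(stats::runif(1, 1, 3), stats::runif(1, 8, 11),
                           stats::runif(1, 2, 4), stats::runif(1, 4, 4.8),
                           stats::runif(1, 1.0, 1.3),
                           stats::runif(1, 9.6, 10.4),
                           sample(c(stats::runif(1, 0.65, 0.8),
                                    stats::runif(1, 1.25, 1.55)), 1)),
    stop("no recovery draw for ", family))
}

# Fit one family the way the cascade would seed it.
fit_family_seeded <- function(x, y, family) {
  if (family %in% c("flat", "linear", "sigmoid")) {
    return(fit_family(x, y, family))
  }
  split <- split_series(length(x))
  sig <- fit_family(x, y, "sigmoid")
  fd <- fit_family(x, y, "double_sigmoid",
                   start = curvecomp:::dbs_starts(sig, x, y, split))
  if (family == "double_sigmoid") return(fd)
  fit_family(x, y, "gen_double_sigmoid", start = curvecomp:::gds_starts(fd))
}

# Build a pair-comparison data frame from a compact spec: one row per cell,
# with counts, used to reproduce printed cross-tabulations.
pairs_fixture <- function(cells) {
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    data.frame(gene_id = paste0("fx", i, "_", seq_len(n)),
               label_1 = cells$label_1[i], label_2 = cells$label_2[i],
               shape_1 = cells$shape_1[i], shape_2 = cells$shape_2[i],
               direction_1 = cells$dir_1[i], direction_2 = cells$dir_2[i],
               trend_1 = cells$trend_1[i], trend_2 = cells$trend_2[i],
               heteromorphy = cells$label_1[i] != cells$label_2[i],
               hm = 0, hc = 0,
               heterometry_flag = FALSE, heterochrony_flag = FALSE,
               stringsAsFactors = FALSE)
  }))
  rows
}

cell <- function(shape_1, dir_1, shape_2, dir_2, n,
                 trend_1 = NULL, trend_2 = NULL) {
  lab <- function(s, d) if (s == "flat") s else paste0(s, d)
  data.frame(shape_1 = shape_1, dir_1 = dir_1, shape_2 = shape_2,
             dir_2 = dir_2, n = n,
             label_1 = lab(shape_1, dir_1), label_2 = lab(shape_2, dir_2),
             trend_1 = if (is.null(trend_1)) dir_1 else trend_1,
             trend_2 = if (is.null(trend_2)) dir_2 else trend_2,
             stringsAsFactors = FALSE)
}

# A fake converged curve_fit for classifier/comparison tests on exact curves.
exact_fit <- function(family, params) {
  names(params) <- curvecomp:::param_names(family)
  structure(list(family = family, params = params, converged = TRUE),
            class = "curve_fit")
}
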