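#' Parsimony-leeway cutoff
#'
#' The RPE bound tested in Step 2 of the selection algorithm: a curve with
#' fewer parameters than the best-fitting curve is accepted when its RPE is
#' at or below `rpe_A + leeway`. With a best RPE of 8% and the default 5%
#' leeway, the cutoff is 13%.
#'
#' @param rpe_A Smallest candidate RPE (percent, >= 0).
#' @param leeway Leeway (percentage points, >= 0).
#' @return The cutoff, in percent.
#' @examples
#' leeway_threshold(8, 5)  # 13
#' @export
leeway_threshold <- function(rpe_A, leeway) {
  stopifnot(rpe_A >= 0, leeway >= 0)
  rpe_A + leeway
}

#' Curve selection by held-out RPE with a parsimony leeway
#'
#' Implements the two-step selection algorithm on a table of candidate
#' curves (one label per fitted model family):
#'
#' *Step 1.* Curve A is the candidate with the smallest RPE (ties broken by
#' fewer parameters, then a fixed label order). If its RPE exceeds the
#' good-fit threshold, no curve is reported.
#'
#' *Step 2.* Among candidates with *fewer* parameters than Curve A, those
#' with RPE at or below `RPE_A + leeway` form the eligible subset. If the
#' subset is empty, Curve A is reported and the most-parameter member of the
#' fewer-parameter set is kept as the comparison curve; otherwise the
#' fewest-parameter member of the subset is reported as Curve B (Curve A
#' becomes the comparison curve).
#'
#' @param candidates Data frame with columns `label`, `shape`, `direction`,
#'   `n_params`, `rpe` (and optionally `aic`), one row per candidate curve.
#' @param good_fit_rpe Good-fit RPE threshold (percent). Default 10.
#' @param leeway_rpe Parsimony leeway (percentage points). Default 5.
#' @return A list of class `curve_selection`: `curve_A`, `curve_B` (row or
#'   `NULL`), `reported` (row or `NULL`), `comparison` (row or `NULL`),
#'   `leeway_cutoff`, and the input `candidates`.
#' @examples
#' cand <- data.frame(
#'   label = c("flat", "lineU", "sigmoidU", "impulseU", "impulse+U"),
#'   shape = c("flat", "line", "sigmoid", "impulse", "impulse+"),
#'   direction = c("none", "U", "U", "U", "U"),
#'   n_params = c(1, 2, 4, 6, 7),
#'   rpe = c(30, 12, 11, 8, 9))
#' select_curves(cand)$reported$label  # "lineU"
#' @export
select_curves <- function(candidates, good_fit_rpe = 10, leeway_rpe = 5) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    stop("candidates must be a non-empty data frame")
  }
  req <- c("label", "shape", "n_params", "rpe")
  if (!all(req %in% names(candidates))) {
    stop("candidates must have columns: ", paste(req, collapse = ", "))
  }
  cand <- candidates[is.finite(candidates$rpe), , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidate has a finite RPE")

  ord <- order(cand$rpe, cand$n_params, label_order(cand$shape))
  cand <- cand[ord, , drop = FALSE]
  A <- cand[1, , drop = FALSE]
  cutoff <- leeway_threshold(A$rpe, leeway_rpe)

  set_B <- cand[cand$n_params < A$n_params, , drop = FALSE]
  subset_B <- set_B[set_B$rpe <= cutoff, , drop = FALSE]

  B <- NULL; reported <- NULL; comparison <- NULL
  if (A$rpe <= good_fit_rpe) {
    if (nrow(subset_B) == 0) {
      reported <- A
      if (nrow(set_B) > 0) {
        ordB <- order(-set_B$n_params, label_order(set_B$shape), set_B$rpe)
        comparison <- set_B[ordB[1], , drop = FALSE]
      }
    } else {
      ordB <- order(subset_B$n_params, label_order(subset_B$shape),
                    subset_B$rpe)
      B <- subset_B[ordB[1], , drop = FALSE]
      reported <- B
      comparison <- A
    }
  }
  structure(list(curve_A = A, curve_B = B, reported = reported,
                 comparison = comparison, leeway_cutoff = cutoff,
                 good_fit_rpe = good_fit_rpe, leeway_rpe = leeway_rpe,
                 candidates = cand),
            class = "curve_selection")
}

#' @export
print.curve_selection <- function(x, ...) {
  cat("Curve selection (good fit <=", x$good_fit_rpe,
      "% RPE, leeway", x$leeway_rpe, "points)\n")
  tab <- x$candidates[, c("label", "n_params", "rpe")]
  tab$rpe <- round(tab$rpe, 3)
  print(tab, row.names = FALSE)
  if (is.null(x$reported)) {
    cat("Reported: none (best RPE", round(x$curve_A$rpe, 3),
        "% exceeds threshold)\n")
  } else {
    cat("Curve A:", x$curve_A$label,
        "| reported:", x$reported$label,
        if (!is.null(x$curve_B)) "(Curve B)" else "(Curve A)", "\n")
    if (!is.null(x$comparison)) {
      cat("Comparison curve:", x$comparison$label, "\n")
    }
  }
  invisible(x)
}
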