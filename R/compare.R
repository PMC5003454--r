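#' Characteristic condition values of a classified curve
#'
#' The points at which vertical (heterometry) differences are measured:
#' any single point for a flat curve (the left endpoint is used); the two
#' endpoints for line, transition, hockey, sigmoid, step and step+ curves;
#' the endpoints plus the peak/trough location for impulse and impulse+.
#'
#' @param label A `shape_label` (from [classify_fit]).
#' @param x_range Numeric length-2 observed condition range.
#' @return Numeric vector of condition values.
#' @export
characteristic_points <- function(label, x_range) {
  stopifnot(inherits(label, "shape_label"), length(x_range) == 2)
  if (label$shape == "flat") return(x_range[1])
  pts <- c(x_range[1], x_range[2])
  if (label$shape %in% c("impulse", "impulse+") && is.finite(label$extremum_x)) {
    pts <- c(pts, label$extremum_x)
  }
  pts
}

#' Transition point of a classified curve
#'
#' The condition value marking the curve's transition, used for heterochrony:
#' the location of maximum absolute slope for sigmoid, hockey, transition,
#' step and step+ curves (found on a dense grid over the observed range), and
#' the peak/trough location for impulse and impulse+ curves. Undefined (`NA`)
#' for flat and line curves, which have no transition.
#'
#' @param label A `shape_label`.
#' @param fit The corresponding `curve_fit`.
#' @param x_range Numeric length-2 observed condition range.
#' @param grid_points Grid resolution for the slope search.
#' @return Condition value, or `NA` for flat/line.
#' @export
transition_point <- function(label, fit, x_range, grid_points = 1001) {
  stopifnot(inherits(label, "shape_label"), inherits(fit, "curve_fit"))
  if (label$shape %in% c("flat", "line")) return(NA_real_)
  if (label$shape %in% c("impulse", "impulse+")) return(label$extremum_x)
  grid <- seq(x_range[1], x_range[2], length.out = grid_points)
  slopes <- abs(curve_deriv(fit$family, fit$params, grid))
  grid[which.max(slopes)]
}

#' Heterometry (HM) between two reported curves
#'
#' The mean vertical difference between the two curves, evaluated at the
#' union of their characteristic points, expressed as a percentage of the
#' vertical response range (the range of both curves' values over that same
#' union of points):
#' `HM = 100 * mean(|f1(x) - f2(x)|) / R_v`.
#'
#' Two flat curves at distinct levels give HM = 100 (the difference *is* the
#' range); two identical curves give 0.
#'
#' @param fit_1,fit_2 `curve_fit` objects of the two reported curves.
#' @param label_1,label_2 Their `shape_label`s.
#' @param x_range Numeric length-2 observed condition range.
#' @return HM in percent.
#' @export
hm <- function(fit_1, label_1, fit_2, label_2, x_range) {
  pts <- sort(unique(c(characteristic_points(label_1, x_range),
                       characteristic_points(label_2, x_range))))
  f1 <- curve_eval(fit_1$family, fit_1$params, pts)
  f2 <- curve_eval(fit_2$family, fit_2$params, pts)
  r_v <- max(c(f1, f2)) - min(c(f1, f2))
  num <- mean(abs(f1 - f2))
  if (r_v < 1e-12 * max(1, abs(max(c(f1, f2))))) {
    return(if (num < 1e-12) 0 else 100)
  }
  100 * num / r_v
}

#' Heterochrony (HC) between two reported curves
#'
#' The horizontal difference between the two curves' transition points,
#' expressed as a percentage of the condition range:
#' `HC = 100 * |t1 - t2| / (x_max - x_min)`. Undefined (`NA`) when either
#' curve is flat or linear.
#'
#' @inheritParams hm
#' @param grid_points Grid resolution for the slope search.
#' @return HC in percent, or `NA`.
#' @export
hc <- function(fit_1, label_1, fit_2, label_2, x_range, grid_points = 1001) {
  t1 <- transition_point(label_1, fit_1, x_range, grid_points)
  t2 <- transition_point(label_2, fit_2, x_range, grid_points)
  if (is.na(t1) || is.na(t2)) return(NA_real_)
  100 * abs(t1 - t2) / (x_range[2] - x_range[1])
}

#' Compare one gene's reported curves under two scenarios
#'
#' Computes heteromorphy (different shape labels), heterometry (HM) and
#' heterochrony (HC) between the reported curves of the two scenarios, and
#' sets the HC/HM flags when the statistics exceed their thresholds
#' (`control$hm_threshold`, `control$hc_threshold`; both default 10%).
#'
#' @param gc_1,gc_2 `gene_curves` objects for the same gene in the two
#'   scenarios (both must have a reported curve).
#' @param control A [curve_control] list.
#' @return A list of class `pair_comparison`: `label_1`, `label_2`,
#'   `heteromorphy`, `hm`, `hc`, `heterometry_flag`, `heterochrony_flag`.
#' @export
compare_pair <- function(gc_1, gc_2, control = curve_control()) {
  stopifnot(inherits(gc_1, "gene_curves"), inherits(gc_2, "gene_curves"))
  rep1 <- gc_1$selection$reported
  rep2 <- gc_2$selection$reported
  if (is.null(rep1) || is.null(rep2)) {
    stop("both scenarios must have a reported curve")
  }
  if (!isTRUE(all.equal(gc_1$x, gc_2$x))) {
    stop("the two scenarios must share the same condition values")
  }
  x_range <- range(gc_1$x)
  f1 <- gc_1$fits[[rep1$family]]
  f2 <- gc_2$fits[[rep2$family]]
  l1 <- row_to_label(rep1)
  l2 <- row_to_label(rep2)
  hm_val <- hm(f1, l1, f2, l2, x_range)
  hc_val <- hc(f1, l1, f2, l2, x_range, control$grid_points)
  structure(list(
    gene_id = gc_1$gene_id,
    label_1 = rep1$label, label_2 = rep2$label,
    shape_1 = rep1$shape, shape_2 = rep2$shape,
    direction_1 = rep1$direction, direction_2 = rep2$direction,
    trend_1 = curve_trend(rep1, gc_1),
    trend_2 = curve_trend(rep2, gc_2),
    heteromorphy = rep1$label != rep2$label,
    hm = hm_val, hc = hc_val,
    heterometry_flag = is.finite(hm_val) && hm_val > control$hm_threshold,
    heterochrony_flag = is.finite(hc_val) && hc_val > control$hc_threshold
  ), class = "pair_comparison")
}

# Direction used to stratify a reported curve into the U/D tables. A flat
# curve has no direction of its own; its underlying trend (the sign of the
# gene's linear-fit slope in that scenario) is used instead, so flat-reported
# genes can land in either stratum.
curve_trend <- function(rep_row, gc) {
  if (rep_row$direction != "none") return(rep_row$direction)
  lin <- gc$fits$linear
  if (!is.null(lin) && lin$converged) {
    if (unname(lin$params["beta"]) >= 0) "U" else "D"
  } else "none"
}

row_to_label <- function(row) {
  structure(list(shape = row$shape, direction = row$direction,
                 label = row$label, family = row$family,
                 n_params = row$n_params, extremum_x = row$extremum_x),
            class = "shape_label")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair: %s vs %s | HM %.2f%% | HC %s | %s>\n",
              x$label_1, x$label_2, x$hm,
              if (is.na(x$hc)) "undefined" else sprintf("%.2f%%", x$hc),
              paste0(c(if (x$heteromorphy) "heteromorphy",
                       if (x$heterometry_flag) "heterometry",
                       if (x$heterochrony_flag) "heterochrony",
                       if (!x$heteromorphy && !x$heterometry_flag &&
                           !x$heterochrony_flag) "concordant"),
                     collapse = "+")))
  invisible(x)
}
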