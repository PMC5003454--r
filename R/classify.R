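SHAPE_ORDER <- c("flat", "line", "transition", "hockey", "sigmoid",
                 "impulse", "step", "impulse+", "step+",
                 "poly3", "poly5", "poly7")

#' The fixed label order used for deterministic tie-breaking
#'
#' Within equal parameter counts, ties are broken in this order, which places
#' the biologically motivated shapes before the polynomial controls.
#' @keywords internal
label_order <- function(shape) match(shape, SHAPE_ORDER)

label_text <- function(shape, direction) {
  if (direction == "none") shape else paste0(shape, direction)
}

#' Classify a converged fit into a curve-shape label
#'
#' Maps a fitted model onto the shape taxonomy:
#'
#' * flat model -> `flat` (no direction);
#' * linear model -> `lineU`/`lineD` by slope sign;
#' * sigmoid model -> count boundary steady states (derivative magnitude at
#'   the first and last observed condition value at or below
#'   `control$steady_slope`): two -> `sigmoid`, one -> `hockey`,
#'   zero -> `transition`; direction from comparing the curve's first and
#'   last values;
#' * double sigmoid / generalized double sigmoid -> scan a dense grid over
#'   the observed range: a strict interior extremum makes it an
#'   `impulse`/`impulse+` (U for a peak, D for a trough), otherwise a
#'   `step`/`step+` with direction from the endpoint comparison;
#' * polynomials -> `poly3/5/7` with direction from endpoint comparison.
#'
#' @param fit A converged `curve_fit`.
#' @param x_range Numeric length-2: first and last observed condition values.
#' @param control A [curve_control] list (`steady_slope`, `grid_points`).
#' @return A list of class `shape_label`: `shape`, `direction` (`"U"`,
#'   `"D"` or `"none"`), `label` (e.g. `"sigmoidU"`), `family`, `n_params`,
#'   and `extremum_x` (condition value of the interior peak/trough, `NA`
#'   otherwise).
#' @export
classify_fit <- function(fit, x_range, control = curve_control()) {
  stopifnot(inherits(fit, "curve_fit"), length(x_range) == 2)
  if (!fit$converged) {
    stop("cannot classify a fit that did not converge")
  }
  fam <- fit$family
  p <- fit$params
  x0 <- x_range[1]; x1 <- x_range[2]
  ends <- curve_eval(fam, p, c(x0, x1))
  dir_ends <- if (ends[2] >= ends[1]) "U" else "D"
  extremum_x <- NA_real_

  if (fam == "flat") {
    shape <- "flat"; direction <- "none"
  } else if (fam == "linear") {
    shape <- "line"
    direction <- if (p[["beta"]] > 0) "U" else "D"
  } else if (fam == "sigmoid") {
    slopes <- abs(curve_deriv(fam, p, c(x0, x1)))
    n_steady <- sum(slopes <= control$steady_slope)
    shape <- c("transition", "hockey", "sigmoid")[n_steady + 1]
    direction <- dir_ends
  } else if (fam %in% c("double_sigmoid", "gen_double_sigmoid")) {
    plus <- fam == "gen_double_sigmoid"
    grid <- seq(x0, x1, length.out = control$grid_points)
    fg <- curve_eval(fam, p, grid)
    tol <- 1e-8 * (max(fg) - min(fg) + .Machine$double.eps)
    i_max <- which.max(fg); i_min <- which.min(fg)
    n <- length(grid)
    interior_max <- i_max > 1 && i_max < n && fg[i_max] > max(fg[1], fg[n]) + tol
    interior_min <- i_min > 1 && i_min < n && fg[i_min] < min(fg[1], fg[n]) - tol
    if (interior_max || interior_min) {
      shape <- if (plus) "impulse+" else "impulse"
      # if both a peak and a trough are interior, report the larger excursion
      dev_max <- if (interior_max) fg[i_max] - max(fg[1], fg[n]) else -Inf
      dev_min <- if (interior_min) min(fg[1], fg[n]) - fg[i_min] else -Inf
      if (dev_max >= dev_min) {
        direction <- "U"; extremum_x <- grid[i_max]
      } else {
        direction <- "D"; extremum_x <- grid[i_min]
      }
    } else {
      shape <- if (plus) "step+" else "step"
      direction <- dir_ends
    }
  } else {
    shape <- fam  # polynomial controls keep their family name as shape
    direction <- dir_ends
  }
  structure(list(shape = shape, direction = direction,
                 label = label_text(shape, direction),
                 family = fam, n_params = n_params(fam),
                 extremum_x = extremum_x),
            class = "shape_label")
}

#' @export
print.shape_label <- function(x, ...) {
  cat(sprintf("<shape_label: %s (%s, %d params)>\n",
              x$label, x$family, x$n_params))
  invisible(x)
}
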