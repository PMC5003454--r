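#' Fit, score and select response curves for one gene
#'
#' The central fitting function. It splits the series into fitted
#' (odd-indexed) and evaluation (even-indexed) points, fits the model cascade
#' to the fitted points ([fit_cascade]), scores every converged fit on the
#' evaluation points by Relative Prediction Error ([rpe]) and evaluation-point
#' AIC ([aic_eval]), classifies each fit into a shape label ([classify_fit]),
#' and runs the parsimony-leeway selection ([select_curves]).
#'
#' @param x Strictly increasing vector of condition values (time, dose, ...),
#'   length >= 12 (>= 14 when `control$max_model` is the generalized double
#'   sigmoid).
#' @param y Responses, same length as `x`, all finite.
#' @param gene_id Optional identifier carried into printouts and reports.
#' @param control A [curve_control] list.
#' @return An object of class `gene_curves` with components `fits` (named
#'   list of `curve_fit`), `candidates` (score table: label, shape, direction,
#'   family, n_params, rpe, aic, extremum_x), `selection`
#'   (a `curve_selection`), plus the series, split and control.
#' @examples
#' x <- 1:14
#' y <- curve_eval("sigmoid", c(2, 1.5, 8, 7), x)
#' g <- fit_gene_curves(x, y)
#' g$selection$reported$label  # "sigmoidU"
#' @seealso [compare_scenarios] for the two-scenario pipeline.
#' @export
fit_gene_curves <- function(x, y, gene_id = NULL, control = curve_control()) {
  validate_series(x, y)
  n <- length(x)
  if (control$max_model == "gen_double_sigmoid" && n < 14) {
    stop("max_model 'gen_double_sigmoid' requires at least 14 points; ",
         "use max_model = 'double_sigmoid' for 12-13 points")
  }
  split <- split_series(n)
  fits <- fit_cascade(x, y,
                      include_gds = control$max_model == "gen_double_sigmoid",
                      include_poly = control$include_polynomials,
                      control = control)
  ye <- y[split$eval_idx]
  x_range <- range(x)

  rows <- list()
  for (fam in names(fits)) {
    fit <- fits[[fam]]
    if (!fit$converged) next
    lab <- classify_fit(fit, x_range, control)
    score <- rpe(ye, fit$predicted_eval)
    rows[[fam]] <- data.frame(
      label = lab$label, shape = lab$shape, direction = lab$direction,
      family = fam, n_params = lab$n_params,
      rpe = as.numeric(score),
      rpe_range_fallback = isTRUE(attr(score, "range_fallback")),
      aic = aic_eval(ye, fit$predicted_eval, n_params(fam)),
      extremum_x = lab$extremum_x,
      stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, rows)
  selection <- select_curves(candidates, control$good_fit_rpe,
                             control$leeway_rpe)
  structure(list(gene_id = gene_id, x = x, y = y, split = split,
                 fits = fits, candidates = candidates,
                 selection = selection, control = control),
            class = "gene_curves")
}

reported_label <- function(object) {
  if (is.null(object$selection$reported)) NA_character_
  else object$selection$reported$label
}

reported_fit <- function(object) {
  rep <- object$selection$reported
  if (is.null(rep)) NULL else object$fits[[rep$family]]
}

#' @export
print.gene_curves <- function(x, ...) {
  cat("Response-curve fits",
      if (!is.null(x$gene_id)) paste0("for gene ", x$gene_id), "\n")
  cat(sprintf("%d points: %d fitted, %d held out for evaluation\n",
              length(x$x), length(x$split$fitted_idx),
              length(x$split$eval_idx)))
  print(x$selection)
  invisible(x)
}

#' @export
summary.gene_curves <- function(object, ...) {
  structure(list(gene_id = object$gene_id,
                 candidates = object$candidates,
                 selection = object$selection,
                 reported = reported_label(object)),
            class = "summary.gene_curves")
}

#' @export
print.summary.gene_curves <- function(x, ...) {
  cat("Candidate curves",
      if (!is.null(x$gene_id)) paste0("(gene ", x$gene_id, ")"), "\n")
  tab <- x$candidates[, c("label", "family", "n_params", "rpe", "aic")]
  tab$rpe <- round(tab$rpe, 3); tab$aic <- round(tab$aic, 3)
  print(tab, row.names = FALSE)
  cat("Reported curve:", if (is.na(x$reported)) "none" else x$reported, "\n")
  invisible(x)
}

#' @export
coef.gene_curves <- function(object, ...) {
  fit <- reported_fit(object)
  if (is.null(fit)) return(NULL)
  fit$params
}

#' Predict from the reported (or any fitted) curve
#'
#' @param object A `gene_curves` object.
#' @param newdata Condition values; defaults to the observed `x`.
#' @param family Which fitted family to predict from; defaults to the
#'   reported curve's family.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.gene_curves <- function(object, newdata = object$x, family = NULL, ...) {
  fit <- if (is.null(family)) reported_fit(object) else object$fits[[family]]
  if (is.null(fit)) {
    stop("no reported curve for this gene; pass `family` explicitly")
  }
  curve_eval(fit$family, fit$params, newdata)
}

#' @export
residuals.gene_curves <- function(object, ...) {
  object$y - predict(object)
}

#' @export
fitted.gene_curves <- function(object, ...) predict(object)

#' Simulate new series from the reported curve
#'
#' Draws `nsim` replicate series from the reported curve plus i.i.d. Gaussian
#' noise with standard deviation estimated from the evaluation-point
#' residuals.
#'
#' @param object A `gene_curves` object with a reported curve.
#' @param nsim Number of replicate series.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A matrix, `nsim` columns of simulated responses at `object$x`.
#' @export
simulate.gene_curves <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fit <- reported_fit(object)
  if (is.null(fit)) stop("no reported curve to simulate from")
  mu <- curve_eval(fit$family, fit$params, object$x)
  ye <- object$y[object$split$eval_idx]
  sd_hat <- sqrt(mean((ye - fit$predicted_eval)^2))
  matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sd_hat),
         ncol = nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim))))
}

#' Plot the data and the selected curves for one gene
#'
#' Base-graphics panel: fitted points (red), evaluation points (black), the
#' reported curve (blue, solid) and the comparison curve (orange, dashed),
#' annotated with their RPEs.
#'
#' @param x A `gene_curves` object.
#' @param main Plot title.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot].
#' @export
plot.gene_curves <- function(x, main = NULL,
                             xlab = "condition", ylab = "response", ...) {
  obj <- x
  grid <- seq(min(obj$x), max(obj$x), length.out = 200)
  rep_row <- obj$selection$reported
  cmp_row <- obj$selection$comparison
  curves <- list()
  if (!is.null(rep_row)) {
    curves$reported <- curve_eval(obj$fits[[rep_row$family]]$family,
                                  obj$fits[[rep_row$family]]$params, grid)
  }
  if (!is.null(cmp_row)) {
    curves$comparison <- curve_eval(obj$fits[[cmp_row$family]]$family,
                                    obj$fits[[cmp_row$family]]$params, grid)
  }
  ylim <- range(c(obj$y, unlist(curves)))
  if (is.null(main)) {
    main <- paste0(if (!is.null(obj$gene_id)) paste0(obj$gene_id, ": "),
                   if (is.null(rep_row)) "no reported curve"
                   else rep_row$label)
  }
  plot(obj$x, obj$y, type = "n", main = main, xlab = xlab, ylab = ylab,
       ylim = ylim, ...)
  if (!is.null(cmp_row)) {
    graphics::lines(grid, curves$comparison, col = "orange", lwd = 2, lty = 2)
  }
  if (!is.null(rep_row)) {
    graphics::lines(grid, curves$reported, col = "blue", lwd = 2)
  }
  graphics::points(obj$x[obj$split$fitted_idx], obj$y[obj$split$fitted_idx],
                   col = "red", pch = 19)
  graphics::points(obj$x[obj$split$eval_idx], obj$y[obj$split$eval_idx],
                   col = "black", pch = 1, lwd = 2)
  leg <- c("fitted", "evaluation",
           if (!is.null(rep_row))
             sprintf("%s (RPE %.1f%%)", rep_row$label, rep_row$rpe),
           if (!is.null(cmp_row))
             sprintf("%s (RPE %.1f%%)", cmp_row$label, cmp_row$rpe))
  graphics::legend("topleft", legend = leg, bty = "n", cex = 0.8,
                   col = c("red", "black",
                           if (!is.null(rep_row)) "blue",
                           if (!is.null(cmp_row)) "orange"),
                   pch = c(19, 1, NA, NA)[seq_along(leg)],
                   lty = c(NA, NA,
                           if (!is.null(rep_row)) 1,
                           if (!is.null(cmp_row)) 2))
  invisible(obj)
}
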