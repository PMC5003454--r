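#' Split a series into fitted and evaluation points
#'
#' Curves are fit to every other response and judged on the points left out:
#' odd (1-based) indices are the fitted points, even indices the evaluation
#' points. With 14 observations this gives 7 fitted and 7 evaluation points —
#' the minimum needed to fit and evaluate the 7-parameter generalized double
#' sigmoid.
#'
#' @param n Number of observations (>= 12).
#' @return List with integer vectors `fitted_idx` and `eval_idx`.
#' @examples
#' split_series(14)
#' @export
split_series <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 12) {
    stop("need at least 12 points (>= 14 for the generalized double sigmoid)")
  }
  n <- as.integer(n)
  list(fitted_idx = seq.int(1L, n, by = 2L),
       eval_idx = seq.int(2L, n, by = 2L))
}

validate_series <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite")
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  invisible(TRUE)
}

new_curve_fit <- function(family, params, x, y, split, converged) {
  names(params) <- param_names(family)
  f_fit <- curve_eval(family, params, x[split$fitted_idx])
  f_eval <- curve_eval(family, params, x[split$eval_idx])
  structure(list(
    family = family,
    params = params,
    converged = converged,
    fitted_values = f_fit,
    predicted_eval = f_eval,
    sse_fit = sum((y[split$fitted_idx] - f_fit)^2),
    sse_eval = sum((y[split$eval_idx] - f_eval)^2)
  ), class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit: %s, %s>\n", x$family,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$params, 6))
  cat(sprintf("SSE fitted %.6g | SSE eval %.6g\n", x$sse_fit, x$sse_eval))
  invisible(x)
}

lm_coef_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0  # rank deficiency (e.g. degree-7 poly on 7 points)
  cf
}

#' Fit one model family to the fitted points of a series
#'
#' Minimizes the sum of squared residuals over the fitted (odd-indexed)
#' points. Flat, linear and polynomial families are solved in closed form by
#' ordinary least squares; the sigmoid families use Levenberg–Marquardt
#' ([minpack.lm::nls.lm]) from the supplied start (or the family's default
#' multi-start scheme when `start` is `NULL`). Optimizer failure never
#' raises: the best point found is returned with `converged = FALSE`.
#'
#' @param x,y The full series (all points); the split decides which enter the
#'   objective.
#' @param family One of [CURVE_FAMILIES].
#' @param start Optional numeric start vector of the family's arity, or a
#'   list of such vectors for multi-start. `NULL` uses defaults.
#' @param split Output of [split_series]; defaults to the split of
#'   `length(x)`.
#' @param control A [curve_control] list (optimizer tolerances).
#' @return A `curve_fit` object.
#' @export
fit_family <- function(x, y, family, start = NULL, split = split_series(length(x)),
                       control = curve_control()) {
  validate_series(x, y)
  family <- match.arg(family, CURVE_FAMILIES)
  xf <- x[split$fitted_idx]
  yf <- y[split$fitted_idx]

  if (family == "flat") {
    return(new_curve_fit("flat", mean(yf), x, y, split, TRUE))
  }
  if (family == "linear") {
    cf <- lm_coef_fit(cbind(1, xf), yf)
    return(new_curve_fit("linear", cf, x, y, split, TRUE))
  }
  if (family %in% c("poly3", "poly5", "poly7")) {
    deg <- as.integer(substring(family, 5))
    cf <- lm_coef_fit(outer(xf, 0:deg, `^`), yf)
    return(new_curve_fit(family, cf, x, y, split, TRUE))
  }

  starts <- if (is.null(start)) {
    default_starts(family, x, y, split)
  } else if (is.list(start)) start else list(start)

  xe <- x[split$eval_idx]
  ye <- y[split$eval_idx]
  best <- NULL
  best_sse <- Inf
  best_sse_eval <- Inf
  conv <- FALSE
  for (s0 in starts) {
    if (length(s0) != n_params(family)) {
      stop(sprintf("start for '%s' must have %d parameters",
                   family, n_params(family)))
    }
    res <- lm_minimize(family, s0, xf, yf, control)
    if (is.null(res)) next
    # near-exact ties in fitted SSE (multiple interpolants of a saturated
    # model) are broken by evaluation SSE, so the returned solution is the
    # interpolant that generalizes
    sse_eval <- sum((ye - curve_eval(family, res$par, xe))^2)
    tied <- res$sse <= best_sse * (1 + 1e-9) + 1e-12
    if (res$sse < best_sse * (1 - 1e-9) - 1e-12 ||
        (tied && sse_eval < best_sse_eval)) {
      best_sse <- min(res$sse, best_sse)
      best_sse_eval <- sse_eval
      best <- res$par
      conv <- res$converged
    }
  }
  if (is.null(best)) {
    # all starts failed outright: report the first start, unconverged
    best <- starts[[1]]
    conv <- FALSE
  }
  new_curve_fit(family, best, x, y, split, conv)
}

lm_minimize <- function(family, par0, xf, yf, control) {
  resid_fn <- function(p) {
    if (family %in% c("double_sigmoid", "gen_double_sigmoid") &&
        abs(p[2]) < 1e-12) {
      return(rep.int(1e8, length(yf)))
    }
    r <- yf - curve_eval(family, p, xf)
    r[!is.finite(r)] <- 1e8
    r
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = control$ftol, ptol = control$ptol,
                         maxfev = control$maxfev, maxiter = 1000)),
    error = function(e) NULL
  )
  if (is.null(out)) return(NULL)
  par <- unname(out$par)
  sse <- sum(resid_fn(par)^2)
  if (!is.finite(sse)) return(NULL)
  list(par = par, sse = sse, converged = out$info %in% 1:4)
}

default_starts <- function(family, x, y, split) {
  xf <- x[split$fitted_idx]
  yf <- y[split$fitted_idx]
  nf <- length(xf)
  xr <- max(x) - min(x)
  if (family == "sigmoid") {
    a0 <- mean(yf[1:2])
    g0 <- mean(yf[(nf - 1):nf])
    if (g0 == a0) g0 <- a0 + max(diff(range(yf)), 1e-3)
    # slope start: traverse the level gap over half the condition range
    b0 <- (g0 - a0) / (xr / 2)
    dq <- min(x) + c(0.25, 0.5, 0.75) * xr
    return(c(lapply(dq, function(d) c(a0, b0, g0, d)),
             lapply(dq, function(d) c(a0, 4 * b0, g0, d))))
  }
  stop("no default starts for family ", family)
}

#' Double-sigmoid starting values from a sigmoid fit
#'
#' The double sigmoid is seeded from the sigmoid fit:
#' `alpha = a_sig`, `beta = (a_sig + g_sig) / 2`, `gamma = g_sig`,
#' `delta = d_sig`, `epsilon = 0`, `phi = 0`. A degenerate seed
#' (`beta = 0`, which the model does not admit) is flagged via the attribute
#' `degenerate` and perturbed before use by the cascade.
#'
#' @param sig_fit A `curve_fit` of family `"sigmoid"`.
#' @return Named numeric start vector of length 6.
#' @export
double_sigmoid_start <- function(sig_fit) {
  if (!inherits(sig_fit, "curve_fit") || sig_fit$family != "sigmoid") {
    stop("sig_fit must be a sigmoid curve_fit")
  }
  p <- sig_fit$params
  out <- c(alpha = unname(p["alpha"]),
           beta = unname((p["alpha"] + p["gamma"]) / 2),
           gamma = unname(p["gamma"]),
           delta = unname(p["delta"]),
           epsilon = 0, phi = 0)
  if (out["beta"] == 0) attr(out, "degenerate") <- TRUE
  out
}

dbs_starts <- function(sig_fit, x, y, split) {
  printed <- double_sigmoid_start(sig_fit)
  xr <- max(x) - min(x)
  yf <- y[split$fitted_idx]
  ry <- max(diff(range(yf)), 1e-3)
  a0 <- printed[["alpha"]]; g0 <- printed[["gamma"]]
  b0 <- printed[["beta"]]
  if (abs(b0) < 1e-8 * max(1, ry)) b0 <- ry / 10 + 1e-3  # avoid beta = 0
  d_sig <- printed[["delta"]]
  eps_grid <- c(-2, -0.5, 0.5, 2) * 14 / xr
  q1 <- min(x) + 0.3 * xr
  q3 <- min(x) + 0.7 * xr
  starts <- list(unname(printed))
  for (e in eps_grid) {
    starts <- c(starts, list(
      c(a0, b0, g0, d_sig, e, d_sig),
      c(a0, b0, g0, q1, e, q3)
    ))
  }
  # impulse-shaped seeds: intermediate level beyond both steady states
  for (b in c(max(yf) + 0.1 * ry, min(yf) - 0.1 * ry)) {
    for (e in c(-2, 2) * 14 / xr) {
      starts <- c(starts, list(c(a0, b, g0, q1, e, q3)))
    }
  }
  starts
}

gds_starts <- function(dbs_fit) {
  p <- unname(dbs_fit$params)
  lapply(c(0, 0.5, 1, 2), function(l) c(p, l))
}

#' Fit the full model cascade to one series
#'
#' Fits flat, linear and sigmoid always; fits the double sigmoid only when
#' the sigmoid model is not already an adequate description — its RPE exceeds
#' the linear model's, or exceeds the good-fit threshold
#' (`control$good_fit_rpe`); fits
#' the generalized double sigmoid, seeded from the double-sigmoid estimates,
#' when `include_gds` and the series has >= 14 points; optionally adds
#' polynomial controls of degree 3, 5 and 7. A degenerate series (all
#' responses identical) gets only the flat fit; the other families are
#' returned unconverged.
#'
#' @inheritParams fit_family
#' @param include_gds Fit the generalized double sigmoid (requires n >= 14).
#' @param include_poly Add polynomial controls (degrees 3, 5, 7).
#' @return Named list of `curve_fit` objects, one per family attempted.
#' @export
fit_cascade <- function(x, y, include_gds = TRUE, include_poly = FALSE,
                        control = curve_control()) {
  validate_series(x, y)
  split <- split_series(length(x))
  if (include_gds && length(x) < 14) {
    stop("the generalized double sigmoid needs at least 14 points")
  }
  ye <- y[split$eval_idx]
  fits <- list(flat = fit_family(x, y, "flat", split = split, control = control))

  if (max(y) == min(y)) {
    # degenerate: only the flat model is meaningful
    return(fits)
  }

  fits$linear <- fit_family(x, y, "linear", split = split, control = control)
  fits$sigmoid <- fit_family(x, y, "sigmoid", split = split, control = control)

  rpe_lin <- rpe(ye, fits$linear$predicted_eval)
  rpe_sig <- rpe(ye, fits$sigmoid$predicted_eval)
  if (rpe_sig > rpe_lin || rpe_sig > control$good_fit_rpe) {
    fits$double_sigmoid <- fit_family(
      x, y, "double_sigmoid",
      start = dbs_starts(fits$sigmoid, x, y, split),
      split = split, control = control)
    if (include_gds) {
      fits$gen_double_sigmoid <- fit_family(
        x, y, "gen_double_sigmoid",
        start = gds_starts(fits$double_sigmoid),
        split = split, control = control)
    }
  }
  if (include_poly) {
    for (fam in c("poly3", "poly5", "poly7")) {
      fits[[fam]] <- fit_family(x, y, fam, split = split, control = control)
    }
  }
  fits
}
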