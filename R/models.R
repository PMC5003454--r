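#' Candidate model families
#'
#' The model cascade comprises five biologically motivated families plus
#' optional polynomial controls:
#'
#' * `"flat"` — a constant, one steady state (1 parameter).
#' * `"linear"` — constant addition/removal of product (2 parameters).
#' * `"sigmoid"` — two steady states joined by a logistic transition
#'   (4 parameters); depending on where its steady states fall relative to
#'   the observed condition range it presents as a sigmoid, hockey-stick or
#'   transition curve.
#' * `"double_sigmoid"` — the product of two logistic factors (6 parameters);
#'   presents as an impulse (interior peak/trough) or step (interior plateau).
#' * `"gen_double_sigmoid"` — double sigmoid with an extra slope-ratio
#'   parameter `lambda` allowing unequal slopes on the two transitions
#'   (7 parameters); presents as impulse+ or step+.
#' * `"poly3"`, `"poly5"`, `"poly7"` — raw polynomials of degree 3/5/7
#'   (4/6/8 parameters), included only as an overfitting control.
#'
#' @format A character vector of family names.
#' @export
CURVE_FAMILIES <- c("flat", "linear", "sigmoid", "double_sigmoid",
                    "gen_double_sigmoid", "poly3", "poly5", "poly7")

#' Number of free parameters of a model family
#'
#' Parameter counts drive the parsimony rule of the selection algorithm:
#' flat (1) < linear (2) < sigmoid (4) < double sigmoid (6) < generalized
#' double sigmoid (7). Polynomials of degree d have d + 1 coefficients.
#'
#' @param family One of [CURVE_FAMILIES].
#' @return Integer parameter count.
#' @examples
#' n_params("gen_double_sigmoid")  # 7
#' n_params("double_sigmoid")      # 6
#' @export
n_params <- function(family) {
  counts <- c(flat = 1L, linear = 2L, sigmoid = 4L, double_sigmoid = 6L,
              gen_double_sigmoid = 7L, poly3 = 4L, poly5 = 6L, poly7 = 8L)
  family <- match.arg(family, CURVE_FAMILIES)
  unname(counts[family])
}

#' Logistic (expit) function
#'
#' `expit(x) = exp(x) / (1 + exp(x))`, computed in a branch that never
#' overflows: for large |x| it saturates cleanly at 0 or 1.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1) (attaining 0/1 at floating-point saturation).
#' @examples
#' expit(0)    # 0.5
#' expit(800)  # 1, no overflow
#' @export
expit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

param_names <- function(family) {
  switch(family,
    flat = "alpha",
    linear = c("alpha", "beta"),
    sigmoid = c("alpha", "beta", "gamma", "delta"),
    double_sigmoid = c("alpha", "beta", "gamma", "delta", "epsilon", "phi"),
    gen_double_sigmoid = c("alpha", "beta", "gamma", "delta", "epsilon",
                           "phi", "lambda"),
    poly3 = paste0("c", 0:3),
    poly5 = paste0("c", 0:5),
    poly7 = paste0("c", 0:7),
    stop("unknown family: ", family)
  )
}

check_params <- function(family, params) {
  k <- n_params(family)
  if (length(params) != k) {
    stop(sprintf("family '%s' requires %d parameters, got %d",
                 family, k, length(params)))
  }
  if (family %in% c("double_sigmoid", "gen_double_sigmoid") &&
      params[[2]] == 0) {
    stop("double sigmoid requires beta != 0")
  }
  invisible(TRUE)
}

#' Evaluate a response-curve model
#'
#' Evaluates the named model family at condition values `x`.
#'
#' Parameterizations (parameters given in order):
#'
#' * flat: `f(x) = alpha`.
#' * linear: `f(x) = alpha + beta * x`.
#' * sigmoid `(alpha, beta, gamma, delta)`:
#'   `f(x) = alpha + (gamma - alpha) * expit(s * (x - delta))` with internal
#'   rate `s = 4 * beta / (gamma - alpha)`, so that `alpha` and `gamma` are
#'   the two steady-state levels, `delta` is the condition value of steepest
#'   change and `beta` is the maximum slope there (response units per
#'   condition unit).
#' * double sigmoid `(alpha, beta, gamma, delta, epsilon, phi)`:
#'   `f(x) = (1/beta) * [alpha + (beta - alpha) * expit(epsilon * (x - delta))]
#'   * [gamma + (beta - gamma) * expit(-epsilon * (x - phi))]`.
#'   For `epsilon > 0` the curve runs from level `alpha` (small x) through an
#'   intermediate level governed by `beta` to level `gamma` (large x):
#'   an impulse when `beta` lies outside `[alpha, gamma]`, a step when inside.
#' * generalized double sigmoid: same with the second factor's exponent slope
#'   `-epsilon` replaced by `-lambda * epsilon`, allowing unequal slopes on
#'   the two transitions.
#' * poly3/5/7: polynomial in `x`, coefficients in increasing-degree order,
#'   evaluated by Horner's scheme.
#'
#' @param family One of [CURVE_FAMILIES].
#' @param params Numeric parameter vector of the family's arity.
#' @param x Numeric vector of condition values.
#' @return Numeric vector of responses, `length(x)`.
#' @examples
#' curve_eval("sigmoid", c(0, 1, 1, 5), 5)  # 0.5: logistic midpoint
#' @export
curve_eval <- function(family, params, x) {
  family <- match.arg(family, CURVE_FAMILIES)
  check_params(family, params)
  params <- as.numeric(params)
  switch(family,
    flat = rep.int(params[1], length(x)),
    linear = params[1] + params[2] * x,
    sigmoid = {
      a <- params[1]; b <- params[2]; g <- params[3]; d <- params[4]
      if (g == a) return(rep.int(a, length(x)))
      s <- 4 * b / (g - a)
      a + (g - a) * expit(s * (x - d))
    },
    double_sigmoid = eval_dbs(params[1], params[2], params[3], params[4],
                              params[5], params[6], 1, x),
    gen_double_sigmoid = eval_dbs(params[1], params[2], params[3], params[4],
                                  params[5], params[6], params[7], x),
    # polynomials: Horner in increasing-degree coefficients
    {
      coefs <- rev(params)
      out <- rep.int(coefs[1], length(x))
      for (cf in coefs[-1]) out <- out * x + cf
      out
    }
  )
}

eval_dbs <- function(a, b, g, d, e, phi, lambda, x) {
  (1 / b) *
    (a + (b - a) * expit(e * (x - d))) *
    (g + (b - g) * expit(-lambda * e * (x - phi)))
}

#' Canonical form of double-sigmoid parameters
#'
#' The (generalized) double sigmoid is over-parameterized: two exact gauge
#' symmetries map a parameter vector onto a different vector with the
#' identical curve — (i) swapping the two logistic factors,
#' `(alpha, beta, gamma, delta, epsilon, phi) -> (gamma, beta, alpha, phi,
#' -epsilon, delta)` (for the generalized model the exponent rates swap too:
#' `epsilon -> -lambda * epsilon`, `lambda -> 1/lambda`), and (ii) swapping
#' the transition locations with a conjugate intermediate level,
#' `(alpha, alpha*gamma/beta, gamma, phi, epsilon, delta)` (generalized:
#' `epsilon -> lambda * epsilon`, `lambda -> 1/lambda`). Parameter vectors
#' are therefore only comparable after reduction to a canonical
#' representative: `epsilon > 0` and `delta <= phi`.
#'
#' @param params Numeric parameter vector (length 6 or 7).
#' @return Parameter vector of the same length describing the same curve.
#' @export
canonical_dbs <- function(params) {
  p <- as.numeric(params)
  stopifnot(length(p) %in% c(6, 7))
  gds <- length(p) == 7
  if (p[5] < 0) {
    p <- if (gds) {
      c(p[3], p[2], p[1], p[6], -p[7] * p[5], p[4], 1 / p[7])
    } else {
      c(p[3], p[2], p[1], p[6], -p[5], p[4])
    }
  }
  if (p[4] > p[6] && p[2] != 0) {
    p <- if (gds) {
      c(p[1], p[1] * p[3] / p[2], p[3], p[6], p[7] * p[5], p[4], 1 / p[7])
    } else {
      c(p[1], p[1] * p[3] / p[2], p[3], p[6], p[5], p[4])
    }
  }
  names(p) <- param_names(if (gds) "gen_double_sigmoid" else "double_sigmoid")
  p
}

#' All gauge-equivalent double-sigmoid parameter vectors
#'
#' Returns the (up to four) parameter vectors that describe the identical
#' curve under the two gauge symmetries documented in [canonical_dbs].
#' Comparing two parameter vectors of this family means comparing one
#' against the closest member of the other's orbit; the canonical
#' representative alone can sit on an unstable branch when `beta` is near 0
#' (the conjugate level `alpha*gamma/beta` diverges).
#'
#' @param params Numeric parameter vector (length 6 or 7).
#' @return List of parameter vectors (the orbit, including `params` itself).
#' @export
dbs_orbit <- function(params) {
  p <- as.numeric(params)
  stopifnot(length(p) %in% c(6, 7))
  gds <- length(p) == 7
  swap1 <- function(q) if (gds) {
    c(q[3], q[2], q[1], q[6], -q[7] * q[5], q[4], 1 / q[7])
  } else c(q[3], q[2], q[1], q[6], -q[5], q[4])
  swap2 <- function(q) if (q[2] == 0) NULL else if (gds) {
    c(q[1], q[1] * q[3] / q[2], q[3], q[6], q[7] * q[5], q[4], 1 / q[7])
  } else c(q[1], q[1] * q[3] / q[2], q[3], q[6], q[5], q[4])
  orbit <- list(p, swap1(p))
  s2 <- swap2(p)
  if (!is.null(s2)) orbit <- c(orbit, list(s2, swap1(s2)))
  orbit
}

#' First derivative of a response-curve model
#'
#' Analytic derivatives for flat/linear/sigmoid/polynomial; the double-sigmoid
#' families use a centered finite difference with step scaled to the curve's
#' own slope parameter. Used for steady-state detection (boundary slopes) and
#' transition-point location.
#'
#' @inheritParams curve_eval
#' @return Numeric vector of df/dx at `x`.
#' @keywords internal
curve_deriv <- function(family, params, x) {
  family <- match.arg(family, CURVE_FAMILIES)
  check_params(family, params)
  params <- as.numeric(params)
  switch(family,
    flat = rep.int(0, length(x)),
    linear = rep.int(params[2], length(x)),
    sigmoid = {
      a <- params[1]; b <- params[2]; g <- params[3]; d <- params[4]
      if (g == a) return(rep.int(0, length(x)))
      s <- 4 * b / (g - a)
      p <- expit(s * (x - d))
      (g - a) * s * p * (1 - p)
    },
    {
      # numeric central difference; h tied to the transition slope scale
      h <- if (family %in% c("double_sigmoid", "gen_double_sigmoid")) {
        min(1e-4, 1e-3 / max(abs(params[5]), 1))
      } else 1e-6 * max(1, abs(x))
      (curve_eval(family, params, x + h) -
         curve_eval(family, params, x - h)) / (2 * h)
    }
  )
}
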