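#' Control parameters for curve fitting, selection and comparison
#'
#' Collects every tunable knob of the pipeline in one place.
#'
#' @param good_fit_rpe RPE threshold (percent) below or at which a fit counts
#'   as good; genes whose best curve exceeds it report no curve. Default 10.
#' @param leeway_rpe Parsimony leeway (percentage points): a curve with fewer
#'   parameters than the best-fitting curve is preferred when its RPE is
#'   within this margin of the best RPE. Default 5.
#' @param steady_slope Boundary-derivative magnitude (response units per
#'   condition unit) at or below which a curve end counts as a steady state,
#'   separating sigmoid / hockey / transition shapes. Default 0.10.
#' @param grid_points Number of evenly spaced grid points over the condition
#'   range used for interior-extremum detection and transition-point location.
#'   Default 1001.
#' @param hm_threshold,hc_threshold Percent thresholds above which the
#'   heterometry / heterochrony flags are set. Default 10.
#' @param max_model The most complex family fit: `"gen_double_sigmoid"`
#'   (needs >= 14 points) or `"double_sigmoid"` (needs >= 12).
#' @param include_polynomials Add polynomial controls (degrees 3, 5, 7) to
#'   the candidate set. Default `FALSE`.
#' @param ftol,ptol Levenberg–Marquardt convergence tolerances. Default 1e-10.
#' @param maxfev Maximum residual-function evaluations per start. Default 2000.
#' @param seed RNG seed used by any randomized component (the synthetic
#'   generator); the fitting itself is deterministic.
#' @return A named list of class `curve_control`.
#' @export
curve_control <- function(good_fit_rpe = 10, leeway_rpe = 5,
                          steady_slope = 0.10, grid_points = 1001,
                          hm_threshold = 10, hc_threshold = 10,
                          max_model = c("gen_double_sigmoid", "double_sigmoid"),
                          include_polynomials = FALSE,
                          ftol = 1e-10, ptol = 1e-10, maxfev = 2000,
                          seed = 20140214) {
  max_model <- match.arg(max_model)
  stopifnot(good_fit_rpe >= 0, leeway_rpe >= 0, steady_slope >= 0,
            grid_points >= 11)
  structure(list(good_fit_rpe = good_fit_rpe, leeway_rpe = leeway_rpe,
                 steady_slope = steady_slope, grid_points = grid_points,
                 hm_threshold = hm_threshold, hc_threshold = hc_threshold,
                 max_model = max_model,
                 include_polynomials = include_polynomials,
                 ftol = ftol, ptol = ptol, maxfev = maxfev, seed = seed),
            class = "curve_control")
}
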