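# Default shape mixture: emulates the relative prevalence of reported curve
# families seen in comparative developmental expression data — sigmoid and
# hockey dominate, lines are common, impulses and steps are uncommon, flat
# and the generalized (+) shapes are rare.
default_mixture <- function() {
  c(flat = 0.05, line = 0.15, transition = 0.03, hockey = 0.20,
    sigmoid = 0.35, impulse = 0.10, step = 0.07,
    `impulse+` = 0.03, `step+` = 0.02)
}

fake_fit <- function(family, params) {
  names(params) <- param_names(family)
  structure(list(family = family, params = params, converged = TRUE),
            class = "curve_fit")
}

true_label <- function(family, params, x_range, control = curve_control()) {
  classify_fit(fake_fit(family, params), x_range, control)
}

# Sample true parameters for one gene of the requested shape. Levels live on
# a log2-expression-like scale in [0, 12]; transition locations sit in the
# central part of the condition range (leaving room for a planted shift of
# `hc` fraction of the range); maximum slopes are kept in a band that leaves
# the shapes identifiable from 7 fitted points.
sample_params <- function(shape, x, hc = 0) {
  xr <- max(x) - min(x)
  x0 <- min(x)
  up <- stats::runif(1) < 0.5
  sl_scale <- 13 / xr  # slope band calibrated to a unit-spaced 14-point axis
  switch(shape,
    flat = list(family = "flat", params = stats::runif(1, 2, 10)),
    line = {
      rise <- stats::runif(1, 4, 10)
      beta <- (if (up) 1 else -1) * rise / xr
      alpha <- if (up) stats::runif(1, 0.5, 11.5 - rise)
               else stats::runif(1, 0.5 + rise, 11.5)
      list(family = "linear", params = c(alpha, beta))
    },
    sigmoid = {
      gap <- stats::runif(1, 4, 8) * (if (up) 1 else -1)
      alpha <- if (up) stats::runif(1, 1, 11 - gap)
               else stats::runif(1, 1 - gap, 11)
      beta <- (if (up) 1 else -1) * stats::runif(1, 1.0, 2.5) * sl_scale
      delta <- x0 + stats::runif(1, 0.35, max(0.36, 0.65 - hc)) * xr
      list(family = "sigmoid", params = c(alpha, beta, alpha + gap, delta))
    },
    hockey = {
      gap <- stats::runif(1, 4, 8) * (if (up) 1 else -1)
      alpha <- if (up) stats::runif(1, 1, 11 - gap)
               else stats::runif(1, 1 - gap, 11)
      # slope capped at 1.1: a steeper jump falling between two fitted points
      # is unpredictable at the held-out points and the truth stops being
      # recoverable by any method that sees only every other observation
      beta <- (if (up) 1 else -1) * stats::runif(1, 0.8, 1.1) * sl_scale
      # transition near the right edge: the left steady state is reached,
      # the right one is cut off (window shifts left to absorb a planted
      # heterochrony shift)
      hi <- 0.90 - hc
      delta <- x0 + stats::runif(1, hi - 0.08, hi) * xr
      list(family = "sigmoid", params = c(alpha, beta, alpha + gap, delta))
    },
    transition = {
      gap <- stats::runif(1, 7, 10) * (if (up) 1 else -1)
      alpha <- if (up) stats::runif(1, 0.5, 11.5 - gap)
               else stats::runif(1, 0.5 - gap, 11.5)
      beta <- (if (up) 1 else -1) * stats::runif(1, 0.30, 0.45) * sl_scale
      delta <- x0 + stats::runif(1, 0.45, max(0.46, 0.55 - hc)) * xr
      list(family = "sigmoid", params = c(alpha, beta, alpha + gap, delta))
    },
    impulse = ,
    `impulse+` = {
      a <- stats::runif(1, 1, 4)
      g <- stats::runif(1, 1, 4)
      if (up) {
        b <- max(a, g) + stats::runif(1, 4, 7)  # interior peak
      } else {
        a <- a + 7; g <- g + 7
        b <- min(a, g) - stats::runif(1, 4, 7)  # interior trough
      }
      delta <- x0 + stats::runif(1, 0.25, max(0.26, 0.36 - hc)) * xr
      phi <- x0 + stats::runif(1, 0.62, max(0.63, 0.74 - hc)) * xr
      eps <- stats::runif(1, 1.3, 2.5) * 14 / xr
      if (shape == "impulse") {
        list(family = "double_sigmoid", params = c(a, b, g, delta, eps, phi))
      } else {
        lam <- if (stats::runif(1) < 0.5) stats::runif(1, 0.4, 0.6)
               else stats::runif(1, 1.8, 2.6)
        list(family = "gen_double_sigmoid",
             params = c(a, b, g, delta, eps, phi, lam))
      }
    },
    step = ,
    `step+` = {
      gap <- stats::runif(1, 6, 9) * (if (up) 1 else -1)
      a <- if (up) stats::runif(1, 1, 11 - gap) else stats::runif(1, 1 - gap, 11)
      g <- a + gap
      b <- a + gap * stats::runif(1, 0.4, 0.6)
      delta <- x0 + stats::runif(1, 0.22, max(0.23, 0.34 - hc)) * xr
      phi <- x0 + stats::runif(1, 0.64, max(0.65, 0.76 - hc)) * xr
      eps <- stats::runif(1, 1.8, 3.0) * 14 / xr
      if (shape == "step") {
        list(family = "double_sigmoid", params = c(a, b, g, delta, eps, phi))
      } else {
        lam <- if (stats::runif(1) < 0.5) stats::runif(1, 0.5, 0.7)
               else stats::runif(1, 1.5, 2.2)
        list(family = "gen_double_sigmoid",
             params = c(a, b, g, delta, eps, phi, lam))
      }
    },
    stop("cannot sample shape: ", shape)
  )
}

# Reject sigmoid-family draws whose endpoint slopes sit near the steady-state
# threshold: borderline truths flip between sigmoid/hockey/transition under
# noise, making the planted label meaningless rather than hard.
slope_margin_ok <- function(family, params, x_range, control) {
  if (family != "sigmoid") return(TRUE)
  sl <- abs(curve_deriv(family, params, x_range))
  thr <- control$steady_slope
  all(sl <= 0.5 * thr | sl >= 2 * thr)
}

shift_params <- function(family, params, dx, dy) {
  p <- params
  switch(family,
    flat = p[1] <- p[1] + dy,
    linear = p[1] <- p[1] + dy,
    sigmoid = { p[1] <- p[1] + dy; p[3] <- p[3] + dy; p[4] <- p[4] + dx },
    double_sigmoid = ,
    gen_double_sigmoid = {
      p[1:3] <- p[1:3] + dy; p[4] <- p[4] + dx; p[6] <- p[6] + dx
    })
  p
}

#' Generate synthetic two-scenario expression matrices with planted truth
#'
#' Draws a curve shape per gene from `mixture`, samples identifiable true
#' parameters (levels on a log2-expression-like scale in \[0, 12\],
#' transitions in the central part of the condition range, maximum slopes
#' calibrated to the axis), derives scenario 2 from scenario 1 by planting a
#' heterochrony shift (`planted_hc` fraction of the condition range, applied
#' to the transition locations) and a heterometry shift (`planted_hm`: the
#' vertical offset is chosen so that the measured HM statistic equals
#' `100 * planted_hm` at zero noise), and adds i.i.d. Gaussian noise.
#'
#' Each gene's true labels (derived from the true parameters by the same
#' classifier used on fits) are checked; parameter draws whose label does not
#' match the requested shape in both scenarios are redrawn, so the returned
#' truth table is exact at zero noise.
#'
#' @param n_genes Number of genes.
#' @param x Condition values (default the 14-point axis `1:14`).
#' @param mixture Named probability vector over shapes (must sum to 1);
#'   default mixes all nine biologically relevant shapes.
#' @param noise_sd Gaussian noise standard deviation, response units.
#'   Default 0.25 (a typical replicate-mean residual scale for log2
#'   expression levels spanning \[0, 12\]).
#' @param planted_hc Heterochrony shift as a fraction of the condition range.
#' @param planted_hm Heterometry shift: target HM statistic / 100.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return A list of class `synth_expression`: `mat_1`, `mat_2` (gene x
#'   condition matrices), `x`, and `truth` (data frame with gene_id, shape,
#'   direction, label_1, label_2, family, planted_hc, planted_hm, noise_sd,
#'   and list-columns params_1, params_2).
#' @examples
#' syn <- synth_expression(5, seed = 1)
#' dim(syn$mat_1)
#' @export
synth_expression <- function(n_genes, x = 1:14, mixture = default_mixture(),
                             noise_sd = 0.25, planted_hc = 0,
                             planted_hm = 0, seed = 20140214) {
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  if (is.null(names(mixture)) ||
      !all(names(mixture) %in% SHAPE_ORDER[1:9])) {
    stop("mixture names must be curve shapes")
  }
  stopifnot(n_genes >= 0, planted_hc >= 0, planted_hc < 0.3,
            planted_hm >= 0, planted_hm < 1)
  set.seed(seed)
  n_x <- length(x)
  x_range <- range(x)
  xr <- diff(x_range)
  control <- curve_control()

  mat_1 <- matrix(numeric(0), nrow = n_genes, ncol = n_x)
  mat_2 <- matrix(numeric(0), nrow = n_genes, ncol = n_x)
  rows <- vector("list", n_genes)
  shapes <- if (n_genes > 0) {
    sample(names(mixture), n_genes, replace = TRUE, prob = mixture)
  } else character(0)

  for (i in seq_len(n_genes)) {
    shape <- shapes[i]
    for (try in 1:200) {
      draw <- sample_params(shape, x, hc = planted_hc)
      p1 <- draw$params
      lab1 <- true_label(draw$family, p1, x_range, control)
      if (lab1$shape != shape) next
      if (!slope_margin_ok(draw$family, p1, x_range, control)) next
      # vertical offset giving HM = 100 * planted_hm at zero noise
      dy <- if (planted_hm > 0) {
        cp <- characteristic_points(lab1, x_range)
        v <- curve_eval(draw$family, p1, cp)
        r <- max(v) - min(v)
        if (r < 1e-9) planted_hm else planted_hm * r / (1 - planted_hm)
      } else 0
      p2 <- shift_params(draw$family, p1, dx = planted_hc * xr, dy = dy)
      lab2 <- true_label(draw$family, p2, x_range, control)
      if (lab2$shape != shape || lab2$direction != lab1$direction) next
      rows[[i]] <- list(shape = shape, direction = lab1$direction,
                        label_1 = lab1$label, label_2 = lab2$label,
                        family = draw$family, p1 = p1, p2 = p2)
      break
    }
    if (is.null(rows[[i]])) {
      stop("could not realize shape '", shape, "' for gene ", i)
    }
  }

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  mat_1 <- matrix(NA_real_, n_genes, n_x,
                  dimnames = list(gene_ids, paste0("x", x)))
  mat_2 <- mat_1
  for (i in seq_len(n_genes)) {
    mu1 <- curve_eval(rows[[i]]$family, rows[[i]]$p1, x)
    mu2 <- curve_eval(rows[[i]]$family, rows[[i]]$p2, x)
    mat_1[i, ] <- mu1 + stats::rnorm(n_x, 0, noise_sd)
    mat_2[i, ] <- mu2 + stats::rnorm(n_x, 0, noise_sd)
  }
  truth <- data.frame(
    gene_id = gene_ids,
    shape = vapply(rows, `[[`, "", "shape"),
    direction = vapply(rows, `[[`, "", "direction"),
    label_1 = vapply(rows, `[[`, "", "label_1"),
    label_2 = vapply(rows, `[[`, "", "label_2"),
    family = vapply(rows, `[[`, "", "family"),
    planted_hc = rep(planted_hc, n_genes),
    planted_hm = rep(planted_hm, n_genes),
    noise_sd = rep(noise_sd, n_genes),
    stringsAsFactors = FALSE)
  truth$params_1 <- I(lapply(rows, `[[`, "p1"))
  truth$params_2 <- I(lapply(rows, `[[`, "p2"))
  structure(list(mat_1 = mat_1, mat_2 = mat_2, x = x, truth = truth),
            class = "synth_expression")
}

#' @export
print.synth_expression <- function(x, ...) {
  cat(sprintf("<synth_expression: %d genes x %d conditions, noise sd %.3g>\n",
              nrow(x$mat_1), ncol(x$mat_1), unique(x$truth$noise_sd)[1]))
  if (nrow(x$truth) > 0) print(table(x$truth$shape))
  invisible(x)
}

#' Write a synthetic bundle to TSV files
#'
#' Writes `scenario1.tsv`, `scenario2.tsv` (the dialect [read_response_matrix]
#' reads) and `truth.tsv` (parameters serialized comma-separated) into `dir`.
#'
#' @param syn A `synth_expression` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(syn, dir) {
  stopifnot(inherits(syn, "synth_expression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_response_matrix(syn$mat_1, file.path(dir, "scenario1.tsv"), syn$x)
  write_response_matrix(syn$mat_2, file.path(dir, "scenario2.tsv"), syn$x)
  tr <- syn$truth
  tr$params_1 <- vapply(tr$params_1, function(p) paste(p, collapse = ","), "")
  tr$params_2 <- vapply(tr$params_2, function(p) paste(p, collapse = ","), "")
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
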