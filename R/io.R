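#' Read a response matrix from delimited text
#'
#' Expects a header row (condition labels) and a first column of gene IDs;
#' remaining cells are numeric responses. Missing, blank or non-numeric cells
#' and duplicated gene IDs are rejected with the offending row named.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Numeric matrix, genes in rows (rownames = gene IDs).
#' @export
read_response_matrix <- function(path, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("matrix file needs a gene-ID column plus responses")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num) | is.na(vals) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or missing cell at gene '%s' (row %d), column %d",
                 ids[bad[1, 1]], bad[1, 1], bad[1, 2]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write a response matrix as TSV
#'
#' Inverse of [read_response_matrix].
#'
#' @param mat Numeric matrix with gene-ID rownames.
#' @param path Output path.
#' @param x Optional condition values used as column headers.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(mat, path, x = NULL) {
  cn <- if (!is.null(x)) paste0("x", x) else colnames(mat)
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", cn)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

selection_row <- function(gc) {
  rep <- gc$selection$reported
  A <- gc$selection$curve_A
  data.frame(
    gene_id = gc$gene_id,
    reported = !is.null(rep),
    label = if (is.null(rep)) NA_character_ else rep$label,
    shape = if (is.null(rep)) NA_character_ else rep$shape,
    direction = if (is.null(rep)) NA_character_ else rep$direction,
    family = if (is.null(rep)) NA_character_ else rep$family,
    n_params = if (is.null(rep)) NA_integer_ else rep$n_params,
    rpe = if (is.null(rep)) NA_real_ else rep$rpe,
    aic = if (is.null(rep)) NA_real_ else rep$aic,
    curve_A = A$label, rpe_A = A$rpe,
    is_curve_B = !is.null(gc$selection$curve_B),
    stringsAsFactors = FALSE)
}

#' Run the full two-scenario comparison pipeline
#'
#' For every gene: fit the model cascade independently in each scenario
#' ([fit_gene_curves]), and — for genes with a reported (good-fitting) curve
#' in *both* scenarios — compute the pair comparison ([compare_pair]).
#' Genes where the optimizer fails outright are logged and skipped, never
#' fatal.
#'
#' @param mat_1,mat_2 Numeric gene x condition matrices with identical gene
#'   IDs as rownames and one column per condition value.
#' @param x Condition values (strictly increasing, length = `ncol(mat_1)`).
#' @param control A [curve_control] list.
#' @param scenario_names Length-2 labels for reports and plots.
#' @param keep_fits Keep the per-gene `gene_curves` objects (needed for
#'   plotting; drop to save memory on very large runs).
#' @return An object of class `curve_comparison`: `selections_1`,
#'   `selections_2` (per-gene selection tables), `pairs` (per-gene HM/HC/flag
#'   table for genes reported in both scenarios), `genes` (per-gene fit
#'   bundles when `keep_fits`), `n_both`, `n_one`, `n_neither`, plus inputs.
#' @export
compare_scenarios <- function(mat_1, mat_2, x, control = curve_control(),
                              scenario_names = c("scenario_1", "scenario_2"),
                              keep_fits = TRUE) {
  if (!is.matrix(mat_1) || !is.matrix(mat_2)) stop("inputs must be matrices")
  if (!identical(dim(mat_1), dim(mat_2))) {
    stop("the two matrices must have identical dimensions")
  }
  if (!identical(rownames(mat_1), rownames(mat_2))) {
    stop("the two matrices must have identical gene IDs")
  }
  if (ncol(mat_1) != length(x)) {
    stop("condition vector length must equal the column count")
  }
  if (control$max_model == "gen_double_sigmoid" && length(x) < 14) {
    stop("max_model 'gen_double_sigmoid' requires >= 14 condition values")
  }
  ids <- rownames(mat_1)
  if (is.null(ids)) ids <- sprintf("g%05d", seq_len(nrow(mat_1)))

  sel1 <- vector("list", length(ids))
  sel2 <- vector("list", length(ids))
  genes <- if (keep_fits) stats::setNames(vector("list", length(ids)), ids)
  pair_rows <- list()
  failures <- character(0)

  for (i in seq_along(ids)) {
    g1 <- tryCatch(fit_gene_curves(x, mat_1[i, ], ids[i], control),
                   error = function(e) e)
    g2 <- tryCatch(fit_gene_curves(x, mat_2[i, ], ids[i], control),
                   error = function(e) e)
    if (inherits(g1, "error") || inherits(g2, "error")) {
      failures <- c(failures, ids[i])
      next
    }
    sel1[[i]] <- selection_row(g1)
    sel2[[i]] <- selection_row(g2)
    cmp <- NULL
    if (!is.null(g1$selection$reported) && !is.null(g2$selection$reported)) {
      cmp <- compare_pair(g1, g2, control)
      pair_rows[[length(pair_rows) + 1]] <- as_pairs_df(list(cmp))
    }
    if (keep_fits) {
      genes[[ids[i]]] <- list(scenario_1 = g1, scenario_2 = g2,
                              comparison = cmp)
    }
  }
  selections_1 <- do.call(rbind, sel1)
  selections_2 <- do.call(rbind, sel2)
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    as_pairs_df(list())
  rep1 <- selections_1$reported
  rep2 <- selections_2$reported
  structure(list(
    selections_1 = selections_1, selections_2 = selections_2,
    pairs = pairs, genes = if (keep_fits) genes,
    n_both = sum(rep1 & rep2), n_one = sum(xor(rep1, rep2)),
    n_neither = sum(!rep1 & !rep2), failures = failures,
    x = x, control = control, scenario_names = scenario_names
  ), class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  n <- nrow(x$selections_1)
  cat(sprintf("Two-scenario curve comparison (%s vs %s): %d genes\n",
              x$scenario_names[1], x$scenario_names[2], n))
  cat(sprintf("good fits: both scenarios %d (%.1f%%), one %d (%.1f%%), neither %d (%.1f%%)\n",
              x$n_both, 100 * x$n_both / n,
              x$n_one, 100 * x$n_one / n,
              x$n_neither, 100 * x$n_neither / n))
  if (length(x$failures)) {
    cat("fit failures (skipped):", paste(x$failures, collapse = ", "), "\n")
  }
  if (!is.null(x$pairs) && nrow(x$pairs) > 0) {
    cat(sprintf("pairs: %d heteromorphy, %d heterochrony flag, %d heterometry flag\n",
                sum(x$pairs$heteromorphy), sum(x$pairs$heterochrony_flag),
                sum(x$pairs$heterometry_flag)))
  }
  invisible(x)
}

#' @export
summary.curve_comparison <- function(object, min_count = 5, ...) {
  summary_table(object$pairs, min_count)
}

#' @export
plot.curve_comparison <- function(x, gene_id, ...) {
  if (is.null(x$genes)) stop("run compare_scenarios with keep_fits = TRUE")
  g <- x$genes[[gene_id]]
  if (is.null(g)) stop("unknown or failed gene: ", gene_id)
  graphics::par(mfrow = c(1, 2))
  plot(g$scenario_1, main = paste(x$scenario_names[1], gene_id), ...)
  plot(g$scenario_2, main = paste(x$scenario_names[2], gene_id), ...)
  invisible(x)
}

#' Run a comparison from a YAML/JSON config file
#'
#' The config mirrors the nine driver inputs: `matrix_1`, `matrix_2` (TSV
#' paths), `conditions` (numeric vector), `condition_label`,
#' `response_label`, `scenario_names` (length 2), `scenario_prefixes`,
#' and optional threshold knobs (`good_fit_rpe`, `leeway_rpe`,
#' `steady_slope`, `grid_points`, `hm_threshold`, `hc_threshold`,
#' `max_model`, `include_polynomials`, `seed`).
#'
#' @param config Path to a YAML (or JSON) config file, or an equivalent list.
#' @param out_dir Output directory for [write_report] (`NULL` to skip
#'   writing).
#' @param plots Emit per-gene plots.
#' @return The `curve_comparison`, invisibly.
#' @export
run_comparison <- function(config, out_dir = NULL, plots = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required to read YAML configs")
      }
      yaml::read_yaml(config)
    }
  }
  req <- c("matrix_1", "matrix_2", "conditions")
  if (!all(req %in% names(config))) {
    stop("config must provide: ", paste(req, collapse = ", "))
  }
  x <- as.numeric(config$conditions)
  knobs <- intersect(names(config),
                     c("good_fit_rpe", "leeway_rpe", "steady_slope",
                       "grid_points", "hm_threshold", "hc_threshold",
                       "max_model", "include_polynomials", "seed"))
  control <- do.call(curve_control, config[knobs])
  if (control$max_model == "gen_double_sigmoid" && length(x) < 14) {
    stop("config error: max_model 'gen_double_sigmoid' requires >= 14 ",
         "condition values, got ", length(x))
  }
  mat_1 <- read_response_matrix(config$matrix_1)
  mat_2 <- read_response_matrix(config$matrix_2)
  scen <- config$scenario_names %||% c("scenario_1", "scenario_2")
  comp <- compare_scenarios(mat_1, mat_2, x, control, scenario_names = scen)
  if (!is.null(out_dir)) write_report(comp, out_dir, plots = plots)
  invisible(comp)
}
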