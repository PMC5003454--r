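BIO_SHAPES <- SHAPE_ORDER[1:9]

# direction used for stratifying a pair: a flat curve uses its underlying
# linear trend (`trend_*`, computed by compare_pair) when available, else
# inherits the other curve's direction; an entirely directionless pair goes
# to the U/U stratum
effective_directions <- function(pairs) {
  d1 <- if ("trend_1" %in% names(pairs)) pairs$trend_1 else pairs$direction_1
  d2 <- if ("trend_2" %in% names(pairs)) pairs$trend_2 else pairs$direction_2
  swp <- d1 == "none" & d2 != "none"
  d1[swp] <- d2[swp]
  swp <- d2 == "none" & d1 != "none"
  d2[swp] <- d1[swp]
  d1[d1 == "none"] <- "U"
  d2[d2 == "none"] <- "U"
  data.frame(dir_1 = d1, dir_2 = d2, stringsAsFactors = FALSE)
}

as_pairs_df <- function(pairs) {
  if (is.data.frame(pairs)) return(pairs)
  if (length(pairs) == 0) {
    return(data.frame(gene_id = character(0), label_1 = character(0),
                      label_2 = character(0), shape_1 = character(0),
                      shape_2 = character(0), direction_1 = character(0),
                      direction_2 = character(0), trend_1 = character(0),
                      trend_2 = character(0), heteromorphy = logical(0),
                      hm = numeric(0), hc = numeric(0),
                      heterometry_flag = logical(0),
                      heterochrony_flag = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(gene_id = if (is.null(p$gene_id)) NA_character_ else p$gene_id,
               label_1 = p$label_1, label_2 = p$label_2,
               shape_1 = p$shape_1, shape_2 = p$shape_2,
               direction_1 = p$direction_1, direction_2 = p$direction_2,
               trend_1 = if (is.null(p$trend_1)) p$direction_1 else p$trend_1,
               trend_2 = if (is.null(p$trend_2)) p$direction_2 else p$trend_2,
               heteromorphy = p$heteromorphy, hm = p$hm, hc = p$hc,
               heterometry_flag = p$heterometry_flag,
               heterochrony_flag = p$heterochrony_flag,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-tabulate reported curve-pair shapes for one direction stratum
#'
#' Builds the 9 x 9 count grid of reported shapes (scenario 1 in rows,
#' scenario 2 in columns, fixed order flat, line, transition, hockey,
#' sigmoid, impulse, step, impulse+, step+) over the pairs whose effective
#' directions match `dir_1`/`dir_2`. Flat curves carry no direction and are
#' stratified by the other curve's direction.
#'
#' @param pairs A data frame of pair comparisons (or list of
#'   `pair_comparison` objects) with columns `shape_1`, `shape_2`,
#'   `direction_1`, `direction_2`.
#' @param dir_1,dir_2 `"U"` or `"D"`: the stratum.
#' @return A list of class `curve_crosstab`: `counts` (9 x 9 integer matrix),
#'   `total`, `dir_1`, `dir_2`.
#' @export
curve_crosstab <- function(pairs, dir_1, dir_2) {
  stopifnot(dir_1 %in% c("U", "D"), dir_2 %in% c("U", "D"))
  pairs <- as_pairs_df(pairs)
  counts <- matrix(0L, 9, 9, dimnames = list(BIO_SHAPES, BIO_SHAPES))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    keep <- pairs$shape_1 %in% BIO_SHAPES & pairs$shape_2 %in% BIO_SHAPES
    pairs <- pairs[keep, , drop = FALSE]
    eff <- effective_directions(pairs)
    sel <- eff$dir_1 == dir_1 & eff$dir_2 == dir_2
    for (i in which(sel)) {
      counts[pairs$shape_1[i], pairs$shape_2[i]] <-
        counts[pairs$shape_1[i], pairs$shape_2[i]] + 1L
    }
  }
  structure(list(counts = counts, total = sum(counts),
                 dir_1 = dir_1, dir_2 = dir_2),
            class = "curve_crosstab")
}

#' @export
print.curve_crosstab <- function(x, ...) {
  cat(sprintf("Curve-pair counts, scenario 1 %s / scenario 2 %s (total %d)\n",
              x$dir_1, x$dir_2, x$total))
  print(x$counts)
  invisible(x)
}

#' Summary of frequent curve pairs with HC/HM flag counts
#'
#' Tabulates reported label pairs, keeping those with at least `min_count`
#' occurrences, with counts of genes flagged heterochrony-only,
#' heterometry-only, and both.
#'
#' @param pairs Pair comparisons (data frame or list of `pair_comparison`).
#' @param min_count Minimum pair count to keep a row. Default 5.
#' @return Data frame with columns `label_1`, `label_2`, `total`, `hc_only`,
#'   `hm_only`, `hc_and_hm`, sorted by decreasing total.
#' @export
summary_table <- function(pairs, min_count = 5) {
  pairs <- as_pairs_df(pairs)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(label_1 = character(0), label_2 = character(0),
                      total = integer(0), hc_only = integer(0),
                      hm_only = integer(0), hc_and_hm = integer(0)))
  }
  key <- paste(pairs$label_1, pairs$label_2, sep = "\r")
  agg <- lapply(split(pairs, key), function(d) {
    data.frame(label_1 = d$label_1[1], label_2 = d$label_2[1],
               total = nrow(d),
               hc_only = sum(d$heterochrony_flag & !d$heterometry_flag),
               hm_only = sum(d$heterometry_flag & !d$heterochrony_flag),
               hc_and_hm = sum(d$heterochrony_flag & d$heterometry_flag),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[out$total >= min_count, , drop = FALSE]
  out <- out[order(-out$total, out$label_1, out$label_2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-panel diagnostic plot for one gene pair
#'
#' Writes an SVG (or PDF) figure showing both scenarios side by side —
#' fitted points red, evaluation points black, reported curve blue,
#' comparison curve orange, HC/HM annotated — plus a JSON sidecar carrying
#' the labels, RPEs, HM and HC for machine-readable checks. Genes lacking a
#' reported curve in either scenario are skipped with a message and no file.
#'
#' @param gc_1,gc_2 `gene_curves` for the two scenarios.
#' @param comparison The `pair_comparison` for the gene (or `NULL` to skip
#'   the annotation).
#' @param file Output path (extension `.svg` or `.pdf`).
#' @param scenario_names Character length-2 panel titles.
#' @return The file path invisibly, or `NULL` if skipped.
#' @export
plot_gene_pair <- function(gc_1, gc_2, comparison = NULL, file,
                           scenario_names = c("scenario 1", "scenario 2")) {
  if (is.null(gc_1$selection$reported) || is.null(gc_2$selection$reported)) {
    message("skipping ", gc_1$gene_id %||% "gene",
            ": no reported curve in at least one scenario")
    return(invisible(NULL))
  }
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    grDevices::svg(file, width = 10, height = 5)
  } else {
    grDevices::pdf(file, width = 10, height = 5)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2))
  plot(gc_1, main = paste0(scenario_names[1], ": ",
                           gc_1$selection$reported$label))
  plot(gc_2, main = paste0(scenario_names[2], ": ",
                           gc_2$selection$reported$label))
  if (!is.null(comparison)) {
    graphics::mtext(sprintf("HM %.1f%%  HC %s",
                            comparison$hm,
                            if (is.na(comparison$hc)) "n/a"
                            else sprintf("%.1f%%", comparison$hc)),
                    side = 3, line = -1.5, outer = TRUE, cex = 0.9)
  }
  sidecar <- list(
    gene_id = gc_1$gene_id,
    label_1 = gc_1$selection$reported$label,
    label_2 = gc_2$selection$reported$label,
    rpe_1 = gc_1$selection$reported$rpe,
    rpe_2 = gc_2$selection$reported$rpe,
    comparison_1 = if (!is.null(gc_1$selection$comparison))
      gc_1$selection$comparison$label else NULL,
    comparison_2 = if (!is.null(gc_2$selection$comparison))
      gc_2$selection$comparison$label else NULL,
    hm = if (!is.null(comparison)) comparison$hm else NULL,
    hc = if (!is.null(comparison)) comparison$hc else NULL)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(file), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the full result bundle of a two-scenario comparison
#'
#' Writes, under `dir`: the four direction-stratified crosstabs
#' (`crosstab_DD.tsv`, `crosstab_DU.tsv`, `crosstab_UD.tsv`,
#' `crosstab_UU.tsv`), the frequent-pair summary (`summary.tsv`), per-gene
#' pair statistics (`pairs.tsv`), per-scenario selections
#' (`selections_1.tsv`, `selections_2.tsv`), gene lists under `gene_lists/`
#' (heteromorphy, heterochrony, heterometry), and optionally per-gene plots
#' under `plots/`.
#'
#' @param comp A `curve_comparison` (from [compare_scenarios]).
#' @param dir Output directory.
#' @param plots Emit per-gene SVG plots (can be slow for many genes).
#' @param min_count Passed to [summary_table].
#' @return `dir`, invisibly.
#' @export
write_report <- function(comp, dir, plots = FALSE, min_count = 5) {
  stopifnot(inherits(comp, "curve_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  for (d1 in c("D", "U")) for (d2 in c("D", "U")) {
    ct <- curve_crosstab(comp$pairs, d1, d2)
    out <- cbind(shape_1 = rownames(ct$counts), as.data.frame(ct$counts))
    wt(out, sprintf("crosstab_%s%s.tsv", d1, d2))
  }
  wt(summary_table(comp$pairs, min_count), "summary.tsv")
  if (!is.null(comp$pairs) && nrow(comp$pairs) > 0) wt(comp$pairs, "pairs.tsv")
  wt(comp$selections_1, "selections_1.tsv")
  wt(comp$selections_2, "selections_2.tsv")

  gl <- file.path(dir, "gene_lists")
  dir.create(gl, showWarnings = FALSE)
  p <- comp$pairs
  if (!is.null(p) && nrow(p) > 0) {
    writeLines(p$gene_id[p$heteromorphy], file.path(gl, "heteromorphy.txt"))
    writeLines(p$gene_id[p$heterochrony_flag], file.path(gl, "heterochrony.txt"))
    writeLines(p$gene_id[p$heterometry_flag], file.path(gl, "heterometry.txt"))
  }
  if (plots && !is.null(p) && nrow(p) > 0) {
    pd <- file.path(dir, "plots")
    dir.create(pd, showWarnings = FALSE)
    for (g in p$gene_id) {
      plot_gene_pair(comp$genes[[g]]$scenario_1, comp$genes[[g]]$scenario_2,
                     comp$genes[[g]]$comparison,
                     file.path(pd, paste0(g, ".svg")),
                     comp$scenario_names)
    }
  }
  invisible(dir)
}
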