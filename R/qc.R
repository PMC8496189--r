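#' Quality-control thresholds
#'
#' @param actb_gene housekeeping gene row used for the low-expression filter
#'   (default `"Actb"`).
#' @param actb_percentile percentile of the housekeeping log2-CPM below (or
#'   at) which cells are removed; default 1 (the 1st percentile).
#' @param min_total_counts minimum total raw counts; cells must strictly
#'   exceed it (default `2^16 = 65536`).
#' @param actb_scope `"dataset"` computes the percentile over all candidate
#'   cells, `"plate"` within each plate.
#' @param percentile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(actb_gene = "Actb", actb_percentile = 1,
                          min_total_counts = 65536L,
                          actb_scope = c("dataset", "plate"),
                          percentile_type = 7) {
  stopifnot(actb_percentile > 0, actb_percentile < 100, min_total_counts >= 0)
  structure(list(actb_gene = actb_gene, actb_percentile = actb_percentile,
                 min_total_counts = as.integer(min_total_counts),
                 actb_scope = match.arg(actb_scope),
                 percentile_type = percentile_type),
            class = "qc_thresholds")
}

#' Remove control wells, spike-ins, and undetected genes
#'
#' Drops bulk and empty control wells, genes whose id carries the `ERCC-`
#' spike-in prefix, and genes with zero counts across all remaining cells
#' (recomputed after the control wells are removed, so a gene detected only in
#' a control well is also dropped).
#'
#' @param counts genes x cells integer matrix with dimnames.
#' @param metadata data.frame with `cell_id` and `well_type` in
#'   `{single_cell, bulk_control, empty_control}` covering every column.
#' @return list with `counts` (filtered matrix), `metadata` (filtered rows)
#'   and `removed` (named counts per removal category).
#' @export
exclude_controls_and_spikeins <- function(counts, metadata) {
  if (!all(colnames(counts) %in% metadata$cell_id))
    stop("metadata does not cover cells: ",
         paste(utils::head(setdiff(colnames(counts), metadata$cell_id), 5),
               collapse = ", "))
  md <- metadata[match(colnames(counts), metadata$cell_id), , drop = FALSE]
  known <- c("single_cell", "bulk_control", "empty_control")
  bad <- !md$well_type %in% known
  if (any(bad))
    stop("unknown well_type for cell(s): ",
         paste(utils::head(md$cell_id[bad], 5), collapse = ", "))
  is_ctl <- md$well_type != "single_cell"
  keep_cells <- !is_ctl
  m <- counts[, keep_cells, drop = FALSE]
  is_spike <- startsWith(rownames(m), "ERCC-")
  m2 <- m[!is_spike, , drop = FALSE]
  zero_gene <- Matrix::rowSums(m2) == 0
  out <- m2[!zero_gene, , drop = FALSE]
  list(counts = out,
       metadata = md[keep_cells, , drop = FALSE],
       removed = c(control_wells = sum(is_ctl),
                   spikein_genes = sum(is_spike),
                   zero_genes = sum(zero_gene)))
}

#' Compute log2 counts-per-million expression
#'
#' `v_gc = log2(1e6 * x_gc / sum_g x_gc + 1)`: per-cell depth normalization to
#' one million, pseudocount 1, log2 transform. The transform is exactly
#' invertible: `sum_g (2^v - 1) = 1e6` for every cell.
#'
#' @param counts genes x cells count matrix; every cell must have positive
#'   total counts.
#' @return numeric matrix of the same shape (class `log2cpm` attribute-free).
#' @export
compute_log_cpm <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(counts)[tot == 0], 5), collapse = ", "))
  v <- log2(sweep(as.matrix(counts), 2, tot, "/") * 1e6 + 1)
  dimnames(v) <- dimnames(counts)
  v
}

#' Filter cells with low total counts
#'
#' Keeps cells whose total raw counts strictly exceed
#' `thresholds$min_total_counts` (a cell at exactly the threshold is removed).
#'
#' @param counts genes x cells raw count matrix.
#' @param thresholds a [qc_thresholds()].
#' @return list with character vectors `kept` and `removed` (cell ids).
#' @export
filter_low_counts <- function(counts, thresholds = qc_thresholds()) {
  tot <- colSums(counts)
  keep <- tot > thresholds$min_total_counts
  list(kept = colnames(counts)[keep], removed = colnames(counts)[!keep])
}

#' Filter cells with low housekeeping-gene expression
#'
#' The threshold is the `actb_percentile` percentile (linear interpolation
#' between order statistics by default) of the housekeeping log2-CPM over all
#' candidate cells; cells strictly above the threshold are kept. If every cell
#' carries the same value the strict inequality removes all of them; this
#' degenerate case raises a warning.
#'
#' @param expr log2-CPM matrix from [compute_log_cpm()].
#' @param thresholds a [qc_thresholds()].
#' @param plate_of optional named vector mapping cell id to plate, required
#'   when `actb_scope = "plate"`.
#' @param threshold optional precomputed threshold(s) (named per scope
#'   group); reapplying the filter with its recorded threshold is a no-op,
#'   which makes the filter idempotent.
#' @return list with `kept`, `removed` (cell ids) and `threshold` (named
#'   numeric, one per scope group).
#' @export
filter_low_actb <- function(expr, thresholds = qc_thresholds(),
                            plate_of = NULL, threshold = NULL) {
  g <- thresholds$actb_gene
  if (!g %in% rownames(expr)) stop("housekeeping gene not found: ", g)
  v <- expr[g, ]
  p <- thresholds$actb_percentile / 100
  groups <- if (thresholds$actb_scope == "plate") {
    if (is.null(plate_of)) stop("plate scope requires plate_of")
    plate_of[colnames(expr)]
  } else rep("dataset", ncol(expr))
  thr <- if (!is.null(threshold)) {
    if (is.null(names(threshold)) && length(threshold) == 1)
      names(threshold) <- unique(groups)
    threshold
  } else tapply(v, groups, stats::quantile, probs = p,
                type = thresholds$percentile_type, names = FALSE)
  keep <- v > thr[groups]
  if (!any(keep) && length(v) > 0)
    warning("degenerate housekeeping distribution: all cells at or below the ",
            "percentile threshold")
  list(kept = colnames(expr)[keep], removed = colnames(expr)[!keep],
       threshold = thr)
}

#' Build a per-plate quality-control report
#'
#' One row per plate plus a `TOTAL` row. For every row
#' `passed = sequenced - low_read_count - low_actb` and
#' `pct_passed = round(100 * passed / sequenced, 2)` (IEEE half-to-even
#' rounding, which matches how such tables are conventionally printed).
#'
#' @param metadata data.frame with `cell_id`, `plate_id`, `condition` and
#'   optionally `sort_gate` for sequenced single cells.
#' @param outcomes named character vector over the same cells with values in
#'   `{"low_read", "low_actb", "passed"}`; each cell must have exactly one.
#' @return data.frame of class `qc_report` with columns `plate_id`,
#'   `sort_gate`, `condition`, `sequenced`, `low_read_count`, `low_actb`,
#'   `passed`, `pct_passed`.
#' @export
build_qc_report <- function(metadata, outcomes) {
  ids <- metadata$cell_id
  if (!setequal(names(outcomes), ids))
    stop("outcomes must cover exactly the sequenced cells")
  if (anyDuplicated(names(outcomes)))
    stop("cell(s) with more than one outcome: ",
         paste(utils::head(unique(names(outcomes)[duplicated(names(outcomes))]), 5),
               collapse = ", "))
  ok <- outcomes %in% c("low_read", "low_actb", "passed")
  if (!all(ok)) stop("invalid outcome values: ",
                     paste(utils::head(unique(outcomes[!ok]), 5), collapse = ", "))
  o <- outcomes[ids]
  sg <- if ("sort_gate" %in% names(metadata)) metadata$sort_gate else ""
  key <- data.frame(plate_id = metadata$plate_id, sort_gate = sg,
                    condition = metadata$condition, stringsAsFactors = FALSE)
  agg <- stats::aggregate(
    cbind(sequenced = rep(1L, nrow(key)),
          low_read_count = as.integer(o == "low_read"),
          low_actb = as.integer(o == "low_actb")),
    by = key, FUN = sum)
  agg <- agg[order(agg$plate_id), , drop = FALSE]
  total <- data.frame(plate_id = "TOTAL", sort_gate = "", condition = "",
                      sequenced = sum(agg$sequenced),
                      low_read_count = sum(agg$low_read_count),
                      low_actb = sum(agg$low_actb), stringsAsFactors = FALSE)
  agg <- rbind(agg, total)
  qc_report_from_counts(agg)
}

#' Derive passed/percent columns from plate accounting counts
#'
#' Completes a plate accounting table (sequenced / low-read / low-Actb counts
#' per row) with the `passed` and `pct_passed` columns under the row
#' invariant `passed = sequenced - low_read_count - low_actb`.
#'
#' @param tab data.frame with columns `sequenced`, `low_read_count`,
#'   `low_actb` (any identifier columns are carried through).
#' @return the table with `passed` and `pct_passed` appended, class
#'   `qc_report`.
#' @export
qc_report_from_counts <- function(tab) {
  need <- c("sequenced", "low_read_count", "low_actb")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  tab$passed <- tab$sequenced - tab$low_read_count - tab$low_actb
  tab$pct_passed <- round(100 * tab$passed / tab$sequenced, 2)
  class(tab) <- c("qc_report", "data.frame")
  tab
}

#' Run the full cell-level QC sequence
#'
#' Order of operations: control wells, spike-ins and undetected genes are
#' removed; the minimum-count rule (strictly greater than 2^16 by default) is
#' applied to raw totals; log2-CPM is computed on the survivors and the
#' housekeeping percentile rule is applied. A cell failing both rules is
#' attributed to the low-read category (the count filter runs first), so the
#' report categories are disjoint by construction.
#'
#' @param counts raw genes x cells matrix (controls/spike-ins still present).
#' @param metadata metadata covering all columns.
#' @param thresholds a [qc_thresholds()].
#' @return list with `counts` (QC-passed raw matrix), `expr` (log2-CPM of
#'   passed cells), `metadata` (passed rows), `report` (a `qc_report`),
#'   `outcomes` (named vector over sequenced single cells), `removed`
#'   (exclusion summary) and `actb_threshold`.
#' @export
run_qc <- function(counts, metadata, thresholds = qc_thresholds()) {
  ex <- exclude_controls_and_spikeins(counts, metadata)
  m <- ex$counts
  md <- ex$metadata
  lc <- filter_low_counts(m, thresholds)
  outcomes <- stats::setNames(rep("passed", ncol(m)), colnames(m))
  outcomes[lc$removed] <- "low_read"
  m2 <- m[, lc$kept, drop = FALSE]
  expr <- compute_log_cpm(m2)
  la <- filter_low_actb(expr, thresholds,
                        plate_of = stats::setNames(md$plate_id, md$cell_id))
  outcomes[la$removed] <- "low_actb"
  report <- build_qc_report(md, outcomes)
  keep <- la$kept
  list(counts = m2[, keep, drop = FALSE],
       expr = expr[, keep, drop = FALSE],
       metadata = md[match(keep, md$cell_id), , drop = FALSE],
       report = report, outcomes = outcomes, removed = ex$removed,
       actb_threshold = la$threshold)
}
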