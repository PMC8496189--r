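#' One-vs-rest cluster marker detection
#'
#' For every cluster with at least 3 cells, each gene's in-cluster and
#' out-of-cluster detection fractions (`expression > 0`) and natural-log fold
#' change `ln(mean(2^v - 1) + 1)_in - ln(mean(2^v - 1) + 1)_out` are computed.
#' Genes pass when `logFC >= logfc_threshold` and
#' `max(pct_in, pct_out) >= min_pct`; a Wilcoxon rank-sum test supplies the
#' p-value and Bonferroni correction is applied over the genes actually tested
#' for that cluster.
#'
#' @param expr log2-CPM matrix.
#' @param labels cluster labels named by (or aligned with) the columns.
#' @param logfc_threshold minimum natural-log fold change (default `log(2)`).
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param min_diff_pct optional minimum `pct_in - pct_out` (default 0: off).
#' @param min_pct_in optional minimum in-cluster fraction (default 0: off).
#' @return data.frame of class `marker_records` with `gene_id`, `cluster`,
#'   `log_fold_change`, `pct_in`, `pct_out`, `p_value`, `p_adjusted`.
#' @export
find_cluster_markers <- function(expr, labels, logfc_threshold = log(2),
                                 min_pct = 0.1, min_diff_pct = 0,
                                 min_pct_in = 0) {
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  labels <- as.character(labels)
  cl_levels <- sort(unique(labels))
  if (length(cl_levels) < 2) stop("need at least 2 clusters")
  d <- 2^expr - 1
  det <- expr > 0
  out <- list()
  for (cl in cl_levels) {
    inc <- labels == cl
    if (sum(inc) < 3) {
      warning("cluster skipped (fewer than 3 cells): ", cl)
      next
    }
    pct_in <- rowMeans(det[, inc, drop = FALSE])
    pct_out <- rowMeans(det[, !inc, drop = FALSE])
    lfc <- log(rowMeans(d[, inc, drop = FALSE]) + 1) -
      log(rowMeans(d[, !inc, drop = FALSE]) + 1)
    pass <- lfc >= logfc_threshold &
      pmax(pct_in, pct_out) >= min_pct &
      (pct_in - pct_out) >= min_diff_pct &
      pct_in >= min_pct_in
    genes <- which(pass)
    if (length(genes) == 0) next
    p <- vapply(genes, function(g)
      suppressWarnings(stats::wilcox.test(expr[g, inc], expr[g, !inc]))$p.value,
      numeric(1))
    out[[cl]] <- data.frame(gene_id = rownames(expr)[genes], cluster = cl,
                            log_fold_change = lfc[genes],
                            pct_in = pct_in[genes], pct_out = pct_out[genes],
                            p_value = p,
                            p_adjusted = pmin(1, p * length(genes)),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), cluster = character(0),
               log_fold_change = numeric(0), pct_in = numeric(0),
               pct_out = numeric(0), p_value = numeric(0),
               p_adjusted = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("marker_records", "data.frame")
  res
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' The reference library is the one whose 75th-percentile count fraction is
#' closest to the mean across libraries. For every other library, gene-wise
#' log2 ratios M (of library-size-scaled proportions against the reference,
#' over genes nonzero in both) are doubly trimmed: the most extreme
#' `trim_m` fraction by M on each side and `trim_a` by average log intensity
#' A. The factor is 2 to the precision-weighted (inverse asymptotic variance)
#' mean of the surviving M values, and factors are rescaled to geometric mean
#' 1.
#'
#' @param counts genes x libraries count matrix.
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_normalization_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  nlib <- ncol(counts)
  if (nlib < 2) stop("need at least 2 libraries")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; nr <- lib[ref]
  f <- numeric(nlib)
  for (j in seq_len(nlib)) {
    yo <- counts[, j]; no <- lib[j]
    keep <- yo > 0 & yr > 0
    if (!any(keep)) {
      warning("library shares no nonzero genes with the reference: ",
              colnames(counts)[j])
      f[j] <- 0
      next
    }
    M <- log2((yo[keep] / no) / (yr[keep] / nr))
    A <- (log2(yo[keep] / no) + log2(yr[keep] / nr)) / 2
    v <- (no - yo[keep]) / (no * yo[keep]) + (nr - yr[keep]) / (nr * yr[keep])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (length(M) == 0 || max(abs(M)) < 1e-6) {
      f[j] <- 0
      next
    }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[j] <- if (any(sel)) sum(M[sel] / v[sel]) / sum(1 / v[sel]) else 0
  }
  fac <- 2^f
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(counts))
}

#' Pairwise differential expression between two groups
#'
#' Counts are normalized to TMM-scaled log2-CPM (effective library size =
#' library size times TMM factor, pseudocount 1); the log fold change is the
#' difference of group means on that scale, the p-value a Wilcoxon rank-sum
#' test per gene, and the false discovery rate Benjamini-Hochberg. Moderated
#' (empirical-Bayes) linear models are deliberately not reimplemented; this
#' rank-based substitute is the documented contract.
#'
#' @param counts genes x libraries count matrix.
#' @param groupA,groupB column ids or indices, each of size >= 3, disjoint.
#' @return data.frame with `gene_id`, `logFC` (log2), `p`, `fdr`, ordered by
#'   `p`.
#' @export
pairwise_differential_expression <- function(counts, groupA, groupB) {
  counts <- as.matrix(counts)
  if (is.character(groupA)) groupA <- match(groupA, colnames(counts))
  if (is.character(groupB)) groupB <- match(groupB, colnames(counts))
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("both groups need at least 3 libraries")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  sel <- c(groupA, groupB)
  sub <- counts[, sel, drop = FALSE]
  fac <- tmm_normalization_factors(sub)
  eff <- colSums(sub) * fac
  v <- log2(sweep(sub, 2, eff, "/") * 1e6 + 1)
  ia <- seq_along(groupA)
  ib <- length(groupA) + seq_along(groupB)
  lfc <- rowMeans(v[, ia, drop = FALSE]) - rowMeans(v[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(v)), function(g) {
    if (all(sub[g, ] == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v[g, ia], v[g, ib]))$p.value
  }, numeric(1))
  lfc[rowSums(sub) == 0] <- 0
  out <- data.frame(gene_id = rownames(counts), logFC = lfc, p = p,
                    fdr = stats::p.adjust(p, "BH"), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$gene_id), , drop = FALSE]
}

#' Transcription-factor correlogram construction
#'
#' Marker records are restricted to a transcription factor list, filtered by
#' detection-fraction difference, fold change, in-cluster detection and FDR,
#' and at most `top_n` TFs per cluster are kept by fold change. A TF claimed
#' by several clusters is owned by the one where its fold change is largest.
#' The output correlation matrix is the Pearson correlation of the selected
#' TFs' log2-CPM across all cells in `expr`.
#'
#' @param markers a `marker_records` data.frame (with adjusted p-values).
#' @param tf_list character vector of transcription factor gene ids.
#' @param expr log2-CPM matrix over the cells in scope.
#' @param min_diff_pct minimum `pct_in - pct_out` (default 0.10).
#' @param logfc_min minimum natural-log fold change (default 0.4).
#' @param min_pct minimum in-cluster detection fraction (default 0.3).
#' @param fdr_max adjusted p-value cutoff (default 0.05).
#' @param top_n maximum TFs kept per cluster (default 3).
#' @return list of class `tf_correlogram` with `tf_map` (data.frame `gene_id`,
#'   `cluster`, `log_fold_change`) and `correlation` (square symmetric
#'   matrix); both empty (with a warning) when no TF survives.
#' @export
select_tf_correlogram <- function(markers, tf_list, expr,
                                  min_diff_pct = 0.10, logfc_min = 0.4,
                                  min_pct = 0.3, fdr_max = 0.05, top_n = 3) {
  if (length(tf_list) == 0) stop("tf_list must be nonempty")
  m <- markers[markers$gene_id %in% tf_list &
                 (markers$pct_in - markers$pct_out) >= min_diff_pct &
                 markers$log_fold_change >= logfc_min &
                 markers$pct_in >= min_pct &
                 markers$p_adjusted < fdr_max, , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no transcription factor survives the filters")
    return(structure(list(tf_map = data.frame(gene_id = character(0),
                                              cluster = character(0),
                                              log_fold_change = numeric(0)),
                          correlation = matrix(numeric(0), 0, 0)),
                     class = "tf_correlogram"))
  }
  # unique ownership: a TF goes to the cluster with the highest logFC
  m <- m[order(m$gene_id, -m$log_fold_change), , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]
  # per-cluster top_n by logFC (ties by gene id)
  m <- m[order(m$cluster, -m$log_fold_change, m$gene_id), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(m)), m$cluster),
                        function(i) utils::head(i, top_n)))
  m <- m[sort(keep), , drop = FALSE]
  cm <- stats::cor(t(expr[m$gene_id, , drop = FALSE]), method = "pearson")
  structure(list(tf_map = data.frame(gene_id = m$gene_id,
                                     cluster = m$cluster,
                                     log_fold_change = m$log_fold_change,
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
                 correlation = cm),
            class = "tf_correlogram")
}
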