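#' Condition centroids in a 2-D embedding
#'
#' Arithmetic mean embedding coordinates per condition, returned in
#' experimental time order. Intended to be run on trajectory (microglial)
#' cells only.
#'
#' @param coords cells x 2 matrix (e.g. tSNE coordinates) with rownames.
#' @param metadata data.frame with `cell_id`, `condition`,
#'   `condition_time_order`.
#' @param condition_subset optional character vector restricting conditions.
#' @return data.frame of class `condition_centroids` with `condition`,
#'   `time_order`, `x`, `y`, ordered by `time_order`.
#' @export
compute_condition_centroids <- function(coords, metadata,
                                        condition_subset = NULL) {
  md <- metadata[match(rownames(coords), metadata$cell_id), , drop = FALSE]
  if (is.null(condition_subset)) condition_subset <- unique(md$condition)
  out <- lapply(condition_subset, function(cc) {
    i <- which(md$condition == cc)
    if (length(i) == 0) stop("condition with no cells: ", cc)
    data.frame(condition = cc,
               time_order = md$condition_time_order[i[1]],
               x = mean(coords[i, 1]), y = mean(coords[i, 2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (anyDuplicated(out$time_order)) stop("time_order must be unique per condition")
  out <- out[order(out$time_order), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("condition_centroids", "data.frame")
  out
}

#' Assign each cell to its nearest condition centroid
#'
#' Euclidean distance in the embedding; ties are broken toward the smaller
#' `time_order`.
#'
#' @param coords cells x 2 coordinate matrix.
#' @param centroids a `condition_centroids` data.frame.
#' @return data.frame with `cell_id`, `nearest_centroid` (condition label)
#'   and `distance`.
#' @export
assign_nearest_centroid <- function(coords, centroids) {
  if (nrow(centroids) < 1) stop("need at least one centroid")
  cen <- centroids[order(centroids$time_order), , drop = FALSE]
  D <- outer(coords[, 1], cen$x, "-")^2 + outer(coords[, 2], cen$y, "-")^2
  pick <- apply(D, 1, which.min)   # first minimum = smallest time_order
  data.frame(cell_id = rownames(coords),
             nearest_centroid = cen$condition[pick],
             distance = sqrt(D[cbind(seq_len(nrow(D)), pick)]),
             stringsAsFactors = FALSE)
}

#' Fit an anchored principal curve through time-ordered centroids
#'
#' A natural cubic spline interpolates the centroids in time order,
#' parameterized by cumulative chord length and densely resampled
#' (`samples_per_segment` points per inter-anchor segment). The curve passes
#' through every anchor exactly; cumulative arc length is computed along the
#' resampled polyline. Coincident consecutive centroids are collapsed to a
#' single anchor with a warning.
#'
#' @param centroids a `condition_centroids` data.frame (>= 2 distinct
#'   anchors).
#' @param samples_per_segment dense sampling rate (default 128).
#' @param refit if `TRUE`, one smoothing pass is applied after an initial
#'   projection: the curve is refit by locally averaging the anchored
#'   spline's coordinates along arc length (kept off by default; the anchored
#'   interpolating curve is the canonical mode).
#' @return list of class `principal_curve_fit` with `points` (samples x 2),
#'   `arclength` (cumulative, per sample), `total_length`,
#'   `anchor_arclength` (named per condition), `anchors`.
#' @export
fit_principal_curve <- function(centroids, samples_per_segment = 128,
                                refit = FALSE) {
  cen <- centroids[order(centroids$time_order), , drop = FALSE]
  if (nrow(cen) >= 2) {
    dup <- c(FALSE, diff(cen$x)^2 + diff(cen$y)^2 == 0)
    if (any(dup)) {
      warning("coincident consecutive centroids collapsed: ",
              paste(cen$condition[dup], collapse = ", "))
      cen <- cen[!dup, , drop = FALSE]
    }
  }
  if (nrow(cen) < 2) stop("need at least 2 distinct centroids")
  chord <- c(0, cumsum(sqrt(diff(cen$x)^2 + diff(cen$y)^2)))
  tt <- unlist(lapply(seq_len(nrow(cen) - 1L), function(i) {
    s <- seq(chord[i], chord[i + 1], length.out = samples_per_segment + 1L)
    if (i < nrow(cen) - 1L) s[-length(s)] else s
  }))
  xs <- stats::spline(chord, cen$x, xout = tt, method = "natural")$y
  ys <- stats::spline(chord, cen$y, xout = tt, method = "natural")$y
  pts <- cbind(x = xs, y = ys)
  if (refit) {
    sm <- max(0.2, 3 / nrow(cen))
    xs <- stats::predict(stats::loess(xs ~ tt, span = sm, degree = 2))
    ys <- stats::predict(stats::loess(ys ~ tt, span = sm, degree = 2))
    pts <- cbind(x = xs, y = ys)
  }
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arclength <- c(0, cumsum(seg))
  anchor_idx <- match(chord, tt)
  structure(list(points = pts, arclength = arclength,
                 total_length = arclength[length(arclength)],
                 anchor_arclength = stats::setNames(arclength[anchor_idx],
                                                    cen$condition),
                 anchors = cen, samples_per_segment = samples_per_segment),
            class = "principal_curve_fit")
}

#' Project cells onto the anchored curve and read off pseudotime
#'
#' Each cell is mapped to the nearest sampled curve point (Euclidean; ties go
#' to the smaller arc length) and its pseudotime is that point's cumulative
#' arc length divided by the total curve length, so pseudotime lies in
#' `[0, 1]` with anchors at their normalized arc lengths.
#'
#' @param coords cells x 2 coordinate matrix.
#' @param curve a `principal_curve_fit`.
#' @param centroids optional `condition_centroids` for nearest-centroid
#'   annotation.
#' @param mode `"projection"` (default) or `"centroid_rank"`, which instead
#'   places every cell at its assigned centroid's normalized arc length.
#' @return data.frame of class `pseudotime_assignment` with `cell_id`,
#'   `pseudotime`, `projection_distance`, and `nearest_centroid` when
#'   centroids are given.
#' @export
project_pseudotime <- function(coords, curve, centroids = NULL,
                               mode = c("projection", "centroid_rank")) {
  mode <- match.arg(mode)
  assign <- if (!is.null(centroids))
    assign_nearest_centroid(coords, centroids) else NULL
  if (mode == "centroid_rank") {
    if (is.null(assign)) stop("centroid_rank mode requires centroids")
    pt <- curve$anchor_arclength[assign$nearest_centroid] / curve$total_length
    out <- data.frame(cell_id = rownames(coords), pseudotime = unname(pt),
                      projection_distance = assign$distance,
                      stringsAsFactors = FALSE)
  } else {
    P <- curve$points
    # squared distances to every sampled point, blockwise to bound memory
    n <- nrow(coords)
    idx <- integer(n); d2 <- numeric(n)
    block <- max(1L, floor(5e6 / nrow(P)))
    for (s in seq(1L, n, by = block)) {
      e <- min(n, s + block - 1L)
      DD <- outer(coords[s:e, 1], P[, 1], "-")^2 +
        outer(coords[s:e, 2], P[, 2], "-")^2
      ii <- apply(DD, 1, which.min)      # first minimum = smaller arc length
      idx[s:e] <- ii
      d2[s:e] <- DD[cbind(seq_along(ii), ii)]
    }
    out <- data.frame(cell_id = rownames(coords),
                      pseudotime = curve$arclength[idx] / curve$total_length,
                      projection_distance = sqrt(d2),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(assign)) out$nearest_centroid <- assign$nearest_centroid
  class(out) <- c("pseudotime_assignment", "data.frame")
  out
}

#' Per-gene linear trends of expression against pseudotime
#'
#' Ordinary least squares of log2-CPM on pseudotime for every gene, via the
#' closed-form normal equations, vectorized across genes. A constant gene has
#' slope 0 and r-squared 0.
#'
#' @param expr log2-CPM matrix (genes x cells).
#' @param pseudotime numeric vector named by (or aligned with) the columns of
#'   `expr`; needs at least 3 distinct values.
#' @return data.frame of class `gene_trends` with `gene_id`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
fit_gene_trends <- function(expr, pseudotime) {
  if (!is.null(names(pseudotime)))
    pseudotime <- pseudotime[colnames(expr)]
  t <- as.numeric(pseudotime)
  if (length(unique(t)) < 3) stop("need >= 3 cells with distinct pseudotime")
  vt <- stats::var(t)
  if (vt == 0) stop("pseudotime has zero variance")
  tc <- t - mean(t)
  n <- length(t)
  gm <- rowMeans(expr)
  cov_gt <- as.vector(expr %*% tc) / (n - 1)
  slope <- cov_gt / vt
  intercept <- gm - slope * mean(t)
  var_g <- rowSums((expr - gm)^2) / (n - 1)
  r2 <- ifelse(var_g > 0, (cov_gt^2) / (vt * var_g), 0)
  zero_var <- var_g == 0
  slope[zero_var] <- 0
  data.frame(gene_id = rownames(expr), slope = slope, intercept = intercept,
             r_squared = r2, row.names = NULL, stringsAsFactors = FALSE) |>
    structure(class = c("gene_trends", "data.frame"))
}

#' Select the genes with the most extreme pseudotime slopes
#'
#' Top `k` by slope descending (up) and ascending (down); ties broken by
#' lexicographic gene id so the selection is deterministic.
#'
#' @param trends a `gene_trends` data.frame.
#' @param k genes per direction (default 10).
#' @return list with character vectors `up` and `down`, each length `k`,
#'   disjoint.
#' @export
select_extreme_slope_genes <- function(trends, k = 10) {
  n <- nrow(trends)
  if (k > n / 2) stop("k must be at most half the number of genes")
  up_ord <- order(-trends$slope, trends$gene_id)
  up <- trends$gene_id[up_ord[seq_len(k)]]
  rest <- trends[!trends$gene_id %in% up, , drop = FALSE]
  down_ord <- order(rest$slope, rest$gene_id)
  list(up = up, down = rest$gene_id[down_ord[seq_len(k)]])
}

#' Order genes by hierarchical clustering for heatmap display
#'
#' Rows are z-scored (constant rows map to zero), clustered agglomeratively
#' with average linkage on Euclidean distance, and returned in dendrogram
#' leaf order.
#'
#' @param expr_subset genes x cells expression matrix (>= 1 gene).
#' @return character vector of gene ids in display order.
#' @export
order_genes_hierarchically <- function(expr_subset) {
  if (nrow(expr_subset) < 2) return(rownames(expr_subset))
  z <- t(scale(t(expr_subset)))
  z[is.na(z)] <- 0
  h <- stats::hclust(stats::dist(z), method = "average")
  rownames(expr_subset)[h$order]
}

#' Loess smoothing of one gene's expression along pseudotime
#'
#' Local linear regression (tricube weights, degree 1) with a pointwise 95%
#' band `fit +/- 1.96 * SE`. If the requested span leaves too few points for
#' the local fits it is widened with a warning.
#'
#' @param expr_gene numeric expression vector (one gene).
#' @param pseudotime numeric vector of equal length (>= 10 cells).
#' @param span loess span (default 0.75).
#' @return data.frame with `pseudotime`, `fit`, `lower`, `upper`, sorted by
#'   pseudotime.
#' @export
smooth_gene_trend <- function(expr_gene, pseudotime, span = 0.75) {
  if (length(expr_gene) < 10) stop("need >= 10 cells")
  ord <- order(pseudotime)
  x <- pseudotime[ord]; y <- expr_gene[ord]
  fit <- NULL
  s <- span
  repeat {
    fit <- tryCatch(suppressWarnings(stats::loess(y ~ x, span = s, degree = 1,
                                                  family = "gaussian")),
                    error = function(e) NULL)
    if (!is.null(fit)) break
    s <- s * 1.5
    if (s > 10) stop("loess failed even with a widened span")
  }
  if (s > span) warning("span widened from ", span, " to ", s)
  pr <- stats::predict(fit, se = TRUE)
  data.frame(pseudotime = x, fit = pr$fit,
             lower = pr$fit - 1.96 * pr$se.fit,
             upper = pr$fit + 1.96 * pr$se.fit)
}
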