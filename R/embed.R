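#' Select highly variable genes by binned normalized dispersion
#'
#' For each gene the mean of log2-CPM and the dispersion
#' `log(variance/mean)` of the de-logged values (`2^v - 1`) are computed.
#' Genes are placed into `n_bins` equal-width bins of mean expression and the
#' dispersion is z-scored within each bin. A gene is selected when
#' `mean > mean_cutoff` and `normalized dispersion > dispersion_cutoff`
#' (both strict). Constant or undetected genes have dispersion `-Inf` and are
#' never selected; a bin holding a single gene gets normalized dispersion 0
#' with a warning.
#'
#' @param expr log2-CPM matrix from [compute_log_cpm()].
#' @param mean_cutoff,dispersion_cutoff strict lower cutoffs (defaults 0.3
#'   and 0.5).
#' @param n_bins number of equal-width mean-expression bins (default 20).
#' @return list of class `hvg_selection` with `gene_ids` (selected), `mean`,
#'   `dispersion`, `norm_dispersion` (all named per gene) and the cutoffs.
#' @export
select_hvg <- function(expr, mean_cutoff = 0.3, dispersion_cutoff = 0.5,
                       n_bins = 20) {
  m <- rowMeans(expr)
  d <- 2^expr - 1
  mu <- rowMeans(d)
  va <- apply(d, 1, stats::var)
  disp <- ifelse(mu > 0 & va > 0, log(va / mu), -Inf)
  bins <- cut(m, breaks = n_bins, include.lowest = TRUE)
  nd <- rep(NA_real_, length(m))
  singletons <- FALSE
  for (b in levels(bins)) {
    i <- which(bins == b)
    if (length(i) == 0) next
    fin <- disp[i][is.finite(disp[i])]
    if (length(i) == 1 || length(fin) < 2 || stats::sd(fin) == 0) {
      nd[i] <- ifelse(is.finite(disp[i]), 0, -Inf)
      if (length(i) == 1) singletons <- TRUE
      next
    }
    nd[i] <- ifelse(is.finite(disp[i]),
                    (disp[i] - mean(fin)) / stats::sd(fin), -Inf)
  }
  if (singletons)
    warning("bin(s) with a single gene: normalized dispersion set to 0")
  sel <- m > mean_cutoff & nd > dispersion_cutoff
  structure(list(gene_ids = rownames(expr)[sel],
                 mean = stats::setNames(m, rownames(expr)),
                 dispersion = stats::setNames(disp, rownames(expr)),
                 norm_dispersion = stats::setNames(nd, rownames(expr)),
                 mean_cutoff = mean_cutoff,
                 dispersion_cutoff = dispersion_cutoff, n_bins = n_bins),
            class = "hvg_selection")
}

#' Scale selected genes and run exact PCA over cells
#'
#' Genes are centred and scaled to unit variance, values clipped at +10
#' (large positive outliers are truncated, as is conventional for scaled
#' single-cell data), the clipped matrix is re-centred, and an exact singular
#' value decomposition supplies the principal components. Sign convention:
#' the loading with the largest absolute value in each component is positive.
#'
#' @param expr log2-CPM matrix.
#' @param genes an `hvg_selection` or character vector of gene ids.
#' @param n_components number of components (default 50; reduced with a
#'   warning when fewer cells are available).
#' @return list of class `pca_result` with `scores` (cells x components),
#'   `sdev`, `rotation`.
#' @export
scale_and_pca <- function(expr, genes, n_components = 50) {
  ids <- if (inherits(genes, "hvg_selection")) genes$gene_ids else genes
  if (length(ids) < 2) stop("need at least 2 selected genes")
  X <- t(expr[ids, , drop = FALSE])       # cells x genes
  X <- scale(X)
  X[is.na(X)] <- 0                        # constant gene safeguard
  X[X > 10] <- 10
  X <- scale(X, center = TRUE, scale = FALSE)
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_comp) {
    warning("reducing n_components from ", n_components, " to ", max_comp)
    n_components <- max_comp
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rotation <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  dimnames(rotation) <- list(ids, colnames(scores))
  structure(list(scores = scores,
                 sdev = sv$d[seq_len(n_components)] / sqrt(max(1, nrow(X) - 1)),
                 rotation = rotation),
            class = "pca_result")
}

#' Build a shared-nearest-neighbour (SNN) graph
#'
#' k-nearest neighbours by Euclidean distance in the first `dims` principal
#' components; each cell's neighbourhood is itself plus its `k_neighbors`
#' nearest neighbours (distance ties broken by index). The edge weight between
#' two cells is the Jaccard overlap of their neighbourhoods; weights below
#' `prune` are dropped. The graph is undirected, weighted, without self-loops.
#'
#' @param pca_scores cells x components score matrix.
#' @param dims number of leading components to use (default 17).
#' @param k_neighbors neighbourhood size excluding self (default 20).
#' @param prune minimum retained Jaccard weight (default 1/15).
#' @return an [igraph::graph] with vertex names equal to the cell ids.
#' @export
build_snn_graph <- function(pca_scores, dims = 17, k_neighbors = 20,
                            prune = 1 / 15) {
  n <- nrow(pca_scores)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  dims <- min(dims, ncol(pca_scores))
  X <- pca_scores[, seq_len(dims), drop = FALSE]
  D <- as.matrix(stats::dist(X))
  nb_size <- k_neighbors + 1L
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(nb_size)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = nb_size),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)              # pairwise intersection sizes
  S <- as(S, "TsparseMatrix")
  keep <- S@i < S@j                       # upper triangle, no self-loops
  i <- S@i[keep] + 1L
  j <- S@j[keep] + 1L
  inter <- S@x[keep]
  w <- inter / (2 * nb_size - inter)
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(pca_scores)[i[ok]],
               to = rownames(pca_scores)[j[ok]], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = rownames(pca_scores)))
  g
}

#' Louvain community detection on an SNN graph
#'
#' Resolution-scaled modularity maximization; labels are renumbered
#' deterministically from 0 by decreasing cluster size (ties by first member).
#'
#' @param graph weighted undirected graph from [build_snn_graph()].
#' @param resolution modularity resolution (default 1.3).
#' @param seed integer RNG seed making the heuristic deterministic.
#' @return list of class `cluster_assignment` with `labels` (named integer
#'   vector, 0-based) and `resolution`.
#' @export
cluster_louvain <- function(graph, resolution = 1.3, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  cl <- with_seed(seed,
    igraph::cluster_louvain(graph, resolution = resolution))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  relab <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  labels <- stats::setNames(as.integer(relab[as.character(memb)]),
                            igraph::V(graph)$name)
  structure(list(labels = labels, resolution = resolution, seed = seed),
            class = "cluster_assignment")
}

#' tSNE embedding of PCA scores
#'
#' Barnes-Hut tSNE on the leading components. Coordinates are reproducible
#' for a fixed seed within this implementation; no agreement with other tSNE
#' implementations is implied.
#'
#' @param pca_scores cells x components matrix.
#' @param dims leading components to embed (default 15).
#' @param perplexity tSNE perplexity (default 70); must be below
#'   `(n_cells - 1) / 3`.
#' @param seed integer RNG seed (default 132).
#' @param max_iter gradient-descent iterations (default 1000).
#' @return cells x 2 coordinate matrix with columns `tSNE1`, `tSNE2`.
#' @export
embed_tsne <- function(pca_scores, dims = 15, perplexity = 70, seed = 132L,
                       max_iter = 1000) {
  n <- nrow(pca_scores)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large: must be < (n_cells - 1)/3 = ", (n - 1) / 3)
  dims <- min(dims, ncol(pca_scores))
  X <- pca_scores[, seq_len(dims), drop = FALSE]
  if (all(apply(X, 2, function(c) diff(range(c))) == 0)) {
    # fully degenerate input (all points identical): the embedding is a
    # single point; return finite coordinates instead of crashing
    coords <- matrix(0, n, 2,
                     dimnames = list(rownames(pca_scores),
                                     c("tSNE1", "tSNE2")))
    return(coords)
  }
  fit <- with_seed(seed,
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE, max_iter = max_iter,
                 verbose = FALSE))
  coords <- fit$Y
  dimnames(coords) <- list(rownames(pca_scores), c("tSNE1", "tSNE2"))
  coords
}
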