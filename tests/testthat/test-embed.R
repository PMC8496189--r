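test_that("select_hvg matches a brute-force binned z-score oracle", {
  set.seed(11)
  n <- 50
  expr <- matrix(abs(rnorm(n * 30, 1.5, 1.2)), n, 30,
                 dimnames = list(sprintf("g%02d", 1:n), sprintf("c%02d", 1:30)))
  expr[3, ] <- 2            # constant gene: zero variance, never selected
  sel <- suppressWarnings(select_hvg(expr, 0.3, 0.5, n_bins = 5))
  expect_false("g03" %in% sel$gene_ids)

  # independent recomputation (plain loops)
  m <- rowMeans(expr)
  d <- 2^expr - 1
  disp <- sapply(1:n, function(i) {
    mu <- mean(d[i, ]); va <- var(d[i, ])
    if (mu > 0 && va > 0) log(va / mu) else -Inf
  })
  bins <- cut(m, 5, include.lowest = TRUE)
  nd <- rep(-Inf, n)
  for (b in levels(bins)) {
    i <- which(bins == b)
    fv <- disp[i][is.finite(disp[i])]
    if (length(fv) >= 2 && sd(fv) > 0)
      nd[i[is.finite(disp[i])]] <- (disp[i][is.finite(disp[i])] - mean(fv)) / sd(fv)
    else nd[i[is.finite(disp[i])]] <- 0
  }
  oracle <- rownames(expr)[m > 0.3 & nd > 0.5]
  expect_setequal(sel$gene_ids, oracle)

  high <- suppressWarnings(select_hvg(expr, mean_cutoff = max(m) + 1))
  expect_length(high$gene_ids, 0)
})

test_that("scale_and_pca gives centred, sign-fixed, exact components", {
  set.seed(12)
  # points on a 2-D plane embedded in 8 genes
  basis <- matrix(rnorm(16), 8, 2)
  scores2 <- matrix(rnorm(80), 40, 2)
  expr <- t(scores2 %*% t(basis)) + 5
  dimnames(expr) <- list(sprintf("g%d", 1:8), sprintf("c%d", 1:40))
  p <- scale_and_pca(expr, rownames(expr), n_components = 5)
  expect_lt(p$sdev[3] / p$sdev[1], 1e-8)                 # rank 2
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))      # centring

  expr2 <- matrix(rnorm(30 * 20, 4, 2), 20, 30,
                  dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:30)))
  p2 <- scale_and_pca(expr2, rownames(expr2), n_components = 10)
  # oracle: eigendecomposition of the covariance of the scaled, clipped data
  X <- scale(t(expr2)); X[X > 10] <- 10; X <- scale(X, scale = FALSE)
  ev <- eigen(cov(X))
  sc_oracle <- X %*% ev$vectors[, 1:10]
  for (j in 1:10) {
    agree <- max(abs(p2$scores[, j] - sc_oracle[, j]))
    flip <- max(abs(p2$scores[, j] + sc_oracle[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
  expect_warning(scale_and_pca(expr2, rownames(expr2), n_components = 40),
                 "reducing")
})

test_that("SNN graph equals the brute-force kNN + Jaccard construction", {
  set.seed(13)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(sprintf("c%02d", 1:40), NULL))
  k <- 6
  g <- build_snn_graph(X, dims = 5, k_neighbors = k, prune = 1 / 15)
  # oracle: explicit O(n^2) loops
  D <- as.matrix(dist(X))
  nbhd <- lapply(1:40, function(i) order(D[i, ])[1:(k + 1)])
  edges <- list()
  for (i in 1:39) for (j in (i + 1):40) {
    inter <- length(intersect(nbhd[[i]], nbhd[[j]]))
    w <- inter / (2 * (k + 1) - inter)
    if (w >= 1 / 15)
      edges[[length(edges) + 1]] <- data.frame(i = i, j = j, w = w)
  }
  oracle <- do.call(rbind, edges)
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), nrow(oracle))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  oi <- match(key(sprintf("c%02d", oracle$i), sprintf("c%02d", oracle$j)),
              key(el$from, el$to))
  expect_false(anyNA(oi))
  expect_equal(el$weight[oi], oracle$w, tolerance = 1e-12)
  # weights in (0, 1], no self loops
  expect_true(all(el$weight > 0 & el$weight <= 1))
  expect_false(any(el$from == el$to))
  # identical neighbourhoods give weight 1: duplicate one point
  X2 <- rbind(X, `c41` = X["c01", ] + 1e-9)
  g2 <- build_snn_graph(X2, dims = 5, k_neighbors = k)
  el2 <- igraph::as_data_frame(g2)
  hit <- el2[(el2$from == "c01" & el2$to == "c41") |
               (el2$from == "c41" & el2$to == "c01"), ]
  expect_equal(hit$weight, 1)
  expect_error(build_snn_graph(X, k_neighbors = 40), "smaller")
})

test_that("louvain recovers forced partitions deterministically", {
  clique <- function(ids) {
    cmb <- t(combn(ids, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = 1)
  }
  two <- igraph::graph_from_data_frame(
    rbind(clique(sprintf("a%d", 1:6)), clique(sprintf("b%d", 1:6))),
    directed = FALSE)
  cl <- cluster_louvain(two, resolution = 1.3, seed = 1)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(min(cl$labels), 0L)
  expect_length(unique(cl$labels[sprintf("a%d", 1:6)]), 1)

  # a complete graph is one community under plain modularity (resolution 1);
  # above resolution 1 singletons score better (-gamma/n > 1-gamma), so the
  # forced-partition check is made at resolution 1
  one <- igraph::graph_from_data_frame(clique(sprintf("x%d", 1:8)),
                                       directed = FALSE)
  expect_equal(length(unique(cluster_louvain(one, 1.0, seed = 1)$labels)), 1)
  expect_error(cluster_louvain(igraph::make_empty_graph(0)), "empty")
  expect_identical(cluster_louvain(two, 1.3, seed = 9)$labels,
                   cluster_louvain(two, 1.3, seed = 9)$labels)
})

test_that("tsne is deterministic, guarded, and separates planted archetypes", {
  set.seed(14)
  X <- matrix(rnorm(90 * 4), 90, 4, dimnames = list(sprintf("c%d", 1:90), NULL))
  a <- embed_tsne(X, dims = 4, perplexity = 10, seed = 5, max_iter = 300)
  b <- embed_tsne(X, dims = 4, perplexity = 10, seed = 5, max_iter = 300)
  expect_identical(a, b)
  expect_error(embed_tsne(X, perplexity = 40), "perplexity")

  same <- matrix(0, 10, 3, dimnames = list(sprintf("d%d", 1:10), NULL))
  z <- embed_tsne(same, dims = 3, perplexity = 2, seed = 1, max_iter = 100)
  expect_true(all(is.finite(z)))

  # three well-separated archetypes: mean silhouette in tSNE space > 0.5
  centers <- matrix(c(0, 0, 12, 0, 0, 12), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = 40)
  Y <- centers[lab, ] + matrix(rnorm(240, sd = 0.5), 120, 2)
  Y <- cbind(Y, matrix(rnorm(120 * 3, sd = 0.5), 120, 3))
  rownames(Y) <- sprintf("c%d", 1:120)
  emb <- embed_tsne(Y, dims = 5, perplexity = 20, seed = 7, max_iter = 500)
  D <- as.matrix(dist(emb))
  sil <- sapply(1:120, function(i) {
    a_i <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b_i <- min(sapply(setdiff(1:3, lab[i]), function(k) mean(D[i, lab == k])))
    (b_i - a_i) / max(a_i, b_i)
  })
  expect_gt(mean(sil), 0.5)
})
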