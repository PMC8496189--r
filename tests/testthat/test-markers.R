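test_that("marker detection flags exclusive genes and filters flat ones", {
  set.seed(31)
  n_a <- 12; n_b <- 12
  expr <- matrix(0, 4, n_a + n_b,
                 dimnames = list(c("excl", "flat", "shift", "zero"),
                                 sprintf("c%02d", 1:(n_a + n_b))))
  lab <- setNames(rep(c("A", "B"), c(n_a, n_b)), colnames(expr))
  expr["excl", 1:n_a] <- rnorm(n_a, 8, 0.2)
  expr["flat", ] <- rnorm(n_a + n_b, 5, 0.2)
  expr["shift", ] <- c(rnorm(n_a, 7, 0.2), rnorm(n_b, 4, 0.2))
  mk <- find_cluster_markers(expr, lab)
  a <- mk[mk$cluster == "A", ]
  excl <- a[a$gene_id == "excl", ]
  expect_equal(excl$pct_in, 1)
  expect_equal(excl$pct_out, 0)
  expect_gt(excl$log_fold_change, log(2))
  expect_lt(excl$p_adjusted, 0.001)
  expect_false("flat" %in% a$gene_id)

  tiny <- expr[, 1:14]
  expect_warning(find_cluster_markers(tiny, lab[1:14]), "fewer than 3")
  expect_error(find_cluster_markers(expr, setNames(rep("A", 24), colnames(expr))),
               "2 clusters")
})

test_that("wilcoxon p equals the exhaustive permutation enumeration", {
  # tie-free 6 vs 6: enumerate all C(12,6) group assignments
  set.seed(32)
  x <- c(1.3, 2.7, 0.4, 5.1, 3.3, 4.8)
  y <- c(2.1, 6.4, 7.7, 1.9, 8.2, 5.5)
  p_impl <- stats::wilcox.test(x, y)$p.value     # implementation route
  pool <- c(x, y)
  r <- rank(pool)
  W_obs <- sum(r[1:6]) - 6 * 7 / 2
  combos <- combn(12, 6)
  Ws <- apply(combos, 2, function(ix) sum(r[ix]) - 21)
  # two-sided exact p: P(|W - EW| >= |W_obs - EW|)
  EW <- 18
  p_oracle <- mean(abs(Ws - EW) >= abs(W_obs - EW))
  expect_equal(p_impl, p_oracle, tolerance = 1e-12)

  # and a 5 vs 3 case
  x2 <- x[1:5]; y2 <- y[1:3]
  p2 <- stats::wilcox.test(x2, y2)$p.value
  r2 <- rank(c(x2, y2))
  combos2 <- combn(8, 5)
  W2 <- apply(combos2, 2, function(ix) sum(r2[ix]) - 15)
  EW2 <- 5 * (8 + 1) / 2 - 15
  p_oracle2 <- mean(abs(W2 - EW2) >= abs(sum(r2[1:5]) - 15 - EW2))
  expect_equal(p2, p_oracle2, tolerance = 1e-12)
})

test_that("TMM factors match a step-by-step recomputation and edgeR", {
  set.seed(33)
  # identical libraries
  same <- matrix(rep(rpois(100, 50), 3), 100, 3,
                 dimnames = list(sprintf("g%d", 1:100), c("l1", "l2", "l3")))
  expect_equal(unname(tmm_normalization_factors(same)), rep(1, 3),
               tolerance = 1e-12)
  # pure depth difference: factors stay 1
  depth <- cbind(l1 = same[, 1], l2 = same[, 1] * 2L)
  expect_equal(unname(tmm_normalization_factors(depth)), c(1, 1),
               tolerance = 1e-12)

  # 4-library toy with an inflated gene block in library 4
  counts <- matrix(rpois(200 * 4, 60), 200, 4,
                   dimnames = list(sprintf("g%03d", 1:200), paste0("l", 1:4)))
  counts[1:30, 4] <- counts[1:30, 4] * 8L
  f <- tmm_normalization_factors(counts)

  # independent explicit recomputation
  lib <- colSums(counts)
  q75 <- apply(counts, 2, function(cl) quantile(cl / sum(cl), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  logfac <- numeric(4)
  for (j in 1:4) {
    o <- counts[, j]; r <- counts[, ref]
    k <- o > 0 & r > 0
    M <- log2((o[k] / lib[j]) / (r[k] / lib[ref]))
    A <- 0.5 * (log2(o[k] / lib[j]) + log2(r[k] / lib[ref]))
    v <- (lib[j] - o[k]) / (lib[j] * o[k]) + (lib[ref] - r[k]) / (lib[ref] * r[k])
    if (max(abs(M)) < 1e-6) { logfac[j] <- 0; next }
    nn <- length(M)
    keep <- rank(M) >= floor(nn * 0.3) + 1 & rank(M) <= nn - floor(nn * 0.3) &
      rank(A) >= floor(nn * 0.05) + 1 & rank(A) <= nn - floor(nn * 0.05)
    logfac[j] <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  }
  oracle <- 2^logfac
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(f), oracle, tolerance = 1e-9)

  # geometric-mean-1 invariant
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)

  # cross-check against the reference implementation
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(f), unname(fe), tolerance = 1e-6)
})

test_that("pairwise DE controls the null and finds a planted shift", {
  set.seed(34)
  # null: both groups drawn from the same distribution, 20 replications
  hits <- replicate(20, {
    counts <- matrix(rnbinom(200 * 20, mu = 100, size = 2), 200, 20,
                     dimnames = list(sprintf("g%d", 1:200), sprintf("l%d", 1:20)))
    de <- pairwise_differential_expression(counts, 1:10, 11:20)
    sum(de$fdr < 0.05)
  })
  expect_lte(mean(hits) / 200, 0.05)

  # single planted 4-log2-unit shift ranks first
  counts <- matrix(rnbinom(200 * 20, mu = 100, size = 5), 200, 20,
                   dimnames = list(sprintf("g%d", 1:200), sprintf("l%d", 1:20)))
  counts[7, 1:10] <- counts[7, 1:10] * 16L
  de <- pairwise_differential_expression(counts, 1:10, 11:20)
  expect_equal(de$gene_id[1], "g7")
  expect_gt(de$logFC[1], 2)

  counts[9, ] <- 0L
  de2 <- pairwise_differential_expression(counts, 1:10, 11:20)
  z <- de2[de2$gene_id == "g9", ]
  expect_equal(z$logFC, 0)
  expect_equal(z$p, 1)
  expect_error(pairwise_differential_expression(counts, 1:2, 3:20), "at least 3")
})

test_that("TF correlogram selection, ownership and correlations are exact", {
  set.seed(35)
  n <- 60
  lab <- setNames(rep(c("A", "B", "C"), each = 20), sprintf("c%02d", 1:n))
  tfs <- sprintf("tf%d", 1:5)
  expr <- matrix(0, 8, n,
                 dimnames = list(c(tfs, "x1", "x2", "x3"), names(lab)))
  expr[c("x1", "x2", "x3"), ] <- abs(rnorm(3 * n, 2, 0.5))
  expr["tf1", lab == "A"] <- rnorm(20, 9, 0.3)   # exclusive to A
  expr["tf2", lab == "B"] <- rnorm(20, 9, 0.3)
  expr["tf3", lab == "B"] <- rnorm(20, 7, 0.3)
  mk <- find_cluster_markers(expr, lab, logfc_threshold = 0.4, min_pct = 0)
  tfc <- select_tf_correlogram(mk, tfs, expr)
  expect_true(all(c("tf1", "tf2", "tf3") %in% tfc$tf_map$gene_id))
  expect_equal(tfc$tf_map$cluster[tfc$tf_map$gene_id == "tf1"], "A")
  expect_true(all(table(tfc$tf_map$gene_id) == 1))   # unique ownership

  cm <- tfc$correlation
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  expect_equal(cm, t(cm))
  oracle <- cor(t(expr[tfc$tf_map$gene_id, , drop = FALSE]))
  expect_equal(cm, oracle, tolerance = 1e-12)

  expect_warning(
    empty <- select_tf_correlogram(mk, "absent_tf", expr),
    "no transcription factor")
  expect_equal(nrow(empty$tf_map), 0)
  expect_error(select_tf_correlogram(mk, character(0), expr), "nonempty")
})
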