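make_coords <- function(xy, ids = sprintf("c%02d", seq_len(nrow(xy)))) {
  dimnames(xy) <- list(ids, c("tSNE1", "tSNE2"))
  xy
}

test_that("condition centroids are arithmetic means in time order", {
  xy <- make_coords(matrix(c(-1, 0, 1, 0, 4, 4), 3, 2, byrow = TRUE))
  md <- toy_metadata(rownames(xy))
  md$condition <- c("B", "B", "A")
  md$condition_time_order <- c(2L, 2L, 1L)
  cc <- compute_condition_centroids(xy, md)
  expect_equal(cc$condition, c("A", "B"))        # ordered by time
  expect_equal(cc$x, c(4, 0))                    # symmetry: mean of (-1,1)
  expect_equal(cc$y, c(4, 0))

  set.seed(21)
  xy3 <- make_coords(matrix(rnorm(6), 3, 2))
  md3 <- toy_metadata(rownames(xy3))
  cc3 <- compute_condition_centroids(xy3, md3)
  expect_equal(cc3$x, mean(xy3[, 1]))            # direct arithmetic oracle
  expect_equal(cc3$y, mean(xy3[, 2]))

  expect_error(compute_condition_centroids(xy, md, c("A", "Z")), "Z")
})

test_that("nearest-centroid assignment matches the exhaustive argmin", {
  cen <- data.frame(condition = c("c1", "c2", "c3", "c4", "c5"),
                    time_order = 1:5,
                    x = c(0, 2, 4, 6, 8), y = c(0, 1, 0, 1, 0))
  class(cen) <- c("condition_centroids", "data.frame")
  on_cen <- make_coords(matrix(c(4, 0), 1, 2))
  expect_equal(assign_nearest_centroid(on_cen, cen)$nearest_centroid, "c3")
  tie <- make_coords(matrix(c(1, 0.5), 1, 2))    # equidistant from c1 and c2
  expect_equal(assign_nearest_centroid(tie, cen)$nearest_centroid, "c1")

  set.seed(22)
  pts <- make_coords(matrix(rnorm(100, sd = 4), 50, 2))
  got <- assign_nearest_centroid(pts, cen)
  for (i in 1:50) {
    d <- sqrt((pts[i, 1] - cen$x)^2 + (pts[i, 2] - cen$y)^2)
    expect_equal(got$nearest_centroid[i], cen$condition[which.min(d)])
    expect_equal(got$distance[i], min(d))
  }
})

test_that("anchored principal curve interpolates and measures arc length", {
  cen2 <- data.frame(condition = c("a", "b"), time_order = 1:2,
                     x = c(0, 3), y = c(0, 4))
  cv2 <- fit_principal_curve(cen2)
  expect_equal(cv2$total_length, 5, tolerance = 1e-9)     # straight segment

  cen3 <- data.frame(condition = c("a", "b", "c"), time_order = 1:3,
                     x = c(0, 1, 2), y = c(0, 1, 2))      # collinear
  cv3 <- fit_principal_curve(cen3)
  expect_equal(unname(cv3$anchor_arclength[["b"]]), cv3$total_length / 2,
               tolerance = 1e-9)
  resid <- abs(cv3$points[, 2] - cv3$points[, 1])          # stays on y = x
  expect_lt(max(resid), 1e-9)

  set.seed(23)
  cen5 <- data.frame(condition = letters[1:5], time_order = 1:5,
                     x = cumsum(runif(5, 0.5, 2)), y = rnorm(5))
  cv5 <- fit_principal_curve(cen5, samples_per_segment = 128)
  at_anchor <- cv5$points[match(cv5$anchor_arclength, cv5$arclength), ]
  expect_lt(max(abs(at_anchor[, 1] - cen5$x)), 1e-9)
  expect_lt(max(abs(at_anchor[, 2] - cen5$y)), 1e-9)
  dense <- fit_principal_curve(cen5, samples_per_segment = 1280)
  expect_lt(abs(cv5$total_length - dense$total_length) / dense$total_length,
            1e-3)

  dup <- cen3; dup$x[2] <- 0; dup$y[2] <- 0
  expect_warning(fit_principal_curve(dup), "coincident")
  expect_error(fit_principal_curve(cen2[1, , drop = FALSE]), "2 distinct")
})

test_that("projection recovers arc-length fractions and anchor pseudotimes", {
  cen <- data.frame(condition = c("a", "b", "c"), time_order = 1:3,
                    x = c(0, 5, 10), y = c(0, 3, 0))
  class(cen) <- c("condition_centroids", "data.frame")
  cv <- fit_principal_curve(cen)
  ends <- make_coords(matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE))
  pt <- project_pseudotime(ends, cv, cen)
  expect_equal(pt$pseudotime, c(0, 1))
  expect_equal(pt$nearest_centroid, c("a", "c"))

  # cells placed exactly on the curve at known arc-length fractions
  fr <- c(0.1, 0.25, 0.5, 0.8)
  idx <- sapply(fr * cv$total_length, function(s) which.min(abs(cv$arclength - s)))
  on_curve <- make_coords(cv$points[idx, , drop = FALSE])
  pt2 <- project_pseudotime(on_curve, cv)
  expect_equal(pt2$pseudotime, cv$arclength[idx] / cv$total_length,
               tolerance = 1e-12)
  expect_lt(max(abs(pt2$pseudotime - fr)), 1 / 128)

  # centroid-rank mode pins cells to their assigned anchor's arc length
  pt3 <- project_pseudotime(ends, cv, cen, mode = "centroid_rank")
  expect_equal(pt3$pseudotime,
               unname(cv$anchor_arclength[c("a", "c")] / cv$total_length))
})

test_that("gene trends equal the normal-equation oracle", {
  set.seed(24)
  n <- 100
  t <- runif(n)
  expr <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("c%03d", 1:n)))
  expr[1, ] <- 0                                  # constant gene
  expr[2, ] <- t                                  # gene equal to pseudotime
  tr <- fit_gene_trends(expr, setNames(t, colnames(expr)))
  expect_equal(tr$slope[1], 0)
  expect_equal(tr$r_squared[1], 0)
  expect_equal(tr$slope[2], 1, tolerance = 1e-12)
  expect_equal(tr$r_squared[2], 1, tolerance = 1e-12)
  X <- cbind(1, t)
  for (g in 3:20) {
    beta <- solve(t(X) %*% X, t(X) %*% expr[g, ])  # independent OLS
    expect_equal(tr$slope[g], beta[2], tolerance = 1e-10)
    expect_equal(tr$intercept[g], beta[1], tolerance = 1e-10)
  }
  expect_error(fit_gene_trends(expr, rep(0.5, n)), "distinct")
})

test_that("extreme-slope selection is disjoint and tie-stable", {
  tr <- data.frame(gene_id = sprintf("g%02d", 1:30), slope = c(30:1) / 10)
  sel <- select_extreme_slope_genes(tr, k = 10)
  expect_length(sel$up, 10)
  expect_length(sel$down, 10)
  expect_length(intersect(sel$up, sel$down), 0)
  expect_equal(sel$up[1], "g01")

  flat <- data.frame(gene_id = sprintf("g%02d", 1:30), slope = 1)
  sf <- select_extreme_slope_genes(flat, k = 10)
  expect_equal(sf$up, sprintf("g%02d", 1:10))     # lexicographic tie-break
  expect_equal(sf$down, sprintf("g%02d", 11:20))  # still disjoint under ties
  expect_error(select_extreme_slope_genes(tr, k = 16), "half")
})

test_that("hierarchical gene ordering keeps duplicated blocks adjacent", {
  single <- matrix(1:4, 1, 4, dimnames = list("only", NULL))
  expect_equal(order_genes_hierarchically(single), "only")

  set.seed(25)
  a <- rnorm(30); b <- rnorm(30) + 10
  m <- rbind(A1 = a, B1 = b, A2 = a + rnorm(30, sd = 1e-3),
             B2 = b + rnorm(30, sd = 1e-3))
  ord <- order_genes_hierarchically(m)
  posA <- match(c("A1", "A2"), ord)
  posB <- match(c("B1", "B2"), ord)
  expect_equal(abs(diff(posA)), 1)
  expect_equal(abs(diff(posB)), 1)

  two <- m[1:2, ]
  expect_identical(order_genes_hierarchically(two),
                   order_genes_hierarchically(two))  # deterministic
})

test_that("loess smoothing is exact on lines and tracks a sine mean", {
  x <- seq(0, 1, length.out = 50)
  lin <- smooth_gene_trend(2 * x + 1, x)
  expect_lt(max(abs(lin$fit - (2 * lin$pseudotime + 1))), 1e-8)

  flat <- smooth_gene_trend(rep(3, 50), x)
  expect_true(all(flat$upper >= flat$lower))
  expect_equal(flat$fit, rep(3, 50), tolerance = 1e-8)

  set.seed(26)
  n <- 500
  xs <- runif(n)
  amp <- 2
  ys <- amp * sin(2 * pi * xs) + rnorm(n, sd = 0.3)
  sm <- smooth_gene_trend(ys, xs, span = 0.3)
  rmse <- sqrt(mean((sm$fit - amp * sin(2 * pi * sm$pseudotime))^2))
  expect_lt(rmse, 0.1 * amp)
  expect_error(smooth_gene_trend(1:5, 1:5 / 5), ">= 10")
})
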