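# Independent oracle implementations used by the acceptance suite. These are
# deliberately written as plain, slow, step-by-step code.

oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- sapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j] / lib[j], 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  lf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    o <- counts[, j]; r <- counts[, ref]
    k <- o > 0 & r > 0
    M <- log2((o[k] / lib[j]) / (r[k] / lib[ref]))
    A <- 0.5 * (log2(o[k] / lib[j]) + log2(r[k] / lib[ref]))
    v <- (lib[j] - o[k]) / (lib[j] * o[k]) +
      (lib[ref] - r[k]) / (lib[ref] * r[k])
    if (length(M) == 0 || max(abs(M)) < 1e-6) next
    nn <- length(M)
    keep <- rank(M) >= floor(nn * trim_m) + 1 &
      rank(M) <= nn - floor(nn * trim_m) &
      rank(A) >= floor(nn * trim_a) + 1 &
      rank(A) <= nn - floor(nn * trim_a)
    lf[j] <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  }
  f <- 2^lf
  unname(f / exp(mean(log(f))))
}

oracle_wilcox_p <- function(x, y) {
  # exhaustive enumeration of the rank-sum null (tie-free data only)
  m <- length(x)
  r <- rank(c(x, y))
  EW <- m * (length(y)) / 2
  W_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(m + length(y), m)
  Ws <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(abs(Ws - EW) >= abs(W_obs - EW))
}

oracle_snn_edges <- function(X, k, prune = 1 / 15) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nbhd <- lapply(seq_len(n), function(i) order(D[i, ])[seq_len(k + 1)])
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(nbhd[[i]], nbhd[[j]]))
    w <- inter / (2 * (k + 1) - inter)
    if (w >= prune)
      out[[length(out) + 1]] <- data.frame(from = rownames(X)[i],
                                           to = rownames(X)[j], weight = w)
  }
  do.call(rbind, out)
}

oracle_ols <- function(y, t) {
  X <- cbind(1, t)
  as.vector(solve(t(X) %*% X, t(X) %*% y))  # (intercept, slope)
}
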