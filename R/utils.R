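#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library functions do not clobber
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' A single pipeline seed fans out to one seed per named stage so stages can be
#' re-run in isolation with identical results. The derivation is a fixed hash
#' of the stage name mixed with the global seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. `"simulate"`, `"tsne"`).
#' @return a positive integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) * 48271 + h) %% (2^31 - 1)) + 1L
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert-Arabie adjusted Rand index; used to score cluster recovery
#' against planted population labels.
#'
#' @param a,b vectors of equal length with class labels.
#' @return a scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0) return(NaN)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

# integer check tolerant of double storage
is_whole <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
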