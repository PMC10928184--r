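#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats cor cutree hclust as.dist dist prcomp quantile median
#'   mad sd var rnorm runif rpois rnbinom rlnorm phyper p.adjust lm coef
#'   cmdscale predict setNames complete.cases
#' @importFrom utils head tail
NULL

# deterministic 32-bit seed derived from a global seed and a string key;
# keeps per-module permutation streams independent of execution order
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

assert_count_matrix <- function(counts, arg = "counts") {
  counts <- as_gene_matrix(counts)
  if (any(counts < 0)) abort(sprintf("`%s` must be non-negative", arg))
  if (any(counts != round(counts))) {
    abort(sprintf("`%s` must contain integer counts", arg))
  }
  counts
}

# accepts a genes x samples numeric matrix, or a data frame whose first
# column holds gene ids (the on-disk counts schema)
as_gene_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    return(m)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric genes x samples matrix or a counts data frame")
  }
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of planted module structure.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# centred running mean with edge replication, so boundary values are not
# biased toward the interior (a shrinking window distorts curvature at the
# ends of the scanned range)
running_mean <- function(x, window) {
  if (window <= 1L) return(x)
  half <- floor(window / 2)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) mean(xp[i:(i + 2 * half)]), numeric(1))
}

# gene-wise ranks of a genes x samples matrix (average ranks for ties)
row_ranks <- function(x) {
  t(apply(x, 1L, rank))
}

# median pairwise squared Spearman correlation; kernel shared by the
# coexpression statistics (kept here for reuse by the generator tests)
median_r2_kernel <- function(x, method = "spearman") {
  if (nrow(x) < 2L) abort("need at least 2 genes")
  if (ncol(x) < 4L) abort("need at least 4 samples")
  sds <- sqrt(rowSums((x - rowMeans(x))^2))
  if (any(sds == 0)) {
    abort(sprintf("constant gene(s): %s",
                  paste(rownames(x)[sds == 0], collapse = ", ")))
  }
  r <- if (method == "spearman") cor(t(row_ranks(x))) else cor(t(x))
  median(r[upper.tri(r)]^2)
}
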