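#' Hierarchical clustering of samples on principal components
#'
#' Gene-standardises the expression matrix, projects samples onto the top
#' principal components (enough to explain `var_explained` of the variance),
#' and builds a Ward tree on Euclidean distances in that space.
#'
#' @param expr Numeric genes x samples matrix.
#' @param var_explained Cumulative variance fraction the retained PCs must
#'   reach.
#' @return An `hclust` tree over samples, with attribute `n_pcs`.
#' @export
sample_dendrogram <- function(expr, var_explained = 0.8) {
  expr <- as_gene_matrix(expr)
  if (ncol(expr) < 3) abort("need at least 3 samples")
  z <- t(scale(t(expr)))
  z <- z[apply(expr, 1, sd) > 0, , drop = FALSE]
  pc <- prcomp(t(z), center = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pcs <- max(2L, which(cum >= var_explained)[1])
  hc <- hclust(dist(pc$x[, seq_len(n_pcs), drop = FALSE]),
               method = "ward.D2")
  attr(hc, "n_pcs") <- n_pcs
  hc
}

#' Discriminant analysis of principal components
#'
#' PCA reduction of the sample space to `n_pcs` components followed by
#' linear discriminant analysis on the cohort labels with equal priors.
#' Posterior memberships come from the discriminant-space Gaussian model;
#' the reassignment matrix cross-tabulates prior labels against the argmax
#' posterior assignment.
#'
#' @param expr Numeric genes x samples matrix.
#' @param groups Cohort label per sample.
#' @param n_pcs Number of principal components retained (must be smaller
#'   than n_samples - n_groups).
#' @return A `dapc_result`: list with `n_pcs`, `ld_scores` (samples x
#'   discriminant axes), `posterior` (samples x groups, rows sum to 1),
#'   `assigned`, `reassignment` (groups x groups counts), `accuracy`.
#' @export
dapc <- function(expr, groups, n_pcs) {
  expr <- as_gene_matrix(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups for DAPC")
  if (any(table(groups) < 2)) abort("every cohort needs at least 2 samples")
  n <- ncol(expr)
  if (n_pcs >= n - nlevels(groups)) {
    abort("n_pcs must be smaller than n_samples - n_cohorts")
  }
  z <- t(scale(t(expr)))
  z <- z[apply(expr, 1, sd) > 0, , drop = FALSE]
  pc <- prcomp(t(z), center = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups,
                   prior = rep(1 / nlevels(groups), nlevels(groups)))
  pred <- predict(fit, scores)
  reass <- table(prior = groups, assigned = pred$class)
  structure(list(
    n_pcs = n_pcs,
    ld_scores = pred$x,
    posterior = pred$posterior,
    assigned = pred$class,
    groups = groups,
    reassignment = reass,
    accuracy = mean(pred$class == groups)
  ), class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("<dapc_result> %d PCs, %d groups, reassignment accuracy %.2f\n",
              x$n_pcs, nlevels(x$groups), x$accuracy))
  invisible(x)
}

#' Choose the number of PCs for DAPC by the a-score
#'
#' The a-score of a PC count is the observed reassignment proportion minus
#' the mean reassignment proportion over random relabelings of the samples
#' under the same settings: it penalises the overfitting that inflates
#' apparent discrimination as more PCs are retained. Returns the PC count
#' maximising the a-score.
#'
#' @param expr Numeric genes x samples matrix.
#' @param groups Cohort label per sample.
#' @param grid Candidate PC counts (defaults to a spread below the DAPC
#'   validity limit).
#' @param n_shuffles Random relabelings per grid point.
#' @param seed Integer seed (the procedure is deterministic under it).
#' @return List with `n_pcs` (the argmax) and `curve` (tibble: n_pcs,
#'   a_score, observed, null_mean).
#' @export
optimize_a_score <- function(expr, groups, grid = NULL, n_shuffles = 10,
                             seed = 1L) {
  expr <- as_gene_matrix(expr)
  groups <- as.factor(groups)
  max_pcs <- ncol(expr) - nlevels(groups) - 1
  if (is.null(grid)) grid <- unique(pmax(1, round(seq(1, max_pcs, length.out = 8))))
  grid <- grid[grid >= 1 & grid <= max_pcs]
  if (length(grid) == 0) abort("empty PC grid")
  set.seed(derive_seed(seed, "a_score"))
  rows <- purrr::map(grid, function(np) {
    obs <- dapc(expr, groups, np)$accuracy
    null <- vapply(seq_len(n_shuffles), function(i) {
      dapc(expr, sample(groups), np)$accuracy
    }, numeric(1))
    tibble::tibble(n_pcs = np, a_score = obs - mean(null),
                   observed = obs, null_mean = mean(null))
  })
  curve <- dplyr::bind_rows(rows)
  list(n_pcs = curve$n_pcs[which.max(curve$a_score)], curve = curve)
}
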