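#' Spearman dissimilarity between genes
#'
#' `D_ij = 1 - rho_ij` with Spearman rank correlation (average ranks for
#' ties); symmetric, zero diagonal, range \[0, 2\].
#'
#' @param expr Numeric genes x samples matrix.
#' @return Gene x gene dissimilarity matrix.
#' @export
spearman_dissimilarity <- function(expr) {
  expr <- as_gene_matrix(expr)
  if (ncol(expr) < 4) abort("need at least 4 samples")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant gene(s): %s",
                  paste(rownames(expr)[sds == 0], collapse = ", ")))
  }
  1 - cor(t(expr), method = "spearman")
}

#' Soft-thresholded adjacency from a Spearman dissimilarity
#'
#' Signed adjacency `A_ij = ((1 + rho_ij) / 2)^beta` with
#' `rho_ij = 1 - D_ij`; perfectly correlated pairs get 1, perfectly
#' anti-correlated pairs get 0. `1 - A` serves as the clustering distance.
#' With `signed = FALSE`, uses `|rho|^beta` instead.
#'
#' @param D Dissimilarity from [spearman_dissimilarity()].
#' @param beta Soft-thresholding power.
#' @param signed Use the signed functional form (default).
#' @return Adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
soft_adjacency <- function(D, beta = 6, signed = TRUE) {
  if (beta <= 0) abort("`beta` must be positive")
  rho <- 1 - D
  A <- if (signed) ((1 + rho) / 2)^beta else abs(rho)^beta
  diag(A) <- 1
  A
}

#' Select the number of clusters by the inflection of the R-squared curve
#'
#' Cuts a Ward tree of the given distance into K = `k_min` ... `k_max`
#' clusters, computes for each K the fraction of variance explained,
#' `R2(K) = 1 - WSS(K) / TSS`, on a classical-MDS embedding of the distance
#' (coordinates on the positive-eigenvalue axes), smooths the curve with a
#' centred running mean, and selects the K with the largest absolute discrete
#' second difference (the inflection point). A curve with no curvature falls
#' back to `k_min` with a warning.
#'
#' @param distance A `dist` or symmetric matrix (e.g. `1 - A`).
#' @param k_min,k_max Scanned range of K (clipped to the number of objects
#'   with a warning).
#' @param smooth_window Width of the running-mean smoother (1 = none).
#' @return List with `k` (selected K), `r2_curve` (tibble: k, r2, r2_smooth),
#'   and `hclust` (the Ward tree).
#' @export
select_k <- function(distance, k_min = 1, k_max = 200, smooth_window = 1) {
  d <- as.dist(distance)
  n <- attr(d, "Size")
  if (k_max > n) {
    warn(sprintf("k_max clipped from %d to %d objects", k_max, n))
    k_max <- n
  }
  ks <- k_min:k_max
  if (length(ks) < 3) abort("need at least 3 distinct K values to scan")
  hc <- hclust(d, method = "ward.D2")
  # non-Euclidean distances give some non-positive eigenvalues; dropping
  # them (and truncating to 50 axes) is expected, not a condition
  emb <- suppressWarnings(cmdscale(d, k = min(n - 1, 50), eig = TRUE))
  keep <- emb$eig[seq_len(ncol(emb$points))] > 1e-9
  X <- emb$points[, keep, drop = FALSE]
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  ct <- cutree(hc, k = ks)
  r2 <- vapply(seq_along(ks), function(i) {
    cl <- ct[, i]
    centers <- rowsum(X, cl) / as.vector(table(cl))
    wss <- sum((X - centers[as.character(cl), , drop = FALSE])^2)
    if (tss == 0) 1 else 1 - wss / tss
  }, numeric(1))
  r2s <- running_mean(r2, smooth_window)
  if (length(ks) >= 3) {
    interior <- 2:(length(ks) - 1)
    d2 <- r2s[interior + 1] - 2 * r2s[interior] + r2s[interior - 1]
    if (max(abs(d2)) < 1e-10) {
      warn("R-squared curve has no inflection; falling back to k_min")
      k_sel <- k_min
    } else {
      k_sel <- ks[interior][which.max(abs(d2))]
    }
  }
  list(k = k_sel,
       r2_curve = tibble::tibble(k = ks, r2 = r2, r2_smooth = r2s),
       hclust = hc)
}

# one dissimilarity -> adjacency -> Ward -> cut pass; the unit the LOO
# bootstrap repeats
cluster_pass <- function(expr, beta, signed, k_min, k_max, smooth_window,
                         k_fixed = NULL) {
  D <- spearman_dissimilarity(expr)
  A <- soft_adjacency(D, beta = beta, signed = signed)
  dd <- 1 - A
  if (is.null(k_fixed)) {
    sel <- select_k(dd, k_min = k_min, k_max = k_max,
                    smooth_window = smooth_window)
    k <- sel$k
    hc <- sel$hclust
  } else {
    k <- min(k_fixed, nrow(A))
    hc <- hclust(as.dist(dd), method = "ward.D2")
    sel <- NULL
  }
  membership <- cutree(hc, k = k)
  list(membership = membership, adjacency = A, k = k, selection = sel)
}

#' Leave-one-out stability of gene co-clustering
#'
#' Repeats the full dissimilarity -> soft adjacency -> Ward -> K-selection
#' pass once per sample, each time leaving that sample out, and records for
#' every gene pair the fraction of iterations in which they share a cluster.
#' Genes that become constant in any leave-one-out subset are excluded with a
#' warning. Each iteration also marks its lowest-cohesion ("junk") cluster
#' for [remove_junk()].
#'
#' @param expr Numeric genes x samples matrix (at least 5 samples).
#' @param beta,signed Passed to [soft_adjacency()].
#' @param k_policy `"reselect"` re-runs K selection in every iteration;
#'   `"fixed"` reuses `k_fixed`.
#' @param k_fixed K to reuse when `k_policy = "fixed"`.
#' @param k_min,k_max,smooth_window Passed to [select_k()].
#' @return A `loo_stability` list: `S` (co-clustering similarity, diagonal 1,
#'   entries in multiples of 1/n_iter), `memberships` (genes x iterations),
#'   `junk_cluster` (logical genes x iterations: gene sat in the iteration's
#'   junk cluster), `cohesion_floor_passed`, and `n_iter`.
#' @export
loo_stability <- function(expr, beta = 6, signed = TRUE,
                          k_policy = c("reselect", "fixed"), k_fixed = NULL,
                          k_min = 1, k_max = 200, smooth_window = 1) {
  k_policy <- match.arg(k_policy)
  expr <- as_gene_matrix(expr)
  n_s <- ncol(expr)
  if (n_s < 5) abort("need at least 5 samples for leave-one-out stability")
  ok_gene <- rep(TRUE, nrow(expr))
  for (i in seq_len(n_s)) {
    sds <- apply(expr[, -i, drop = FALSE], 1, sd)
    ok_gene <- ok_gene & sds > 0
  }
  if (!all(ok_gene)) {
    warn(sprintf("%d gene(s) constant in a leave-one-out subset excluded",
                 sum(!ok_gene)))
  }
  x <- expr[ok_gene, , drop = FALSE]
  n_g <- nrow(x)
  co <- matrix(0, n_g, n_g, dimnames = list(rownames(x), rownames(x)))
  memberships <- matrix(NA_integer_, n_g, n_s,
                        dimnames = list(rownames(x), NULL))
  junk <- matrix(FALSE, n_g, n_s, dimnames = list(rownames(x), NULL))
  junk_nf <- junk
  for (i in seq_len(n_s)) {
    pass <- cluster_pass(x[, -i, drop = FALSE], beta, signed,
                         k_min, k_max, smooth_window,
                         k_fixed = if (k_policy == "fixed") k_fixed else NULL)
    cl <- pass$membership
    memberships[, i] <- cl
    co <- co + outer(cl, cl, `==`)
    jc <- junk_cluster_of(pass$adjacency, cl)
    junk_nf[, i] <- cl == jc$cluster
    junk[, i] <- junk_nf[, i] & jc$below_floor
  }
  structure(list(S = co / n_s, memberships = memberships,
                 junk_cluster = junk, junk_cluster_nofloor = junk_nf,
                 n_iter = n_s),
            class = "loo_stability")
}

# identify the lowest-cohesion cluster of one clustering pass; cohesion is
# the mean within-cluster adjacency (off-diagonal); the floor compares it
# with the matrix-wide mean adjacency
junk_cluster_of <- function(A, cl) {
  diag(A) <- NA
  cohesion <- vapply(sort(unique(cl)), function(k) {
    idx <- cl == k
    if (sum(idx) < 2) return(mean(A[idx, ], na.rm = TRUE))
    mean(A[idx, idx], na.rm = TRUE)
  }, numeric(1))
  worst <- sort(unique(cl))[which.min(cohesion)]
  list(cluster = worst,
       below_floor = min(cohesion) < mean(A, na.rm = TRUE))
}

#' Flag junk genes from leave-one-out co-clustering
#'
#' In every leave-one-out iteration the cluster with the lowest mean
#' within-cluster adjacency is the iteration's junk cluster (subject to an
#' optional cohesion floor: only clusters less cohesive than the matrix-wide
#' mean adjacency qualify). A gene is junk if it sat in the junk cluster in
#' at least `junk_fraction` of iterations (inclusive threshold).
#'
#' @param loo A [loo_stability()] result.
#' @param junk_fraction Fraction of iterations required.
#' @param cohesion_floor Apply the matrix-wide-mean cohesion floor (default).
#' @return Character vector of junk gene ids.
#' @export
remove_junk <- function(loo, junk_fraction = 0.50, cohesion_floor = TRUE) {
  if (!inherits(loo, "loo_stability")) abort("`loo` must be a loo_stability")
  flags <- loo$junk_cluster
  if (!cohesion_floor) {
    # without the floor every iteration contributes its lowest-cohesion
    # cluster regardless of absolute cohesion
    flags <- loo$junk_cluster_nofloor %||% flags
  }
  frac <- rowMeans(flags)
  junk <- rownames(flags)[frac >= junk_fraction]
  if (length(junk) == nrow(flags)) {
    abort("all genes flagged as junk; data look degenerate")
  }
  junk
}

#' Consensus modules from the co-clustering similarity
#'
#' Ward-clusters the non-junk genes on distance `1 - S` with K selected by
#' the same inflection rule, assigning every non-junk gene to exactly one
#' preliminary module.
#'
#' @param loo A [loo_stability()] result.
#' @param junk_genes Genes to exclude (from [remove_junk()]).
#' @param k_min,k_max,smooth_window Passed to [select_k()].
#' @return Named integer vector of module indices per gene, with the K
#'   selection stored in attributes `k` and `r2_curve`.
#' @export
consensus_modules <- function(loo, junk_genes = character(0),
                              k_min = 1, k_max = 200, smooth_window = 1) {
  S <- loo$S
  keep <- setdiff(rownames(S), junk_genes)
  if (length(keep) < 2) abort("fewer than 2 non-junk genes")
  d <- 1 - S[keep, keep]
  sel <- select_k(d, k_min = k_min, k_max = min(k_max, length(keep)),
                  smooth_window = smooth_window)
  membership <- cutree(sel$hclust, k = sel$k)
  attr(membership, "k") <- sel$k
  attr(membership, "r2_curve") <- sel$r2_curve
  membership
}

#' Split a module into over/under submodules
#'
#' Computes the module eigengene on disease samples, partitions member genes
#' by the sign of their correlation with it, and labels each non-empty part
#' `o` (over) or `u` (under) by the sign of its mean disease-minus-control
#' log2 expression.
#'
#' @param genes Member gene ids.
#' @param expr_disease,expr_control Expression matrices (genes x samples)
#'   restricted to the cohort's disease and control samples.
#' @return A list of one or two parts, each `list(genes, suffix)`.
#' @export
split_ou <- function(genes, expr_disease, expr_control) {
  if (is.null(expr_control) || ncol(expr_control) == 0) {
    abort("no control samples available for over/under labelling")
  }
  xd <- expr_disease[genes, , drop = FALSE]
  xc <- expr_control[genes, , drop = FALSE]
  if (length(genes) == 1) {
    suffix <- if (mean(xd) - mean(xc) > 0) "o" else "u"
    return(list(list(genes = genes, suffix = suffix)))
  }
  eg <- eigengene(xd)
  cors <- apply(xd, 1, function(g) {
    if (sd(g) == 0) 1 else cor(g, eg)
  })
  parts <- split(genes, factor(cors >= 0, levels = c(TRUE, FALSE)))
  parts <- parts[lengths(parts) > 0]
  lapply(parts, function(gs) {
    delta <- mean(rowMeans(expr_disease[gs, , drop = FALSE])) -
      mean(rowMeans(expr_control[gs, , drop = FALSE]))
    list(genes = gs, suffix = if (delta > 0) "o" else "u")
  })
}

#' Discover stable gene coexpression modules in one cohort
#'
#' The full per-cohort discovery pipeline: MAD variance filter, Spearman
#' dissimilarity, signed soft-thresholded adjacency (power `beta`), Ward
#' clustering with inflection-point K selection, leave-one-out stability
#' bootstrapping, junk-gene removal, consensus clustering of the remaining
#' genes on the co-clustering similarity, and over/under submodule splitting
#' against the cohort's control samples. Modules are only assembled in
#' cohorts with more than `min_samples - 1` disease samples.
#'
#' @param study An `expression_study` from [preprocess_study()].
#' @param cohort Cohort name to analyse (its `disease` samples drive the
#'   network; its `control` samples anchor the o/u labels).
#' @param beta Soft-thresholding power.
#' @param mad_min MAD variance-filter threshold.
#' @param k_min,k_max,smooth_window K-selection settings.
#' @param k_policy `"reselect"` or `"fixed"` K during leave-one-out
#'   iterations.
#' @param junk_fraction,cohesion_floor Junk-gene settings ([remove_junk()]).
#' @param min_samples Minimum number of disease samples (cohorts below the
#'   gate are refused).
#' @param signed Signed adjacency form (see [soft_adjacency()]).
#' @return A `module_set`: list with `cohort`, `modules` (tibble: module_id,
#'   gene_id, stability), `summary` (tibble per module), `k_selected`,
#'   `r2_curve`, `junk_genes`, `filtered_genes`.
#' @export
discover_modules <- function(study, cohort, beta = 6, mad_min = 0.25,
                             k_min = 1, k_max = 200, smooth_window = 1,
                             k_policy = "reselect", junk_fraction = 0.50,
                             cohesion_floor = TRUE, min_samples = 21,
                             signed = TRUE) {
  if (!inherits(study, "expression_study")) {
    abort("`study` must be an expression_study")
  }
  dis <- study_samples(study, cohort, "disease")
  ctl <- study_samples(study, cohort, "control")
  if (length(dis) < min_samples) {
    abort(sprintf(
      "cohort '%s' has %d disease samples; modules are only assembled in cohorts with more than %d samples",
      cohort, length(dis), min_samples - 1))
  }
  expr_d <- study$expr[, dis, drop = FALSE]
  keep <- mad_filter(expr_d, mad_min = mad_min)
  filtered <- setdiff(rownames(expr_d), keep)
  x <- expr_d[keep, , drop = FALSE]
  loo <- loo_stability(x, beta = beta, signed = signed, k_policy = k_policy,
                       k_min = k_min, k_max = min(k_max, nrow(x)),
                       smooth_window = smooth_window)
  junk <- remove_junk(loo, junk_fraction = junk_fraction,
                      cohesion_floor = cohesion_floor)
  membership <- consensus_modules(loo, junk, k_min = k_min,
                                  k_max = min(k_max, nrow(loo$S)),
                                  smooth_window = smooth_window)
  expr_c <- study$expr[, ctl, drop = FALSE]
  rows <- list()
  for (k in sort(unique(membership))) {
    genes <- names(membership)[membership == k]
    parts <- split_ou(genes, study$expr[, dis, drop = FALSE], expr_c)
    for (p in parts) {
      mid <- sprintf("%s.%d.%s", cohort, k, p$suffix)
      stab <- vapply(p$genes, function(g) {
        others <- setdiff(genes, g)
        if (length(others) == 0) 1 else mean(loo$S[g, others])
      }, numeric(1))
      rows[[mid]] <- tibble::tibble(module_id = mid, gene_id = p$genes,
                                    stability = unname(stab))
    }
  }
  modules <- dplyr::bind_rows(rows)
  summary <- modules |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     mean_stability = mean(.data$stability),
                     .groups = "drop") |>
    dplyr::mutate(suffix = stringr::str_extract(.data$module_id, "[ou]$"),
                  cohort = cohort, k_selected = attr(membership, "k"))
  structure(list(
    cohort = cohort, modules = modules, summary = summary,
    k_selected = attr(membership, "k"),
    r2_curve = attr(membership, "r2_curve"),
    junk_genes = junk, filtered_genes = filtered,
    loo = loo
  ), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> cohort %s: %d modules (K = %d), %d junk genes\n",
              x$cohort, nrow(x$summary), x$k_selected, length(x$junk_genes)))
  invisible(x)
}

#' Module gene sets of a module set
#'
#' @param ms A `module_set` (or a modules tibble with `module_id`/`gene_id`).
#' @return Named list of character vectors.
#' @export
module_gene_sets <- function(ms) {
  tbl <- if (inherits(ms, "module_set")) ms$modules else tibble::as_tibble(ms)
  split(tbl$gene_id, tbl$module_id)
}
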