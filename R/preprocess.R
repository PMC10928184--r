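#' Filter genes by minimum expression across cohorts
#'
#' A gene is retained if, within every cohort (default) or within at least one
#' cohort, at least `min_fraction` of that cohort's samples show at least
#' `min_count` counts. Gene order is preserved.
#'
#' @param counts Integer genes x samples matrix (or counts data frame with a
#'   leading gene-id column).
#' @param cohort_map Named character vector mapping sample id -> cohort, or a
#'   metadata data frame with `sample_id` and `cohort` columns.
#' @param min_count Minimum count for a sample to count as detecting the gene.
#' @param min_fraction Minimum fraction of a cohort's samples detecting the
#'   gene.
#' @param scope `"each"` requires the rule in every cohort; `"any"` in at
#'   least one.
#' @return Character vector of retained gene ids, with a `report` attribute:
#'   a tibble (gene_id, retained, reason_dropped).
#' @export
filter_low_expression <- function(counts, cohort_map, min_count = 6,
                                  min_fraction = 0.20,
                                  scope = c("each", "any")) {
  scope <- match.arg(scope)
  counts <- assert_count_matrix(counts)
  if (is.data.frame(cohort_map)) {
    cohort_map <- setNames(as.character(cohort_map$cohort),
                           cohort_map$sample_id)
  }
  if (!all(colnames(counts) %in% names(cohort_map))) {
    abort("every sample must be assigned a cohort")
  }
  cohorts <- split(colnames(counts), cohort_map[colnames(counts)])
  if (any(lengths(cohorts) == 0)) abort("empty cohort")
  frac <- vapply(cohorts, function(smp) {
    rowMeans(counts[, smp, drop = FALSE] >= min_count)
  }, numeric(nrow(counts)))
  frac <- matrix(frac, nrow = nrow(counts))
  ok <- if (scope == "each") {
    rowSums(frac >= min_fraction) == length(cohorts)
  } else {
    rowSums(frac >= min_fraction) > 0
  }
  retained <- rownames(counts)[ok]
  report <- tibble::tibble(
    gene_id = rownames(counts), retained = ok,
    reason_dropped = ifelse(ok, NA_character_,
                            sprintf("detected (>=%d counts) in <%d%% of samples",
                                    min_count, round(100 * min_fraction)))
  )
  attr(retained, "report") <- report
  retained
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling normalisation for count data. The reference sample
#' is the one whose upper-quartile count fraction is closest to the mean
#' upper-quartile fraction; each sample's factor is 2 to the weighted mean of
#' gene-wise log ratios (M-values) against the reference after two-sided
#' trimming of extreme M (by `logratio_trim`) and extreme average abundance A
#' (by `abs_trim`), with inverse approximate binomial variances as weights.
#' Factors are rescaled to multiply to 1.
#'
#' @param counts Integer genes x samples matrix.
#' @param logratio_trim Two-sided trim fraction applied to M-values.
#' @param abs_trim Two-sided trim fraction applied to A-values.
#' @return Named numeric vector of positive scaling factors (product 1).
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- assert_count_matrix(counts)
  if (ncol(counts) < 2) abort("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(sprintf("sample(s) with zero total counts: %s",
                  paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  uq <- vapply(seq_len(ncol(counts)),
               function(j) quantile(counts[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ok <- counts[, j] > 0 & counts[, ref] > 0
    if (!any(ok)) abort("no gene expressed in both sample and reference")
    yj <- counts[ok, j]; yr <- counts[ok, ref]
    pj <- yj / lib[j];   pr <- yr / lib[ref]
    M <- log2(pj / pr)
    A <- 0.5 * log2(pj * pr)
    w <- (lib[j] - yj) / (lib[j] * yj) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
    keep <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep) || all(w[keep] == 0)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Log2 counts per million
#'
#' The standard moderated log-CPM transform:
#' `log2((count + offset) / (library_size * factor + 1) * 1e6)`.
#'
#' @param counts Integer genes x samples matrix.
#' @param factors Scaling factors from [tmm_normalize()] (default all 1).
#' @param offset Pseudo-count added to each count.
#' @return Numeric matrix of the same shape, finite everywhere.
#' @export
log_cpm <- function(counts, factors = NULL, offset = 0.5) {
  counts <- as_gene_matrix(counts)
  if (any(counts < 0)) abort("negative counts")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  lib <- colSums(counts)
  eff <- lib * factors + 1
  log2(sweep(counts + offset, 2, eff, `/`) * 1e6)
}

#' Filter genes by median absolute deviation
#'
#' Retains genes whose raw MAD (no consistency constant) across samples is at
#' least `mad_min`; the threshold is inclusive. Intended for log-scale
#' expression ahead of coexpression network construction.
#'
#' @param expr Numeric genes x samples matrix (log scale).
#' @param mad_min Minimum raw MAD.
#' @return Character vector of retained gene ids.
#' @export
mad_filter <- function(expr, mad_min = 0.25) {
  expr <- as_gene_matrix(expr)
  if (ncol(expr) < 3) abort("need at least 3 samples")
  mads <- apply(expr, 1, mad, constant = 1)
  rownames(expr)[mads >= mad_min]
}

#' Build a normalised expression study from counts and metadata
#'
#' Runs the preprocessing chain: per-cohort low-expression filtering, TMM
#' scaling factors, and log2-CPM transformation, returning the container the
#' downstream module discovery consumes.
#'
#' @param counts Integer genes x samples matrix or counts data frame.
#' @param sample_meta Metadata tibble with at least `sample_id`, `cohort`,
#'   `condition` (`"disease"`/`"control"`).
#' @param min_count,min_fraction,scope Passed to [filter_low_expression()].
#' @return An `expression_study`: list with `expr` (log2 matrix), `sample_meta`,
#'   `gene_ids`, `factors`, and a `provenance` record of applied filters.
#' @export
preprocess_study <- function(counts, sample_meta, min_count = 6,
                             min_fraction = 0.20, scope = "each") {
  counts <- assert_count_matrix(counts)
  sample_meta <- tibble::as_tibble(sample_meta)
  need <- c("sample_id", "cohort", "condition")
  if (!all(need %in% names(sample_meta))) {
    abort("sample_meta needs columns sample_id, cohort, condition")
  }
  if (anyDuplicated(sample_meta$sample_id)) abort("duplicate sample ids")
  if (!setequal(sample_meta$sample_id, colnames(counts))) {
    abort("sample ids in metadata and counts must match")
  }
  counts <- counts[, sample_meta$sample_id, drop = FALSE]
  keep <- filter_low_expression(counts, sample_meta, min_count = min_count,
                                min_fraction = min_fraction, scope = scope)
  report <- attr(keep, "report")
  keep <- as.vector(keep)
  counts_f <- counts[keep, , drop = FALSE]
  if (nrow(counts_f) == 0) abort("no genes pass the expression filter")
  factors <- tmm_normalize(counts_f)
  expr <- log_cpm(counts_f, factors)
  structure(list(
    expr = expr, sample_meta = sample_meta, gene_ids = keep,
    factors = factors,
    provenance = list(
      n_genes_in = nrow(counts), n_genes_kept = length(keep),
      min_count = min_count, min_fraction = min_fraction, scope = scope,
      filter_report = report)
  ), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%d cohorts)\n",
              nrow(x$expr), ncol(x$expr),
              dplyr::n_distinct(x$sample_meta$cohort)))
  invisible(x)
}

# samples of one cohort/arm
study_samples <- function(study, cohort = NULL, condition = NULL) {
  m <- study$sample_meta
  if (!is.null(cohort)) m <- m[m$cohort %in% cohort, ]
  if (!is.null(condition)) m <- m[m$condition %in% condition, ]
  m$sample_id
}
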