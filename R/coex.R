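#' Median pairwise squared correlation within a module
#'
#' Squared Spearman (default) correlation over all unordered gene pairs of
#' the matrix; the median is the module's coexpression statistic.
#'
#' @param expr Numeric genes x samples matrix restricted to the module's
#'   genes (at least 2 genes, 4 samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A number in \[0, 1\].
#' @export
median_pairwise_r2 <- function(expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  median_r2_kernel(as_gene_matrix(expr), method = method)
}

#' Differential coexpression permutation test
#'
#' Tests whether a module's median pairwise squared correlation differs
#' between disease and control samples. The observed statistic is
#' `delta = median R2(disease) - median R2(control)`; the null permutes the
#' disease/control labels over the pooled samples (arm sizes preserved) and
#' recomputes delta. Two-sided empirical p with +1 smoothing:
#' `p = (1 + #\{|delta*| >= |delta|\}) / (n_perm + 1)`.
#'
#' @param expr Expression matrix (genes x samples) covering both arms.
#' @param condition Character vector per sample, `"disease"`/`"control"`.
#' @param genes Module gene ids (default: all rows).
#' @param module_id Label copied into the result and mixed into the
#'   permutation seed, so module-level results are reproducible regardless of
#'   execution order.
#' @param n_perm Number of permutations.
#' @param seed Global integer seed.
#' @param method Correlation flavour (see [median_pairwise_r2()]).
#' @return One-row tibble: module_id, median_r2_disease, median_r2_control,
#'   delta_r2, p_empirical, n_perm, seed.
#' @export
diff_coexpression_test <- function(expr, condition, genes = NULL,
                                   module_id = "module", n_perm = 10000,
                                   seed = 1L,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  expr <- as_gene_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing) > 0) abort("module genes absent from matrix")
    expr <- expr[genes, , drop = FALSE]
  }
  if (length(condition) != ncol(expr)) {
    abort("`condition` must have one label per sample")
  }
  if (n_perm < 100) warn("fewer than 100 permutations; p-values will be coarse")
  is_d <- condition == "disease"
  if (sum(is_d) < 4 || sum(!is_d) < 4) abort("both arms need >= 4 samples")
  delta_of <- function(d_idx) {
    median_r2_kernel(expr[, d_idx, drop = FALSE], method) -
      median_r2_kernel(expr[, !d_idx, drop = FALSE], method)
  }
  r2_d <- median_r2_kernel(expr[, is_d, drop = FALSE], method)
  r2_c <- median_r2_kernel(expr[, !is_d, drop = FALSE], method)
  obs <- r2_d - r2_c
  set.seed(derive_seed(seed, paste0("dcx:", module_id)))
  n_d <- sum(is_d)
  n_s <- ncol(expr)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- logical(n_s)
    perm[sample.int(n_s, n_d)] <- TRUE
    if (abs(delta_of(perm)) >= abs(obs)) exceed <- exceed + 1L
  }
  tibble::tibble(
    module_id = module_id,
    median_r2_disease = r2_d,
    median_r2_control = r2_c,
    delta_r2 = obs,
    p_empirical = (1 + exceed) / (n_perm + 1),
    n_perm = n_perm, seed = seed
  )
}

#' Coexpression conservation test in another cohort
#'
#' Asks whether a module discovered in one cohort is also coexpressed in a
#' target cohort. The statistic is the median pairwise squared correlation of
#' the module's mappable genes in the target matrix; the null redraws random
#' gene sets of the same size from the target cohort's expressed genes.
#' One-sided empirical p for exceeding the null; `conserved` at level `alpha`.
#'
#' @param expr_target Target-cohort expression matrix (genes x samples).
#' @param genes Module gene ids (at least 50% must be present in the target
#'   matrix, else an error).
#' @param module_id,target_cohort Labels copied into the result (and mixed
#'   into the seed).
#' @param is_control Whether the target is control tissue (carried through
#'   for regulome classification).
#' @param n_perm Number of random gene sets.
#' @param seed Global integer seed.
#' @param alpha Significance level for the conservation call.
#' @param method Correlation flavour.
#' @return One-row tibble: module_id, target_cohort, is_control,
#'   median_r2_target, p_empirical, conserved, n_perm.
#' @export
conservation_test <- function(expr_target, genes, module_id = "module",
                              target_cohort = "target", is_control = FALSE,
                              n_perm = 10000, seed = 1L, alpha = 0.05,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  expr_target <- as_gene_matrix(expr_target)
  mappable <- intersect(genes, rownames(expr_target))
  if (length(mappable) < 0.5 * length(genes)) {
    abort(sprintf("only %d/%d module genes mappable in target cohort",
                  length(mappable), length(genes)))
  }
  obs <- median_r2_kernel(expr_target[mappable, , drop = FALSE], method)
  set.seed(derive_seed(seed, paste0("cons:", module_id, ":", target_cohort)))
  pool <- rownames(expr_target)
  sz <- length(mappable)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rnd <- pool[sample.int(length(pool), sz)]
    if (median_r2_kernel(expr_target[rnd, , drop = FALSE], method) >= obs) {
      exceed <- exceed + 1L
    }
  }
  p <- (1 + exceed) / (n_perm + 1)
  tibble::tibble(module_id = module_id, target_cohort = target_cohort,
                 is_control = is_control, median_r2_target = obs,
                 p_empirical = p, conserved = p < alpha, n_perm = n_perm)
}

#' Module eigengene
#'
#' First principal component of the gene-standardised module submatrix,
#' returned as a per-sample score vector with unit variance; the sign is
#' fixed so the eigengene correlates non-negatively with the module's mean
#' expression profile.
#'
#' @param expr Numeric genes x samples matrix (module members; >= 2 genes).
#' @return Numeric vector of per-sample scores (named by sample).
#' @export
eigengene <- function(expr) {
  expr <- as_gene_matrix(expr)
  if (nrow(expr) < 2) abort("need at least 2 genes")
  sds <- apply(expr, 1, sd)
  if (all(sds == 0)) abort("constant submatrix")
  x <- expr[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  mean_profile <- colMeans(z)
  if (sd(mean_profile) > 0 && cor(scores, mean_profile) < 0) scores <- -scores
  scores <- scores / sd(scores)
  setNames(scores, colnames(expr))
}

#' Associate a module eigengene with a phenotype covariate
#'
#' Ordinary least squares of the eigengene on the covariate (plus any extra
#' covariates), with a two-sided t-test on the covariate's slope. When the
#' covariate is `duration` and the metadata carries `age`, age is added as an
#' additional covariate automatically, since disease duration is confounded
#' with patient age.
#'
#' @param scores Eigengene score vector (one per sample, aligned with
#'   `data`).
#' @param data Data frame of per-sample covariates.
#' @param covariate Name of the covariate of interest.
#' @param extra_covariates Further adjustment covariates (names in `data`).
#' @return One-row tibble: covariate, slope, t, p, n, adjusted_for.
#' @export
phenotype_association <- function(scores, data, covariate,
                                  extra_covariates = character(0)) {
  data <- as.data.frame(data)
  if (!covariate %in% names(data)) abort("covariate not found in data")
  if (covariate == "duration" && "age" %in% names(data) &&
      !"age" %in% extra_covariates) {
    extra_covariates <- c(extra_covariates, "age")
  }
  vars <- c(covariate, extra_covariates)
  df <- data.frame(.eigengene = scores, data[vars])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 5 + length(vars)) {
    abort("too few complete observations for the design")
  }
  X <- stats::model.matrix(
    stats::reformulate(vars, response = ".eigengene"), df)
  if (qr(X)$rank < ncol(X)) abort("collinear design")
  fit <- lm(stats::reformulate(vars, response = ".eigengene"), data = df)
  sm <- summary(fit)$coefficients
  row <- grep(paste0("^", covariate), rownames(sm))[1]
  tibble::tibble(covariate = covariate,
                 slope = sm[row, 1], t = sm[row, 3], p = sm[row, 4],
                 n = nrow(df),
                 adjusted_for = paste(extra_covariates, collapse = ","))
}

#' Differential coexpression tests for every module of a module set
#'
#' @param ms A `module_set` from [discover_modules()].
#' @param study The `expression_study` the modules were discovered in.
#' @param n_perm,seed,method Passed to [diff_coexpression_test()].
#' @param alpha Level used for the convenience `significant` flag and the
#'   Benjamini-Hochberg column.
#' @return Tibble of per-module differential-coexpression statistics with a
#'   BH-adjusted column (reported, not used for gating).
#' @export
coexpression_stats <- function(ms, study, n_perm = 1000, seed = 1L,
                               alpha = 0.05,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cohort <- ms$cohort
  samples <- study_samples(study, cohort)
  expr <- study$expr[, samples, drop = FALSE]
  cond <- study$sample_meta$condition[match(samples,
                                            study$sample_meta$sample_id)]
  sets <- module_gene_sets(ms)
  res <- purrr::imap(sets, function(genes, mid) {
    diff_coexpression_test(expr, cond, genes = genes, module_id = mid,
                           n_perm = n_perm, seed = seed, method = method)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(p_bh = p.adjust(.data$p_empirical, "BH"),
                  significant = .data$p_empirical < alpha,
                  cohort = cohort)
}
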