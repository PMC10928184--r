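#' Describe a planted coexpression module
#'
#' A planted module is a group of genes driven by a shared per-sample latent
#' factor, with separately calibrated coexpression strength in disease and
#' control samples. The coexpression target is the median pairwise squared
#' Spearman correlation the member genes should realise at large sample size.
#'
#' @param module_id Label for the module.
#' @param n_genes Number of member genes (ids are assigned from the study
#'   universe by [sim_config()]); alternatively pass explicit ids via `genes`.
#' @param genes Optional explicit gene ids (overrides `n_genes`).
#' @param direction Per-gene direction, `"over"` or `"under"`, recycled to
#'   the module size. "under" genes load negatively on the module factor and
#'   have their baseline mean halved in disease samples.
#' @param r2_disease,r2_control Target median pairwise squared Spearman
#'   correlation among member genes in each arm, in \[0, 1\].
#' @param regulator_tf Optional id of a transcription factor planted as the
#'   module's upstream regulator in the synthetic knowledge base.
#' @param regulator_sign Sign of the planted regulator's edges,
#'   `"activation"` or `"inhibition"`.
#' @param pathway_label Optional name of a planted pathway gene set covering
#'   the module.
#' @param cohorts Cohort names in which the module is planted; `NULL` plants
#'   it in every cohort.
#' @return A `planted_module` list.
#' @export
planted_module <- function(module_id, n_genes = NULL, genes = NULL,
                           direction = "over",
                           r2_disease = 0.7, r2_control = 0.1,
                           regulator_tf = NULL,
                           regulator_sign = c("activation", "inhibition"),
                           pathway_label = NULL, cohorts = NULL) {
  regulator_sign <- match.arg(regulator_sign)
  if (is.null(genes) && is.null(n_genes)) abort("give `n_genes` or `genes`")
  size <- if (is.null(genes)) n_genes else length(genes)
  if (size < 2) abort("a planted module needs at least 2 genes")
  if (r2_disease < 0 || r2_disease > 1 || r2_control < 0 || r2_control > 1) {
    abort("r2 targets must lie in [0, 1]")
  }
  if (!all(direction %in% c("over", "under"))) {
    abort("direction must be 'over' or 'under'")
  }
  structure(list(
    module_id = as.character(module_id),
    genes = genes, n_genes = size,
    direction = rep_len(direction, size),
    r2_disease = r2_disease, r2_control = r2_control,
    regulator_tf = regulator_tf, regulator_sign = regulator_sign,
    pathway_label = pathway_label, cohorts = cohorts
  ), class = "planted_module")
}

#' Configure a synthetic multi-cohort study
#'
#' Defines the study design for [generate_cohorts()]: the gene universe,
#' the cohorts (each with a disease and a matched control arm), the planted
#' coexpression modules, and the count observation layer (negative binomial
#' with lognormal library sizes).
#'
#' @param n_genes Total genes in the universe (planted module genes are
#'   assigned from the front of the universe; the rest are independent
#'   background genes).
#' @param cohorts Data frame with columns `name`, `n_disease`, `n_control`.
#' @param modules List of [planted_module()] objects.
#' @param library_size_mean Mean sequencing depth per sample (expected
#'   total counts scale).
#' @param library_size_cv Coefficient of variation of the lognormal library
#'   sizes.
#' @param nb_dispersion Negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param latent_sd Standard deviation of the latent log-scale biological
#'   signal of module genes.
#' @param background_latent_sd Latent log-scale standard deviation of
#'   background genes (smaller, as most of the transcriptome varies less
#'   than disease-driven programs).
#' @param base_mean_module Relative baseline abundance of module genes.
#' @param background_mean,background_sdlog Lognormal abundance profile of
#'   background genes; their large aggregate mass keeps each module a small
#'   fraction of the library, as in real transcriptomes, so compositional
#'   normalisation does not erode planted correlations.
#' @param fold_change Disease/control fold change applied to module genes
#'   (multiplied for "over", divided for "under" genes).
#' @param seed Integer seed; identical configs with identical seeds produce
#'   byte-identical output.
#' @return A `sim_config` list with resolved module gene ids.
#' @export
sim_config <- function(n_genes, cohorts, modules = list(),
                       library_size_mean = 2e6, library_size_cv = 0.3,
                       nb_dispersion = 0.05, latent_sd = 1,
                       background_latent_sd = 0.4,
                       base_mean_module = 300, background_mean = 3000,
                       background_sdlog = 0.5, fold_change = 2,
                       seed = 1L) {
  if (length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    abort("`seed` must be a single integer")
  }
  cohorts <- tibble::as_tibble(cohorts)
  if (!all(c("name", "n_disease", "n_control") %in% names(cohorts))) {
    abort("`cohorts` needs columns name, n_disease, n_control")
  }
  if (any(cohorts$n_disease < 3) || any(cohorts$n_control < 3)) {
    abort("all cohort arms need at least 3 samples")
  }
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive")
  if (inherits(modules, "planted_module")) modules <- list(modules)
  sizes <- vapply(modules, `[[`, numeric(1), "n_genes")
  if (sum(sizes) > n_genes) {
    abort("planted module sizes exceed `n_genes`")
  }
  ids <- sprintf("gene_%05d", seq_len(n_genes))
  offset <- 0L
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    if (is.null(m$genes)) {
      modules[[i]]$genes <- ids[(offset + 1L):(offset + m$n_genes)]
    } else if (!all(m$genes %in% ids)) {
      abort("explicit module gene ids must belong to the universe")
    }
    offset <- offset + m$n_genes
    if (is.null(m$cohorts)) modules[[i]]$cohorts <- cohorts$name
  }
  mids <- vapply(modules, `[[`, character(1), "module_id")
  if (anyDuplicated(mids)) abort("module ids must be unique")
  structure(list(
    n_genes = n_genes, gene_ids = ids, cohorts = cohorts, modules = modules,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    nb_dispersion = nb_dispersion, latent_sd = latent_sd,
    background_latent_sd = background_latent_sd,
    base_mean_module = base_mean_module, background_mean = background_mean,
    background_sdlog = background_sdlog, fold_change = fold_change,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Map a per-gene factor loading to the Spearman correlation expected between
# two member genes after the count observation layer. The latent pair is
# bivariate Gaussian with Pearson correlation a^2, attenuated by (i) the
# observation noise variance v (delta-method: Var(log NB(mu)) ~ 1/mu + disp)
# and (ii) the compositional weight w of the module in the library (CPM
# normalisation subtracts the library total, which carries a fraction w of
# the module factor, shrinking the effective loading to a(1 - w)). The
# Gaussian Pearson-to-Spearman map is (6/pi) asin(rho/2).
loading_to_spearman <- function(a, latent_sd, noise_var, comp_weight = 0) {
  rho <- a^2 * (1 - comp_weight)^2 * latent_sd^2 / (latent_sd^2 + noise_var)
  (6 / pi) * asin(rho / 2)
}

# Invert the loading map numerically (solved once per module and arm).
calibrate_loading <- function(r2_target, latent_sd, noise_var,
                              comp_weight = 0) {
  if (r2_target <= 0) return(0)
  target <- sqrt(r2_target)
  f <- function(a) {
    loading_to_spearman(a, latent_sd, noise_var, comp_weight) - target
  }
  if (f(1) < 0) {
    warn("r2 target unreachable at this depth/dispersion; loading clipped to 1")
    return(1)
  }
  stats::uniroot(f, c(0, 1), tol = 1e-9)$root
}

#' Generate synthetic multi-cohort count data with planted structure
#'
#' Simulates genes x samples count matrices for every cohort in the design.
#' Each planted module is driven by one per-sample latent factor per arm;
#' member loadings are calibrated numerically so the realised median pairwise
#' squared Spearman correlation approaches the module's `r2_disease` /
#' `r2_control` targets as the sample size grows. Background genes are
#' mutually independent. Counts are negative binomial around a lognormal
#' latent mean scaled by lognormal library sizes.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (integer matrix, genes x all samples),
#'   `sample_meta` (tibble: sample_id, cohort, condition, tissue, age,
#'   seizure_frequency), and `truth` (a `ground_truth` list recording module
#'   assignments, per-module r2 targets, calibrated loadings, the
#'   regulator-to-module and pathway-to-module maps).
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_genes = 60,
#'   cohorts = data.frame(name = "A", n_disease = 10, n_control = 10),
#'   modules = list(planted_module("m1", n_genes = 10, r2_disease = 0.8)),
#'   seed = 7
#' )
#' sim <- generate_cohorts(cfg)
#' dim(sim$counts)
generate_cohorts <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  set.seed(config$seed)
  n_genes <- config$n_genes
  ids <- config$gene_ids
  s <- config$latent_sd
  disp <- config$nb_dispersion

  module_of <- rep(NA_character_, n_genes)
  dir_of <- rep("over", n_genes)
  names(module_of) <- names(dir_of) <- ids
  for (m in config$modules) {
    module_of[m$genes] <- m$module_id
    dir_of[m$genes] <- m$direction
  }
  is_bg <- is.na(module_of)

  # relative baseline abundances; the background carries most of the library
  # mass so each module stays a small fraction of the transcriptome
  base <- numeric(n_genes)
  base[!is_bg] <- config$base_mean_module *
    rlnorm(sum(!is_bg), meanlog = 0, sdlog = 0.2)
  base[is_bg] <- rlnorm(sum(is_bg), meanlog = log(config$background_mean),
                        sdlog = config$background_sdlog)

  # observation-noise variance at the expected depth of a module gene
  total_mass <- config$base_mean_module * sum(!is_bg) +
    config$background_mean * exp(config$background_sdlog^2 / 2) * sum(is_bg)
  expected_count <- config$library_size_mean *
    config$base_mean_module / total_mass
  noise_var_module <- exp(s^2) / expected_count + disp
  loadings <- lapply(config$modules, function(m) {
    fc_d <- ifelse(m$direction == "over", config$fold_change,
                   1 / config$fold_change)
    sgn <- ifelse(m$direction == "over", 1, -1)
    mass_d <- config$base_mean_module * sum(sgn * fc_d)
    mass_c <- config$base_mean_module * sum(sgn)
    w_d <- abs(mass_d) / (total_mass +
                            config$base_mean_module * sum(fc_d - 1))
    w_c <- abs(mass_c) / total_mass
    list(disease = calibrate_loading(m$r2_disease, s, noise_var_module, w_d),
         control = calibrate_loading(m$r2_control, s, noise_var_module, w_c))
  })
  names(loadings) <- vapply(config$modules, `[[`, character(1), "module_id")

  all_counts <- list()
  meta <- list()
  for (ci in seq_len(nrow(config$cohorts))) {
    co <- config$cohorts[ci, ]
    n_d <- co$n_disease
    n_c <- co$n_control
    n_s <- n_d + n_c
    cond <- c(rep("disease", n_d), rep("control", n_c))
    sample_ids <- sprintf("%s_%s_%02d", co$name,
                          ifelse(cond == "disease", "d", "c"),
                          c(seq_len(n_d), seq_len(n_c)))

    z <- matrix(rnorm(n_genes * n_s), n_genes, n_s,
                dimnames = list(ids, sample_ids))
    for (m in config$modules) {
      if (!co$name %in% m$cohorts) next
      a_d <- loadings[[m$module_id]]$disease
      a_c <- loadings[[m$module_id]]$control
      f <- rnorm(n_s)
      sgn <- ifelse(m$direction == "over", 1, -1)
      a <- ifelse(cond == "disease", a_d, a_c)
      idx <- m$genes
      # shared factor plus independent residual keeps each gene marginal N(0,1)
      z[idx, ] <- outer(sgn, a * f) +
        sweep(matrix(rnorm(length(idx) * n_s), length(idx), n_s), 2,
              sqrt(1 - a^2), `*`)
    }

    fc <- matrix(1, n_genes, n_s, dimnames = dimnames(z))
    for (m in config$modules) {
      if (!co$name %in% m$cohorts) next
      up <- m$genes[m$direction == "over"]
      dn <- m$genes[m$direction == "under"]
      fc[up, cond == "disease"] <- config$fold_change
      fc[dn, cond == "disease"] <- 1 / config$fold_change
    }

    sdlog_lib <- sqrt(log(1 + config$library_size_cv^2))
    lib <- rlnorm(n_s, log(config$library_size_mean) - sdlog_lib^2 / 2,
                  sdlog_lib)
    s_gene <- ifelse(is_bg, config$background_latent_sd, s)
    q <- base * fc * exp(s_gene * z - s_gene^2 / 2)
    # compositional scaling: each sample's expected total equals its library
    mu <- sweep(q, 2, lib / colSums(q), `*`)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / disp),
                     n_genes, n_s, dimnames = dimnames(z))

    all_counts[[co$name]] <- counts
    meta[[co$name]] <- tibble::tibble(
      sample_id = sample_ids, cohort = co$name, condition = cond,
      tissue = "cortex",
      age = round(runif(n_s, 5, 60), 1),
      seizure_frequency = ifelse(cond == "disease",
                                 round(rlnorm(n_s, log(10), 0.8), 1), NA_real_)
    )
  }

  truth <- structure(list(
    module_genes = setNames(lapply(config$modules, `[[`, "genes"),
                            names(loadings)),
    direction = setNames(lapply(config$modules, `[[`, "direction"),
                         names(loadings)),
    module_r2 = tibble::tibble(
      module_id = names(loadings),
      r2_disease = vapply(config$modules, `[[`, numeric(1), "r2_disease"),
      r2_control = vapply(config$modules, `[[`, numeric(1), "r2_control"),
      loading_disease = vapply(loadings, `[[`, numeric(1), "disease"),
      loading_control = vapply(loadings, `[[`, numeric(1), "control")
    ),
    module_cohorts = setNames(lapply(config$modules, `[[`, "cohorts"),
                              names(loadings)),
    regulator_map = purrr::compact(setNames(
      lapply(config$modules, function(m)
        if (is.null(m$regulator_tf)) NULL else
          list(tf = m$regulator_tf, sign = m$regulator_sign)),
      names(loadings))),
    pathway_map = purrr::compact(setNames(
      lapply(config$modules, `[[`, "pathway_label"), names(loadings))),
    gene_ids = ids,
    config = config
  ), class = "ground_truth")

  list(counts = do.call(cbind, all_counts),
       sample_meta = dplyr::bind_rows(meta),
       truth = truth)
}

#' Generate a synthetic signed regulatory knowledge base
#'
#' Builds a two-layer signed knowledge base (cell-membrane receptor -> TF ->
#' target gene) around the planted regulators of a simulated study: each
#' planted TF receives signed edges covering most of its module, one signed
#' upstream receptor edge, and the requested numbers of decoy TFs and decoy
#' receptors with random target sets of matched size.
#'
#' @param truth `ground_truth` from [generate_cohorts()].
#' @param n_decoy_tfs,n_decoy_cmps Numbers of decoy regulators.
#' @param seed Integer seed (offset internally so the stream does not collide
#'   with the cohort generator's).
#' @param coverage Fraction of module genes each planted TF targets.
#' @param sign_purity Fraction of a planted TF's module edges carrying its
#'   planted sign (the rest are "unspecified").
#' @return A `knowledge_base` object (see [knowledge_base()]).
#' @export
generate_knowledge_base <- function(truth, n_decoy_tfs = 0, n_decoy_cmps = 0,
                                    seed = 1L, coverage = 0.9,
                                    sign_purity = 0.9) {
  if (!inherits(truth, "ground_truth")) abort("`truth` must be a ground_truth")
  if (length(truth$module_genes) == 0) abort("empty ground truth")
  set.seed(derive_seed(seed, "knowledge_base"))
  ids <- truth$gene_ids
  effects <- c("activation", "inhibition", "unspecified")

  tf_rows <- list()
  cmp_rows <- list()
  planted_sizes <- integer(0)
  for (mid in names(truth$regulator_map)) {
    reg <- truth$regulator_map[[mid]]
    genes <- truth$module_genes[[mid]]
    n_cov <- max(2L, ceiling(coverage * length(genes)))
    targets <- sort(sample(genes, n_cov))
    eff <- rep(reg$sign, n_cov)
    n_flip <- floor((1 - sign_purity) * n_cov)
    if (n_flip > 0) eff[sample(n_cov, n_flip)] <- "unspecified"
    # a few off-module targets so planted target sets are not module subsets
    extra <- sample(setdiff(ids, genes), max(1L, round(0.1 * n_cov)))
    tf_rows[[mid]] <- tibble::tibble(
      regulator_id = reg$tf, regulator_class = "TF",
      target_id = c(targets, extra),
      effect = c(eff, sample(effects, length(extra), replace = TRUE))
    )
    cmp_rows[[mid]] <- tibble::tibble(
      cmp_id = paste0("CMP_", reg$tf), tf_id = reg$tf, effect = "activation"
    )
    planted_sizes <- c(planted_sizes, n_cov)
  }
  if (length(planted_sizes) == 0) planted_sizes <- 25L

  all_tfs <- vapply(truth$regulator_map, function(r) r$tf, character(1))
  if (n_decoy_tfs > 0) {
    for (i in seq_len(n_decoy_tfs)) {
      sz <- sample(planted_sizes, 1L)
      tf_rows[[paste0("decoy_tf_", i)]] <- tibble::tibble(
        regulator_id = sprintf("TF_decoy_%03d", i), regulator_class = "TF",
        target_id = sort(sample(ids, sz)),
        effect = sample(effects, sz, replace = TRUE)
      )
    }
    all_tfs <- c(all_tfs, sprintf("TF_decoy_%03d", seq_len(n_decoy_tfs)))
  }
  if (n_decoy_cmps > 0) {
    for (i in seq_len(n_decoy_cmps)) {
      k <- sample(1:3, 1L)
      cmp_rows[[paste0("decoy_cmp_", i)]] <- tibble::tibble(
        cmp_id = sprintf("CMP_decoy_%03d", i),
        tf_id = sample(all_tfs, min(k, length(all_tfs))),
        effect = sample(effects, min(k, length(all_tfs)), replace = TRUE)
      )
    }
  }
  knowledge_base(dplyr::bind_rows(tf_rows), dplyr::bind_rows(cmp_rows))
}

#' Generate synthetic pathway gene-set collections
#'
#' Each planted pathway label becomes a gene set covering its module plus a
#' padding of random non-member genes; decoy sets are random draws from the
#' gene universe.
#'
#' @param truth `ground_truth` from [generate_cohorts()].
#' @param n_decoy_sets Number of random decoy sets.
#' @param seed Integer seed (namespaced internally).
#' @param noise_frac Fraction of a planted set's module size added as random
#'   non-member padding genes.
#' @param decoy_size Either a single set size or a `c(min, max)` range for
#'   decoy sets.
#' @return A named list of character vectors with class
#'   `gene_set_collection` (writable with [write_gmt()]).
#' @export
generate_genesets <- function(truth, n_decoy_sets = 0, seed = 1L,
                              noise_frac = 0.2, decoy_size = c(20, 80)) {
  if (!inherits(truth, "ground_truth")) abort("`truth` must be a ground_truth")
  set.seed(derive_seed(seed, "genesets"))
  ids <- truth$gene_ids
  sets <- list()
  for (mid in names(truth$pathway_map)) {
    genes <- truth$module_genes[[mid]]
    n_noise <- round(noise_frac * length(genes))
    noise <- if (n_noise > 0) sample(setdiff(ids, genes), n_noise) else
      character(0)
    sets[[truth$pathway_map[[mid]]]] <- c(genes, noise)
  }
  if (n_decoy_sets > 0) {
    for (i in seq_len(n_decoy_sets)) {
      sz <- if (length(decoy_size) == 1) decoy_size else
        sample(decoy_size[1]:decoy_size[2], 1L)
      sets[[sprintf("decoy_set_%03d", i)]] <- sort(sample(ids, sz))
    }
  }
  structure(sets, class = "gene_set_collection",
            descriptions = setNames(rep("synthetic", length(sets)),
                                    names(sets)))
}
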