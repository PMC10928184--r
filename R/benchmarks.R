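# Simulation benchmarks: each one plants known structure with the
# synthetic-data generator, runs the corresponding stage of the pipeline,
# and scores recovery against the ground truth. They back both the
# validation tests and the reproducibility script.

#' Benchmark: recovery of planted coexpression modules
#'
#' Runs the full discovery pipeline (preprocessing, MAD filter, Spearman
#' soft-thresholded adjacency, Ward clustering with inflection-point K
#' selection, leave-one-out stability, junk removal, consensus modules, o/u
#' splitting) on studies with four planted modules (25-50 genes, target
#' within-module r2 = 0.7) over 200 background genes, with 30 disease and 30
#' control samples, and scores the final partition against the planted one
#' by adjusted Rand index.
#'
#' @param n_runs Number of independently seeded studies.
#' @param seed Base seed.
#' @return Tibble: run, ari.
#' @export
benchmark_module_recovery <- function(n_runs = 20, seed = 1L) {
  rows <- purrr::map(seq_len(n_runs), function(i) {
    run_seed <- derive_seed(seed, paste0("recovery:", i))
    cfg <- sim_config(
      n_genes = 345,
      cohorts = data.frame(name = "A", n_disease = 30, n_control = 30),
      modules = list(
        planted_module("m1", n_genes = 25, r2_disease = 0.7,
                       r2_control = 0.1),
        planted_module("m2", n_genes = 30, r2_disease = 0.7,
                       r2_control = 0.1),
        planted_module("m3", n_genes = 40, r2_disease = 0.7,
                       r2_control = 0.1),
        planted_module("m4", n_genes = 50, r2_disease = 0.7,
                       r2_control = 0.1)),
      seed = run_seed)
    sim <- generate_cohorts(cfg)
    study <- preprocess_study(sim$counts, sim$sample_meta)
    ms <- suppressWarnings(discover_modules(study, "A"))
    truth <- rep("background", length(cfg$gene_ids))
    names(truth) <- cfg$gene_ids
    for (m in cfg$modules) truth[m$genes] <- m$module_id
    pred <- rep("junk", length(cfg$gene_ids))
    names(pred) <- cfg$gene_ids
    pred[ms$modules$gene_id] <- sub("[.][ou]$", "", ms$modules$module_id)
    common <- rownames(study$expr)
    tibble::tibble(run = i, ari = adjusted_rand(truth[common], pred[common]))
  })
  dplyr::bind_rows(rows)
}

#' Benchmark: type-I error of the differential coexpression test
#'
#' Generates module-free two-arm studies (both arms share one data-generating
#' process), draws random 30-gene "modules", and measures how often the
#' two-sided permutation test rejects at the given level. The modules are
#' spread over several independently generated studies: modules drawn from
#' one study share samples and genes, so their test outcomes are correlated
#' and a single-study rejection rate is a high-variance estimate of the
#' test's level.
#'
#' @param n_modules Total number of random modules tested.
#' @param n_studies Number of independent studies the modules are spread
#'   over.
#' @param n_perm Permutations per test.
#' @param alpha Nominal level.
#' @param seed Base seed.
#' @return Tibble: study, module, p_empirical, rejected.
#' @export
benchmark_dc_null <- function(n_modules = 200, n_studies = 10, n_perm = 500,
                              alpha = 0.05, seed = 1L) {
  per_study <- ceiling(n_modules / n_studies)
  rows <- purrr::map(seq_len(n_studies), function(s) {
    cfg <- sim_config(
      n_genes = 330,
      cohorts = data.frame(name = "A", n_disease = 30, n_control = 30),
      seed = derive_seed(seed, paste0("dc_null:", s)))
    sim <- generate_cohorts(cfg)
    study <- preprocess_study(sim$counts, sim$sample_meta)
    cond <- study$sample_meta$condition
    genes <- rownames(study$expr)
    set.seed(derive_seed(seed, paste0("dc_null_draws:", s)))
    purrr::map(seq_len(per_study), function(i) {
      g <- sample(genes, 30)
      res <- diff_coexpression_test(study$expr, cond, genes = g,
                                    module_id = sprintf("null_%d_%d", s, i),
                                    n_perm = n_perm, seed = seed)
      tibble::tibble(study = s, module = i,
                     p_empirical = res$p_empirical,
                     rejected = res$p_empirical < alpha)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)[seq_len(n_modules), ]
}

#' Benchmark: power of the differential coexpression test
#'
#' Plants a 30-gene module with target r2 0.6 in disease and 0.1 in control
#' samples (delta 0.5) at 30 samples per arm and measures the rejection rate
#' of the permutation test over independently seeded replicates.
#'
#' @param n_reps Number of replicates.
#' @param n_perm Permutations per test.
#' @param alpha Nominal level.
#' @param seed Base seed.
#' @return Tibble: rep, delta_hat, p_empirical, rejected.
#' @export
benchmark_dc_power <- function(n_reps = 50, n_perm = 500, alpha = 0.05,
                               seed = 1L) {
  rows <- purrr::map(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_genes = 260,
      cohorts = data.frame(name = "A", n_disease = 30, n_control = 30),
      modules = list(planted_module("m", n_genes = 30, r2_disease = 0.6,
                                    r2_control = 0.1)),
      seed = derive_seed(seed, paste0("dc_power:", i)))
    sim <- generate_cohorts(cfg)
    study <- preprocess_study(sim$counts, sim$sample_meta)
    res <- diff_coexpression_test(study$expr, study$sample_meta$condition,
                                  genes = cfg$modules[[1]]$genes,
                                  module_id = paste0("power_", i),
                                  n_perm = n_perm, seed = seed)
    tibble::tibble(rep = i, delta_hat = res$delta_r2,
                   p_empirical = res$p_empirical,
                   rejected = res$p_empirical < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Benchmark: upstream-regulator recovery against decoys
#'
#' Plants one transcription factor over a 30-gene module, adds 50 decoy TFs
#' with matched target-set sizes, and checks per replicate whether the
#' planted TF attains the best FDR for its module.
#'
#' @param n_reps Number of knowledge-base replicates.
#' @param n_decoys Decoy TFs per replicate.
#' @param seed Base seed.
#' @return Tibble: rep, best_regulator, hit.
#' @export
benchmark_regulator_recovery <- function(n_reps = 100, n_decoys = 50,
                                         seed = 1L) {
  cfg <- sim_config(
    n_genes = 345,
    cohorts = data.frame(name = "A", n_disease = 3, n_control = 3),
    modules = list(planted_module("m1", n_genes = 30,
                                  regulator_tf = "TF_planted",
                                  regulator_sign = "activation")),
    seed = derive_seed(seed, "craft_truth"))
  truth <- generate_cohorts(cfg)$truth
  rows <- purrr::map(seq_len(n_reps), function(i) {
    kb <- generate_knowledge_base(truth, n_decoy_tfs = n_decoys,
                                  seed = derive_seed(seed,
                                                     paste0("craft:", i)))
    res <- predict_regulators(list(m1 = truth$module_genes$m1), kb,
                              truth$gene_ids)
    # the planted receptor relaying the planted TF shares its target set;
    # the decoy competition is among TF-class regulators
    tfs <- res[res$regulator_class == "TF", ]
    best <- tfs$regulator_id[which.min(tfs$fdr)]
    tibble::tibble(rep = i, best_regulator = best,
                   hit = best == "TF_planted")
  })
  dplyr::bind_rows(rows)
}

#' Benchmark: four-class regulome classification
#'
#' Plants one regulome of each class across two cohorts (40 disease + 40
#' control samples each): a constitutive program (equally coexpressed in
#' disease and control), an enhanced program (coexpressed in controls,
#' stronger in disease), an activated program (coexpressed only in disease),
#' and a pathology-specific program (present in one cohort only). Runs
#' differential-coexpression and control-tissue conservation tests on the
#' planted memberships, clusters module instances by inclusion index, and
#' checks that every planted family receives its intended class label.
#'
#' The per-test level defaults to 0.005: each class decision aggregates
#' several member-level hypothesis tests, so a stricter per-test level keeps
#' the joint four-label decision reliable (roughly a Bonferroni correction of
#' 0.05 over the ~7 member tests consulted per study).
#'
#' @param n_reps Number of replicates.
#' @param n_perm Permutations per differential-coexpression / conservation
#'   test.
#' @param alpha Per-test significance level for the class rules.
#' @param seed Base seed.
#' @return Tibble: rep, all_recovered, plus one column per planted class with
#'   the label it received.
#' @export
benchmark_regulome_classes <- function(n_reps = 50, n_perm = 300,
                                       alpha = 0.005, seed = 1L) {
  families <- list(
    constitutive = list(r2_d = 0.6, r2_c = 0.6, cohorts = c("A", "B")),
    enhanced = list(r2_d = 0.75, r2_c = 0.3, cohorts = c("A", "B")),
    activated = list(r2_d = 0.75, r2_c = 0, cohorts = c("A", "B")),
    pathology_specific = list(r2_d = 0.75, r2_c = 0, cohorts = "A"))
  rows <- purrr::map(seq_len(n_reps), function(i) {
    rep_seed <- derive_seed(seed, paste0("classes:", i))
    cfg <- sim_config(
      n_genes = 320,
      cohorts = data.frame(name = c("A", "B"), n_disease = c(40, 40),
                           n_control = c(40, 40)),
      modules = purrr::imap(families, function(f, nm) {
        planted_module(nm, n_genes = 30, r2_disease = f$r2_d,
                       r2_control = f$r2_c, cohorts = f$cohorts)
      }),
      seed = rep_seed)
    sim <- generate_cohorts(cfg)
    study <- preprocess_study(sim$counts, sim$sample_meta)
    truth <- sim$truth

    # module instances: the planted memberships per cohort where planted
    mods <- list()
    cohorts_of <- character(0)
    for (fam in names(families)) {
      for (co in families[[fam]]$cohorts) {
        mid <- sprintf("%s.%s.o", co, fam)
        mods[[mid]] <- truth$module_genes[[fam]]
        cohorts_of[mid] <- co
      }
    }
    dcx <- purrr::imap(mods, function(genes, mid) {
      co <- cohorts_of[mid]
      samples <- study_samples(study, co)
      cond <- study$sample_meta$condition[
        match(samples, study$sample_meta$sample_id)]
      diff_coexpression_test(study$expr[, samples], cond, genes = genes,
                             module_id = mid, n_perm = n_perm,
                             seed = rep_seed)
    }) |> dplyr::bind_rows()
    cons <- purrr::imap(mods, function(genes, mid) {
      co <- cohorts_of[mid]
      ctl <- study_samples(study, co, "control")
      conservation_test(study$expr[, ctl], genes, module_id = mid,
                        target_cohort = paste0(co, "_control"),
                        is_control = TRUE, n_perm = n_perm, seed = rep_seed,
                        alpha = alpha)
    }) |> dplyr::bind_rows()
    rs <- build_regulomes(mods, cohorts_of, dcx, cons, alpha = alpha)
    got <- vapply(names(families), function(fam) {
      rid <- rs$assignments$regulome_id[
        rs$assignments$module_id == sprintf("%s.%s.o", "A", fam)]
      rs$regulomes$class[rs$regulomes$regulome_id == rid]
    }, character(1))
    out <- tibble::as_tibble(as.list(got))
    out$rep <- i
    out$all_recovered <- all(got == names(families))
    out
  })
  dplyr::bind_rows(rows)
}
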