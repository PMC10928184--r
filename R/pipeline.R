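#' Load and validate a pipeline configuration
#'
#' Configurations are nested YAML (or an equivalent R list): either a
#' `simulate` block describing a synthetic study, or an `inputs` block with
#' paths to counts/metadata/GMT/knowledge-base files, plus optional per-stage
#' parameter blocks (`preprocess`, `modules`, `dcx`, `conservation`,
#' `craft`, `regulome`, `structure`) and a global `seed`. Missing stage
#' parameters are filled with package defaults; referenced files must exist;
#' if the `craft` stage is enabled a knowledge-base source must be available.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML path or a list")
  defaults <- list(
    preprocess = list(min_count = 6, min_fraction = 0.2, scope = "each"),
    modules = list(beta = 6, mad_min = 0.25, k_min = 1, k_max = 200,
                   smooth_window = 1, min_samples = 21,
                   junk_fraction = 0.5),
    dcx = list(n_perm = 1000, alpha = 0.05),
    conservation = list(n_perm = 1000, alpha = 0.05),
    craft = list(enabled = TRUE, min_targets = 3),
    regulome = list(alpha = 0.05, cross_cohort_ii_min = 0.3, k_cap = 40),
    structure = list(enabled = TRUE, n_pcs = NULL)
  )
  for (nm in names(defaults)) {
    config[[nm]] <- utils::modifyList(defaults[[nm]],
                                      as.list(config[[nm]] %||% list()))
  }
  config$seed <- config$seed %||% 1L
  if (length(config$seed) != 1 || config$seed != round(config$seed)) {
    abort("seed must be a single integer")
  }
  has_sim <- !is.null(config$simulate)
  if (!has_sim) {
    inp <- config$inputs
    if (is.null(inp$counts) || is.null(inp$metadata)) {
      abort("config needs either a `simulate` block or inputs$counts + inputs$metadata")
    }
    for (f in unlist(inp)) {
      if (!file.exists(f)) abort(sprintf("input file not found: %s", f))
    }
    if (isTRUE(config$craft$enabled) && is.null(inp$kb)) {
      abort("craft stage enabled but no knowledge-base path configured")
    }
  }
  structure(config, class = c("pipeline_config", "list"))
}

log_line <- function(stage, msg, logfile = NULL, verbose = TRUE) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  if (verbose) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

sim_config_from_block <- function(block, seed) {
  mods <- lapply(block$modules, function(m) {
    do.call(planted_module, m)
  })
  sim_config(
    n_genes = block$n_genes,
    cohorts = dplyr::bind_rows(lapply(block$cohorts, tibble::as_tibble)),
    modules = mods,
    library_size_mean = block$library_size_mean %||% 2e6,
    library_size_cv = block$library_size_cv %||% 0.3,
    nb_dispersion = block$nb_dispersion %||% 0.05,
    seed = block$seed %||% seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate (or load inputs), preprocess,
#' per-cohort module discovery, differential coexpression and conservation,
#' gene-set enrichment, upstream-regulator prediction, regulome integration,
#' sample-structure analysis, and a per-cohort summary report. Every stage
#' writes its tabular artifacts into `outdir`; a manifest records each file
#' with its MD5 checksum and row count, so reruns with the same
#' configuration and seed can be verified to be bit-identical. A failing
#' stage aborts with the stage named and leaves a `FAILED` marker next to
#' the partial outputs.
#'
#' @param config A [pipeline_config()] (or path / list coercible to one).
#' @param outdir Output directory (created if missing).
#' @param seed Optional override of the configured global seed.
#' @param verbose Log progress to stderr.
#' @return The manifest tibble, invisibly; all artifacts are on disk.
#' @export
run_pipeline <- function(config, outdir, seed = NULL, verbose = TRUE) {
  config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  if (file.exists(logfile)) unlink(logfile)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  artifacts <- character(0)
  rowcounts <- integer(0)
  emit <- function(x, name, writer = write_tsv_plain) {
    path <- file.path(outdir, name)
    writer(x, path)
    artifacts <<- c(artifacts, path)
    rowcounts <<- c(rowcounts, if (is.data.frame(x)) nrow(x) else NA_integer_)
    path
  }
  stage <- function(name, fn) {
    log_line(name, "start", logfile, verbose)
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 failed_marker)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- inputs -------------------------------------------------------------
  kb <- NULL; gmt <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", function() {
      cfg <- sim_config_from_block(config$simulate, config$seed)
      out <- generate_cohorts(cfg)
      emit(out$counts, "counts.tsv", write_counts)
      emit(out$sample_meta, "sample_meta.tsv", write_metadata)
      emit(out$truth, "ground_truth.json", write_ground_truth)
      out
    })
    counts <- sim$counts; meta <- sim$sample_meta; truth <- sim$truth
    if ((config$simulate$n_decoy_tfs %||% 0) >= 0 &&
        length(truth$regulator_map) > 0) {
      kb <- generate_knowledge_base(truth,
                                    n_decoy_tfs = config$simulate$n_decoy_tfs %||% 0,
                                    n_decoy_cmps = config$simulate$n_decoy_cmps %||% 0,
                                    seed = config$seed)
      emit(kb, "knowledge_base.tsv", write_kb)
    }
    if (length(truth$pathway_map) > 0 ||
        (config$simulate$n_decoy_sets %||% 0) > 0) {
      gmt <- generate_genesets(truth,
                               n_decoy_sets = config$simulate$n_decoy_sets %||% 0,
                               seed = config$seed)
      emit(gmt, "gene_sets.gmt", write_gmt)
    }
  } else {
    counts <- read_counts(config$inputs$counts)
    meta <- read_metadata(config$inputs$metadata, counts)
    if (!is.null(config$inputs$kb)) kb <- read_kb(config$inputs$kb)
    if (!is.null(config$inputs$gmt)) gmt <- read_gmt(config$inputs$gmt)
  }

  # --- preprocess ---------------------------------------------------------
  study <- stage("preprocess", function() {
    st <- preprocess_study(counts, meta,
                           min_count = config$preprocess$min_count,
                           min_fraction = config$preprocess$min_fraction,
                           scope = config$preprocess$scope)
    emit(data.frame(gene_id = rownames(st$expr), round(st$expr, 6),
                    check.names = FALSE), "expression_log2.tsv")
    emit(st$provenance$filter_report, "filter_report.tsv")
    st
  })

  # --- module discovery ---------------------------------------------------
  pm <- config$modules
  cohort_sizes <- table(study$sample_meta$cohort[
    study$sample_meta$condition == "disease"])
  eligible <- names(cohort_sizes)[cohort_sizes >= pm$min_samples]
  skipped <- setdiff(names(cohort_sizes), eligible)
  if (length(skipped) > 0) {
    log_line("modules",
             sprintf("cohort(s) below the >%d-sample gate skipped: %s",
                     pm$min_samples - 1, paste(skipped, collapse = ", ")),
             logfile, verbose)
  }
  module_sets <- stage("modules", function() {
    ms <- lapply(eligible, function(co) {
      discover_modules(study, co, beta = pm$beta, mad_min = pm$mad_min,
                       k_min = pm$k_min, k_max = pm$k_max,
                       smooth_window = pm$smooth_window,
                       junk_fraction = pm$junk_fraction,
                       min_samples = pm$min_samples)
    })
    names(ms) <- eligible
    all_mod <- dplyr::bind_rows(lapply(ms, `[[`, "modules"))
    emit(all_mod, "modules.tsv", write_modules)
    emit(dplyr::bind_rows(lapply(ms, `[[`, "summary")), "module_summary.tsv")
    ms
  })
  if (length(module_sets) == 0) abort("no cohort passed the sample gate")

  # --- differential coexpression & conservation ---------------------------
  dcx <- stage("dcx", function() {
    tab <- dplyr::bind_rows(lapply(module_sets, function(ms) {
      coexpression_stats(ms, study, n_perm = config$dcx$n_perm,
                         seed = config$seed, alpha = config$dcx$alpha)
    }))
    emit(tab, "coexpression_stats.tsv")
    tab
  })
  conservation <- stage("conservation", function() {
    rows <- list()
    for (ms in module_sets) {
      sets <- module_gene_sets(ms)
      for (target in names(cohort_sizes)) {
        dis <- study_samples(study, target, "disease")
        ctl <- study_samples(study, target, "control")
        for (mid in names(sets)) {
          if (target != ms$cohort && length(dis) >= 4) {
            rows[[paste(mid, target, "d")]] <- conservation_test(
              study$expr[, dis, drop = FALSE], sets[[mid]], module_id = mid,
              target_cohort = target, is_control = FALSE,
              n_perm = config$conservation$n_perm, seed = config$seed,
              alpha = config$conservation$alpha)
          }
          if (length(ctl) >= 4) {
            rows[[paste(mid, target, "c")]] <- conservation_test(
              study$expr[, ctl, drop = FALSE], sets[[mid]], module_id = mid,
              target_cohort = paste0(target, "_control"), is_control = TRUE,
              n_perm = config$conservation$n_perm, seed = config$seed,
              alpha = config$conservation$alpha)
          }
        }
      }
    }
    tab <- dplyr::bind_rows(rows)
    emit(tab, "conservation.tsv")
    tab
  })

  # --- enrichment ---------------------------------------------------------
  enrich <- NULL
  if (!is.null(gmt)) {
    enrich <- stage("enrich", function() {
      queries <- unlist(lapply(module_sets, module_gene_sets),
                        recursive = FALSE)
      names(queries) <- sub("^[^.]*\\.", "", names(queries))
      tab <- annotate_genesets(queries, list(pathways = gmt),
                               universe = rownames(study$expr))
      emit(tab, "enrichment.tsv")
      tab
    })
  }

  # --- craft --------------------------------------------------------------
  craft_tab <- NULL
  if (isTRUE(config$craft$enabled) && !is.null(kb)) {
    craft_tab <- stage("craft", function() {
      # synthetic knowledge bases label regulators outside the assay
      # namespace; simulated runs therefore only enforce target expression
      kbx <- restrict_to_expressed(
        kb, rownames(study$expr),
        require_regulator_expressed = is.null(config$simulate))
      queries <- unlist(lapply(module_sets, module_gene_sets),
                        recursive = FALSE)
      names(queries) <- sub("^[^.]*\\.", "", names(queries))
      tab <- predict_regulators(queries, kbx,
                                universe = rownames(study$expr),
                                min_targets = config$craft$min_targets)
      emit(tab, "regulator_predictions.tsv")
      tab
    })
  }

  # --- regulome -----------------------------------------------------------
  regs <- stage("regulome", function() {
    mods <- unlist(lapply(module_sets, module_gene_sets), recursive = FALSE)
    names(mods) <- sub("^[^.]*\\.", "", names(mods))
    if (length(mods) < 3) {
      log_line("regulome", "fewer than 3 modules; stage skipped",
               logfile, verbose)
      return(NULL)
    }
    cohorts_of <- setNames(sub("\\..*$", "", names(mods)), names(mods))
    rs <- build_regulomes(mods, cohorts_of, dcx, conservation,
                          alpha = config$regulome$alpha,
                          cross_cohort_ii_min = config$regulome$cross_cohort_ii_min,
                          k_cap = config$regulome$k_cap)
    emit(dplyr::left_join(rs$assignments, rs$regulomes, by = "regulome_id"),
         "regulomes.tsv")
    rs
  })

  # --- sample structure ---------------------------------------------------
  if (isTRUE(config$structure$enabled)) {
    stage("structure", function() {
      # cohort x condition grouping keeps DAPC defined for one-cohort studies
      groups <- paste(study$sample_meta$cohort, study$sample_meta$condition,
                      sep = "_")
      max_pcs <- ncol(study$expr) - dplyr::n_distinct(groups) - 1
      np <- config$structure$n_pcs %||% max(2L, min(10L, max_pcs))
      dr <- dapc(study$expr, groups, n_pcs = np)
      emit(as.data.frame.matrix(dr$reassignment) |>
             (\(d) data.frame(prior = rownames(d), d,
                              check.names = FALSE))(),
           "dapc_reassignment.tsv")
      emit(data.frame(sample_id = colnames(study$expr), dr$posterior,
                      check.names = FALSE), "dapc_posterior.tsv")
      dr
    })
  }

  # --- report -------------------------------------------------------------
  stage("report", function() {
    rep <- purrr::map(module_sets, function(ms) {
      co <- ms$cohort
      mods <- unique(ms$modules$module_id)
      dc <- dcx[dcx$cohort == co, ]
      ann <- if (is.null(enrich)) NA_integer_ else {
        sig <- enrich[enrich$fdr < 0.05 & enrich$query_id %in% mods, ]
        dplyr::n_distinct(sig$query_id)
      }
      nreg <- if (is.null(craft_tab)) NA_integer_ else {
        sig <- craft_tab[craft_tab$fdr < 0.05 &
                           craft_tab$module_id %in% mods, ]
        dplyr::n_distinct(sig$regulator_id)
      }
      tibble::tibble(cohort = co, n_modules = length(mods),
                     n_dc_modules = sum(dc$significant),
                     n_annotated_modules = ann, n_regulators = nreg)
    })
    emit(dplyr::bind_rows(rep), "report.tsv")
    NULL
  })

  # --- manifest -----------------------------------------------------------
  cfg_path <- file.path(outdir, "config_used.yaml")
  cfg_clean <- unclass(config)
  yaml::write_yaml(cfg_clean, cfg_path)
  manifest <- tibble::tibble(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    n_rows = rowcounts
  ) |> dplyr::arrange(.data$file)
  manifest <- dplyr::bind_rows(
    tibble::tibble(file = "config_used.yaml",
                   md5 = unname(tools::md5sum(cfg_path)),
                   n_rows = NA_integer_),
    manifest)
  write_tsv_plain(manifest, file.path(outdir, "manifest.tsv"))
  log_line("done", sprintf("%d artifacts written to %s", nrow(manifest),
                           outdir), logfile, verbose)
  invisible(manifest)
}

#' Cohort sizes of the motivating clinical study
#'
#' Sample counts per cohort of the drug-resistant epilepsy study that
#' motivates the pipeline: two control tissues and four epilepsy pathologies
#' (temporal lobe epilepsy with hippocampal sclerosis, focal cortical
#' dysplasia IIa/IIb, and tuberous sclerosis complex cortical tubers).
#'
#' @return Tibble with `cohort`, `role` (control/epilepsy) and `n_samples`.
#' @export
study_cohort_sizes <- function() {
  path <- system.file("extdata", "study_cohort_sizes.tsv",
                      package = "regulomix", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path))
}
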