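test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(
    n_genes = 80,
    cohorts = data.frame(name = c("A", "B"), n_disease = c(6, 5),
                         n_control = c(5, 6)),
    modules = list(planted_module("m1", n_genes = 10)),
    seed = 7)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sample_meta, b$sample_meta)
})

test_that("configuration violations are rejected", {
  co <- data.frame(name = "A", n_disease = 5, n_control = 5)
  expect_error(sim_config(10, co, list(planted_module("m", n_genes = 20))),
               "exceed")
  expect_error(sim_config(100, co, seed = 1.5), "integer")
  expect_error(sim_config(100, co, nb_dispersion = 0), "positive")
  expect_error(
    sim_config(100, data.frame(name = "A", n_disease = 2, n_control = 5)),
    "at least 3")
  expect_error(planted_module("m", n_genes = 1), "at least 2")
  expect_error(planted_module("m", n_genes = 5, r2_disease = 1.2), "\\[0, 1\\]")
})

test_that("background genes are uncorrelated in a module-free study", {
  cfg <- sim_config(
    n_genes = 150,
    cohorts = data.frame(name = "A", n_disease = 40, n_control = 3),
    seed = 31)
  sim <- generate_cohorts(cfg)
  expr <- log_cpm(sim$counts)[, sim$sample_meta$condition == "disease"]
  rho <- cor(t(expr[1:50, ]), method = "spearman")
  offdiag <- abs(rho[upper.tri(rho)])
  expect_gt(length(offdiag), 1000)
  expect_lt(median(offdiag), 0.2)
})

test_that("planted r2 targets are realised within tolerance in each arm", {
  cfg <- sim_config(
    n_genes = 300,
    cohorts = data.frame(name = "A", n_disease = 100, n_control = 100),
    modules = list(planted_module("m1", n_genes = 30, r2_disease = 0.8,
                                  r2_control = 0.1)),
    seed = 17)
  sim <- generate_cohorts(cfg)
  study <- preprocess_study(sim$counts, sim$sample_meta)
  g <- cfg$modules[[1]]$genes
  dis <- study_samples <- sim$sample_meta$condition == "disease"
  r2_d <- median_pairwise_r2(study$expr[g, dis])
  r2_c <- median_pairwise_r2(study$expr[g, !dis])
  expect_lt(abs(r2_d - 0.8), 0.1)
  expect_lt(abs(r2_c - 0.1), 0.1)
})

test_that("raising the r2 target strictly raises realised coexpression", {
  cfg <- sim_config(
    n_genes = 400,
    cohorts = data.frame(name = "A", n_disease = 200, n_control = 3),
    modules = list(
      planted_module("lo", n_genes = 25, r2_disease = 0.2, r2_control = 0),
      planted_module("mid", n_genes = 25, r2_disease = 0.5, r2_control = 0),
      planted_module("hi", n_genes = 25, r2_disease = 0.8, r2_control = 0)),
    seed = 5)
  sim <- generate_cohorts(cfg)
  expr <- log_cpm(sim$counts,
                  tmm_normalize(sim$counts))[, sim$sample_meta$condition ==
                                               "disease"]
  realised <- vapply(cfg$modules, function(m) {
    median_pairwise_r2(expr[m$genes, ])
  }, numeric(1))
  expect_true(all(diff(realised) > 0))
})

test_that("library-size variation is recovered in the column sums", {
  for (cv in c(0.2, 0.3)) {
    cfg <- sim_config(
      n_genes = 300,
      cohorts = data.frame(name = "A", n_disease = 97, n_control = 3),
      library_size_cv = cv, seed = 23)
    cs <- colSums(generate_cohorts(cfg)$counts)
    expect_lt(abs(sd(cs) / mean(cs) - cv) / cv, 0.2)
  }
})

test_that("planted regulators receive covering signed edge sets", {
  cfg <- sim_config(
    n_genes = 200,
    cohorts = data.frame(name = "A", n_disease = 4, n_control = 4),
    modules = list(planted_module("m1", n_genes = 20, regulator_tf = "TF1",
                                  regulator_sign = "activation")),
    seed = 2)
  truth <- generate_cohorts(cfg)$truth
  kb <- generate_knowledge_base(truth, n_decoy_tfs = 0, n_decoy_cmps = 0,
                                seed = 2)
  tfs <- unique(kb$tf_edges$regulator_id)
  expect_identical(tfs, "TF1")
  mod_genes <- truth$module_genes$m1
  in_module <- kb$tf_edges[kb$tf_edges$target_id %in% mod_genes, ]
  expect_gte(nrow(in_module), 16)
  expect_gte(mean(in_module$effect == "activation"), 0.8)
  expect_gte(nrow(kb$cmp_edges), 1)
  expect_error(generate_knowledge_base(structure(list(module_genes = list()),
                                                 class = "ground_truth")),
               "empty")
})

test_that("decoy TF overlap with a module matches its binomial expectation", {
  cfg <- sim_config(
    n_genes = 5000,
    cohorts = data.frame(name = "A", n_disease = 3, n_control = 3),
    modules = list(planted_module("m1", n_genes = 30, regulator_tf = "TF1")),
    seed = 3)
  truth <- generate_cohorts(cfg)$truth
  kb <- generate_knowledge_base(truth, n_decoy_tfs = 50, seed = 3)
  decoys <- kb$tf_edges[grepl("decoy", kb$tf_edges$regulator_id), ]
  per_decoy <- split(decoys$target_id, decoys$regulator_id)
  overlaps <- vapply(per_decoy, function(t) {
    length(intersect(t, truth$module_genes$m1))
  }, numeric(1))
  sizes <- lengths(per_decoy)
  expected <- mean(sizes) * 30 / 5000
  se <- sqrt(mean(sizes) * (30 / 5000) * (1 - 30 / 5000) / length(per_decoy))
  expect_lt(abs(mean(overlaps) - expected), 3 * se)
})

test_that("planted pathways cover their module with the stated padding", {
  cfg <- sim_config(
    n_genes = 400,
    cohorts = data.frame(name = "A", n_disease = 3, n_control = 3),
    modules = list(planted_module("m1", n_genes = 25,
                                  pathway_label = "pw1")),
    seed = 4)
  truth <- generate_cohorts(cfg)$truth
  sets <- generate_genesets(truth, n_decoy_sets = 0, seed = 4)
  expect_length(sets, 1)
  expect_length(sets$pw1, 30)
  expect_true(all(truth$module_genes$m1 %in% sets$pw1))
})

test_that("decoy gene-set overlap matches its hypergeometric expectation", {
  cfg <- sim_config(
    n_genes = 5000,
    cohorts = data.frame(name = "A", n_disease = 3, n_control = 3),
    modules = list(planted_module("m1", n_genes = 30)),
    seed = 6)
  truth <- generate_cohorts(cfg)$truth
  sets <- generate_genesets(truth, n_decoy_sets = 200, seed = 6,
                            decoy_size = 50)
  decoys <- sets[grepl("decoy", names(sets))]
  overlaps <- vapply(decoys, function(s) {
    length(intersect(s, truth$module_genes$m1))
  }, numeric(1))
  expected <- 50 * 30 / 5000
  se <- sqrt(50 * (30 / 5000) * (1 - 30 / 5000) / 200)
  expect_lt(abs(mean(overlaps) - expected), 3 * se)
})

test_that("ground truth round-trips through its JSON writer", {
  truth <- fix_two_module_sim()$truth
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$module_genes$m1, truth$module_genes$m1)
  expect_equal(back$regulator_map$m1$tf, "TF_m1")
  expect_equal(back$pathway_map$m1, "path_m1")
})
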