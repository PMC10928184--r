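test_that("median pairwise r2 follows the squared-Spearman definition", {
  x <- rbind(a = 1:6, b = 1:6, c = 6:1)
  colnames(x) <- paste0("s", 1:6)
  expect_equal(median_pairwise_r2(x[c("a", "b"), ]), 1)
  expect_equal(median_pairwise_r2(x), 1)  # anti-monotone pairs square to 1
  # permutation vectors with rank correlations verified by the classic
  # rank-difference formula, independent of the implementation
  y <- rbind(p = c(1, 2, 3, 4, 5),
             q = c(2, 1, 3, 5, 4),
             r = c(5, 3, 1, 2, 4))
  colnames(y) <- paste0("s", 1:5)
  rhos <- c(spearman_rankdiff(y["p", ], y["q", ]),
            spearman_rankdiff(y["p", ], y["r", ]),
            spearman_rankdiff(y["q", ], y["r", ]))
  expect_equal(median_pairwise_r2(y), median(rhos^2))
  expect_error(median_pairwise_r2(rbind(y, const = rep(1, 5))), "constant")
  expect_error(median_pairwise_r2(y[1, , drop = FALSE]), "2 genes")
})

test_that("differential coexpression test hits the +1-smoothing floor", {
  set.seed(21)
  n <- 10
  f <- rnorm(n)
  dis <- t(sapply(1:8, function(i) f + rnorm(n, 0, 0.05)))
  ctl <- matrix(rnorm(8 * n), 8, n)
  expr <- cbind(dis, ctl)
  rownames(expr) <- paste0("g", 1:8)
  colnames(expr) <- paste0("s", 1:(2 * n))
  cond <- rep(c("disease", "control"), each = n)
  res <- suppressWarnings(
    diff_coexpression_test(expr, cond, n_perm = 99, seed = 4))
  expect_equal(res$p_empirical, 1 / 100)
  expect_gt(res$delta_r2, 0.8)
  expect_equal(res$delta_r2,
               res$median_r2_disease - res$median_r2_control)
})

test_that("differential coexpression is deterministic and label-order invariant", {
  sim <- fix_two_module_sim()
  study <- fix_two_module_study()
  g <- fix_two_module_config()$modules[[1]]$genes
  cond <- study$sample_meta$condition
  r1 <- diff_coexpression_test(study$expr, cond, genes = g,
                               module_id = "m1", n_perm = 200, seed = 9)
  r2 <- diff_coexpression_test(study$expr, cond, genes = g,
                               module_id = "m1", n_perm = 200, seed = 9)
  expect_identical(r1, r2)
  perm <- sample(ncol(study$expr))
  r3 <- diff_coexpression_test(study$expr[, perm], cond[perm], genes = g,
                               module_id = "m1", n_perm = 200, seed = 9)
  expect_equal(r1$delta_r2, r3$delta_r2)
  expect_equal(r1$p_empirical, r3$p_empirical)
  expect_error(diff_coexpression_test(study$expr, cond, genes = "nope"),
               "absent")
  expect_error(
    diff_coexpression_test(study$expr[g, 1:6], rep("disease", 6)),
    ">= 4 samples")
})

test_that("conservation calls separate planted from random gene sets", {
  cfg <- sim_config(
    n_genes = 300,
    cohorts = data.frame(name = c("A", "B"), n_disease = c(25, 25),
                         n_control = c(4, 4)),
    modules = list(planted_module("m", n_genes = 30, r2_disease = 0.7,
                                  r2_control = 0.1)),
    seed = 33)
  sim <- generate_cohorts(cfg)
  study <- preprocess_study(sim$counts, sim$sample_meta)
  g <- cfg$modules[[1]]$genes
  target <- study$expr[, study$sample_meta$cohort == "B" &
                         study$sample_meta$condition == "disease"]
  hit <- conservation_test(target, g, n_perm = 200, seed = 5)
  expect_true(hit$conserved)
  expect_equal(hit$p_empirical, 1 / 201)
  set.seed(6)
  ps <- replicate(20, {
    rnd <- sample(setdiff(rownames(target), g), 30)
    conservation_test(target, rnd, n_perm = 99, seed = sample.int(1e6, 1),
                      module_id = paste(rnd[1]))$p_empirical
  })
  expect_lte(mean(ps < 0.05), 0.25)   # near-nominal false-call rate
  expect_error(conservation_test(target[1:10, ], g), "mappable")
})

test_that("eigengene is sign-fixed, unit variance, and balanced on split modules", {
  set.seed(31)
  n <- 30
  profile <- rnorm(n)
  x <- t(sapply(1:5, function(i) 2 + profile))
  colnames(x) <- paste0("s", 1:n)
  rownames(x) <- paste0("g", 1:5)
  eg <- eigengene(x)
  expect_equal(sd(eg), 1)
  expect_equal(cor(eg, profile), 1)
  # two anticorrelated halves of equal strength
  f <- rnorm(n)
  up <- t(sapply(1:10, function(i) f + rnorm(n, 0, 0.3)))
  dn <- t(sapply(1:10, function(i) -f + rnorm(n, 0, 0.3)))
  y <- rbind(up, dn)
  dimnames(y) <- list(paste0("g", 1:20), paste0("s", 1:n))
  ey <- eigengene(y)
  expect_lt(abs(abs(cor(ey, colMeans(y[1:10, ]))) -
                  abs(cor(ey, colMeans(y[11:20, ])))), 0.05)
  expect_error(eigengene(matrix(1, 3, 5)), "constant")
})

test_that("phenotype association recovers slopes and auto-adjusts duration", {
  set.seed(41)
  n <- 40
  eg <- rnorm(n)
  meta <- data.frame(age = rnorm(n, 40, 10), duration = rnorm(n, 10, 3),
                     seizure_frequency = rnorm(n))
  self <- suppressWarnings(phenotype_association(eg, data.frame(x = eg), "x"))
  expect_equal(self$slope, 1)
  expect_lt(self$p, 1e-12)
  dur <- phenotype_association(eg, meta, "duration")
  expect_match(dur$adjusted_for, "age")
  plain <- phenotype_association(eg, meta, "seizure_frequency")
  expect_equal(plain$adjusted_for, "")
  expect_error(phenotype_association(eg, data.frame(a = 1:n, b = 2 * (1:n)),
                                     "a", "b"), "collinear")
  # type-I calibration on independent covariates
  set.seed(42)
  rej <- mean(replicate(300, {
    phenotype_association(rnorm(50), data.frame(z = rnorm(50)), "z")$p < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("per-module coexpression statistics are reproducible and complete", {
  study <- fix_two_module_study()
  ms <- suppressWarnings(discover_modules(study, "A"))
  tab <- coexpression_stats(ms, study, n_perm = 100, seed = 3)
  expect_setequal(tab$module_id, unique(ms$modules$module_id))
  expect_true(all(tab$p_empirical >= 1 / 101))
  expect_equal(tab$delta_r2, tab$median_r2_disease - tab$median_r2_control)
  tab2 <- coexpression_stats(ms, study, n_perm = 100, seed = 3)
  expect_identical(tab, tab2)
  # the strongly differentially coexpressed planted module is flagged
  m1_ids <- unique(ms$modules$module_id[
    ms$modules$gene_id %in% fix_two_module_config()$modules[[1]]$genes])
  expect_true(any(tab$significant[tab$module_id %in% m1_ids]))
})
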