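test_that("Spearman dissimilarity matches the rank formula", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  D <- spearman_dissimilarity(x)
  expect_equal(diag(D), setNames(rep(0, 3), rownames(x)))
  expect_equal(D["a", "c"], 2)                       # anti-monotone pair
  expect_equal(D["a", "b"], 1 - spearman_rankdiff(x["a", ], x["b", ]))
  expect_equal(D["a", "b"], 0.2)
  expect_true(isSymmetric(D))
  x["a", ] <- 1
  expect_error(spearman_dissimilarity(x), "constant gene")
  expect_error(spearman_dissimilarity(x[, 1:3]), "4 samples")
})

test_that("soft adjacency maps correlation through the signed power form", {
  D <- matrix(c(0, 0, 2, 0, 0, 1, 2, 1, 0), 3, 3)
  A <- soft_adjacency(D, beta = 6)
  expect_equal(A[1, 2], 1)          # rho = 1
  expect_equal(A[1, 3], 0)          # rho = -1
  expect_equal(A[2, 3], 0.5^6)      # rho = 0
  expect_equal(diag(A), rep(1, 3))
  expect_equal(soft_adjacency(D, beta = 2, signed = FALSE)[1, 3], 1)
  expect_error(soft_adjacency(D, beta = 0), "positive")
})

test_that("K selection finds planted symmetric clusters", {
  th <- 2 * pi * c(0, 1 / 3, 2 / 3)
  centers <- 8 * cbind(cos(th), sin(th))
  hits <- 0
  for (i in 1:20) {
    set.seed(i)
    X <- do.call(rbind, lapply(1:3, function(j) {
      sweep(matrix(rnorm(40, 0, 0.3), 20), 2, centers[j, ], `+`)
    }))
    sel <- select_k(dist(X), k_max = 20)
    hits <- hits + (sel$k == 3)
  }
  expect_gte(hits, 19)
})

test_that("K selection handles degenerate and boundary inputs", {
  d0 <- matrix(0, 10, 10)
  expect_warning(sel <- select_k(d0, k_max = 10), "no inflection")
  expect_equal(sel$k, 1)
  set.seed(1)
  d <- dist(matrix(rnorm(16), 8))
  expect_warning(sel2 <- select_k(d, k_max = 50), "clipped")
  expect_equal(tail(sel2$r2_curve$r2, 1), 1)     # K = n explains everything
  expect_true(all(diff(sel2$r2_curve$r2) > -1e-9))  # non-decreasing curve
  expect_error(select_k(d, k_min = 4, k_max = 5), "3 distinct")
})

test_that("leave-one-out stability runs one iteration per sample", {
  set.seed(2)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  expr[2, ] <- expr[1, ]  # identical pair always co-clusters
  loo <- loo_stability(expr, k_max = 10)
  expect_equal(loo$n_iter, 12)
  expect_equal(ncol(loo$memberships), 12)
  expect_equal(loo$S["g1", "g2"], 1)
  expect_true(all(loo$S >= 0 & loo$S <= 1))
  expect_true(isSymmetric(loo$S))
  # entries are multiples of 1/n_iter
  expect_true(all(abs(loo$S * 12 - round(loo$S * 12)) < 1e-9))
  expect_error(loo_stability(expr[, 1:4]), "5 samples")
})

test_that("planted modules co-cluster and background separates in S", {
  cfg <- sim_config(
    n_genes = 220,
    cohorts = data.frame(name = "A", n_disease = 20, n_control = 3),
    modules = list(
      planted_module("m1", n_genes = 15, r2_disease = 0.8, r2_control = 0),
      planted_module("m2", n_genes = 15, r2_disease = 0.8, r2_control = 0),
      planted_module("m3", n_genes = 15, r2_disease = 0.8, r2_control = 0)),
    seed = 12)
  sim <- generate_cohorts(cfg)
  expr <- log_cpm(sim$counts,
                  tmm_normalize(sim$counts))[, sim$sample_meta$condition ==
                                               "disease"]
  loo <- loo_stability(expr, k_max = 60)
  g1 <- intersect(cfg$modules[[1]]$genes, rownames(loo$S))
  g2 <- intersect(cfg$modules[[2]]$genes, rownames(loo$S))
  expect_gte(mean(loo$S[g1, g1][upper.tri(diag(length(g1)))]), 0.9)
  expect_lte(mean(loo$S[g1, g2]), 0.2)
})

test_that("junk flagging uses the inclusive 50% rule and the cohesion floor", {
  flags <- matrix(FALSE, 3, 12,
                  dimnames = list(c("a", "b", "c"), NULL))
  flags["a", 1:6] <- TRUE   # exactly 50% of iterations
  flags["b", 1:5] <- TRUE
  loo <- structure(list(junk_cluster = flags, junk_cluster_nofloor = flags,
                        n_iter = 12), class = "loo_stability")
  expect_identical(remove_junk(loo), "a")
  all_junk <- loo
  all_junk$junk_cluster[] <- TRUE
  expect_error(remove_junk(all_junk), "degenerate")
})

test_that("a single tight module is protected by the cohesion floor", {
  A <- matrix(0.9, 10, 10)
  diag(A) <- 1
  jc <- regulomix:::junk_cluster_of(A, rep(1, 10))
  expect_false(jc$below_floor)
  # two blocks: the looser one is the junk candidate and sits below the floor
  B <- matrix(0.05, 20, 20)
  B[1:10, 1:10] <- 0.9
  diag(B) <- 1
  jc2 <- regulomix:::junk_cluster_of(B, rep(1:2, each = 10))
  expect_equal(jc2$cluster, 2)
  expect_true(jc2$below_floor)
})

test_that("consensus modules recover perfect blocks up to relabelling", {
  S <- matrix(0, 30, 30, dimnames = list(paste0("g", 1:30), paste0("g", 1:30)))
  S[1:15, 1:15] <- 1
  S[16:30, 16:30] <- 1
  loo <- structure(list(S = S), class = "loo_stability")
  m <- consensus_modules(loo, k_max = 30)
  expect_equal(length(unique(m)), 2)
  expect_equal(length(unique(m[1:15])), 1)
  expect_equal(length(unique(m[16:30])), 1)
  # permuting gene order yields the same partition up to labels
  perm <- sample(30)
  loo2 <- structure(list(S = S[perm, perm]), class = "loo_stability")
  m2 <- consensus_modules(loo2, k_max = 30)
  expect_equal(adjusted_rand(m[names(m2)], m2), 1)
  expect_error(consensus_modules(loo, junk_genes = rownames(S)[-1]),
               "fewer than 2")
})

test_that("over/under splitting follows eigengene sign and fold change", {
  set.seed(9)
  n <- 20
  f <- rnorm(n)
  up <- t(sapply(1:6, function(i) 5 + f + rnorm(n, 0, 0.2)))
  dn <- t(sapply(1:6, function(i) 5 - f + rnorm(n, 0, 0.2)))
  expr_d <- rbind(up + 1, dn - 1)  # over-genes up, under-genes down
  rownames(expr_d) <- paste0("g", 1:12)
  colnames(expr_d) <- paste0("d", 1:n)
  expr_c <- matrix(5, 12, 8, dimnames = list(rownames(expr_d),
                                             paste0("c", 1:8)))
  parts <- split_ou(rownames(expr_d), expr_d, expr_c)
  expect_length(parts, 2)
  suffixes <- vapply(parts, `[[`, character(1), "suffix")
  genes_o <- parts[[which(suffixes == "o")]]$genes
  genes_u <- parts[[which(suffixes == "u")]]$genes
  expect_setequal(genes_o, paste0("g", 1:6))
  expect_setequal(genes_u, paste0("g", 7:12))
  # coherent up-regulated module stays single with suffix o
  one <- split_ou(paste0("g", 1:6), expr_d[1:6, , drop = FALSE],
                  expr_c[1:6, , drop = FALSE])
  expect_length(one, 1)
  expect_equal(one[[1]]$suffix, "o")
  # singleton module labelled by its own fold-change sign
  single <- split_ou("g7", expr_d["g7", , drop = FALSE],
                     expr_c["g7", , drop = FALSE])
  expect_length(single, 1)
  expect_equal(single[[1]]$suffix, "u")
  expect_error(split_ou("g1", expr_d["g1", , drop = FALSE],
                        expr_c["g1", 0, drop = FALSE]), "control")
})

test_that("cohorts at or below the sample gate are refused", {
  sim <- fix_two_module_sim()
  study <- fix_two_module_study()
  expect_error(discover_modules(study, "A", min_samples = 26),
               "only assembled")
})

test_that("the discovery pipeline partitions genes and labels submodules", {
  study <- fix_two_module_study()
  ms <- suppressWarnings(discover_modules(study, "A", min_samples = 21))
  expect_s3_class(ms, "module_set")
  # partition: module genes + junk + filtered + any loo-excluded = input
  assigned <- ms$modules$gene_id
  expect_false(any(duplicated(assigned)))
  expect_length(intersect(assigned, ms$junk_genes), 0)
  expect_length(intersect(assigned, ms$filtered_genes), 0)
  accounted <- c(assigned, ms$junk_genes, ms$filtered_genes,
                 setdiff(rownames(study$expr),
                         c(assigned, ms$junk_genes, ms$filtered_genes)))
  expect_setequal(accounted, rownames(study$expr))
  expect_true(all(grepl("^A\\.\\d+\\.[ou]$", ms$modules$module_id)))
  expect_true(all(ms$modules$stability >= 0 & ms$modules$stability <= 1))
  # the strongly coexpressed planted module is recovered as an over-module
  m1 <- fix_two_module_config()$modules[[1]]
  ids_m1 <- unique(ms$modules$module_id[ms$modules$gene_id %in% m1$genes])
  expect_length(ids_m1, 1)
  expect_match(ids_m1, "\\.o$")
  # tidy/glance accessors
  expect_named(glance(ms), c("cohort", "k_selected", "n_modules",
                             "n_genes_in_modules", "n_junk_genes",
                             "n_filtered_genes", "mean_stability"))
  expect_equal(nrow(tidy(ms)), nrow(ms$modules))
})

test_that("anticorrelated halves of a planted program yield o and u submodules", {
  cfg <- sim_config(
    n_genes = 260,
    cohorts = data.frame(name = "A", n_disease = 25, n_control = 25),
    modules = list(planted_module("mix", n_genes = 30,
                                  direction = rep(c("over", "under"),
                                                  each = 15),
                                  r2_disease = 0.8, r2_control = 0.1)),
    seed = 55)
  sim <- generate_cohorts(cfg)
  study <- preprocess_study(sim$counts, sim$sample_meta)
  ms <- suppressWarnings(discover_modules(study, "A"))
  g <- cfg$modules[[1]]$genes
  hits <- ms$modules[ms$modules$gene_id %in% g, ]
  dir_of <- setNames(cfg$modules[[1]]$direction, g)
  suffix <- sub(".*\\.", "", hits$module_id)
  expect_gte(nrow(hits), 28)
  expect_true(all(suffix[dir_of[hits$gene_id] == "over"] == "o"))
  expect_true(all(suffix[dir_of[hits$gene_id] == "under"] == "u"))
})

test_that("discovery is invariant to gene and sample order", {
  sim <- fix_two_module_sim()
  study <- fix_two_module_study()
  ms1 <- suppressWarnings(discover_modules(study, "A"))
  gperm <- sample(nrow(sim$counts))
  sperm <- sample(ncol(sim$counts))
  study2 <- preprocess_study(sim$counts[gperm, sperm],
                             sim$sample_meta[match(colnames(sim$counts)[sperm],
                                                   sim$sample_meta$sample_id), ])
  ms2 <- suppressWarnings(discover_modules(study2, "A"))
  lab1 <- setNames(sub("[.][ou]$", "", ms1$modules$module_id),
                   ms1$modules$gene_id)
  lab2 <- setNames(sub("[.][ou]$", "", ms2$modules$module_id),
                   ms2$modules$gene_id)
  common <- intersect(names(lab1), names(lab2))
  expect_gte(length(common) / max(length(lab1), length(lab2)), 0.95)
  expect_equal(adjusted_rand(lab1[common], lab2[common]), 1)
})
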