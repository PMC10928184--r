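# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one cohort, two planted modules (one with a TF + pathway, one mixed o/u),
# used across sim / preprocess / coex tests
fix_two_module_config <- function(seed = 101) {
  sim_config(
    n_genes = 300,
    cohorts = data.frame(name = "A", n_disease = 25, n_control = 25),
    modules = list(
      planted_module("m1", n_genes = 30, r2_disease = 0.8, r2_control = 0.1,
                     regulator_tf = "TF_m1", regulator_sign = "activation",
                     pathway_label = "path_m1"),
      planted_module("m2", n_genes = 20,
                     direction = rep(c("over", "under"), each = 10),
                     r2_disease = 0.7, r2_control = 0.1)
    ),
    seed = seed
  )
}

fix_two_module_sim <- function() {
  cached("two_module_sim", generate_cohorts(fix_two_module_config()))
}

fix_two_module_study <- function() {
  cached("two_module_study", {
    sim <- fix_two_module_sim()
    preprocess_study(sim$counts, sim$sample_meta)
  })
}

# the planted-recovery design: four modules over a background, one cohort
fix_recovery_config <- function(seed) {
  sim_config(
    n_genes = 345,
    cohorts = data.frame(name = "A", n_disease = 30, n_control = 30),
    modules = list(
      planted_module("m1", n_genes = 25, r2_disease = 0.7, r2_control = 0.1),
      planted_module("m2", n_genes = 30, r2_disease = 0.7, r2_control = 0.1),
      planted_module("m3", n_genes = 40, r2_disease = 0.7, r2_control = 0.1),
      planted_module("m4", n_genes = 50, r2_disease = 0.7, r2_control = 0.1)),
    seed = seed
  )
}

# run the full discovery pipeline and score recovery against the truth
recovery_ari <- function(seed) {
  cfg <- fix_recovery_config(seed)
  sim <- generate_cohorts(cfg)
  study <- preprocess_study(sim$counts, sim$sample_meta)
  ms <- discover_modules(study, "A")
  truth <- rep("bg", length(cfg$gene_ids))
  names(truth) <- cfg$gene_ids
  for (m in cfg$modules) truth[m$genes] <- m$module_id
  pred <- rep("junk", length(cfg$gene_ids))
  names(pred) <- cfg$gene_ids
  pred[ms$modules$gene_id] <- sub("[.][ou]$", "", ms$modules$module_id)
  common <- rownames(study$expr)
  adjusted_rand(truth[common], pred[common])
}

# brute-force upper-tail hypergeometric probability by enumerating all
# possible draws (independent of the package's log-space kernel)
hyper_upper_bruteforce <- function(k, n, K, N) {
  total <- choose(N, n)
  sum(vapply(k:min(n, K), function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / total
}

# median pairwise squared Spearman correlation recomputed from first
# principles via the classic rank-difference formula (no ties assumed)
spearman_rankdiff <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

expect_tsv_roundtrip <- function(x, writer, reader, ...) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writer(x, path)
  y <- reader(path, ...)
  expect_equal(unname(as.data.frame(y)), unname(as.data.frame(x)),
               ignore_attr = TRUE)
}
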