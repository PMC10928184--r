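kb_toy <- function() {
  knowledge_base(
    tf_edges = tibble::tibble(
      regulator_id = c("TF1", "TF1", "TF1", "TF2", "TF2", "miR1"),
      regulator_class = c("TF", "TF", "TF", "TF", "TF", "miRNA"),
      target_id = c("g1", "g2", "g3", "g2", "g4", "g5"),
      effect = c("activation", "activation", "inhibition", "inhibition",
                 "unspecified", "inhibition")),
    cmp_edges = tibble::tibble(
      cmp_id = c("CMP1", "CMP1", "CMP2"),
      tf_id = c("TF1", "TF2", "TF1"),
      effect = c("activation", "inhibition", "inhibition"))
  )
}

test_that("knowledge base construction validates and deduplicates edges", {
  kb <- kb_toy()
  expect_equal(nrow(kb$tf_edges), 6)
  expect_warning(
    kbc <- knowledge_base(tibble::tibble(
      regulator_id = c("TF1", "TF1"), regulator_class = "TF",
      target_id = "g1", effect = c("activation", "inhibition"))),
    "conflicting")
  expect_equal(kbc$tf_edges$effect, "unspecified")
  # identical duplicates collapse silently
  kbi <- knowledge_base(tibble::tibble(
    regulator_id = c("TF1", "TF1"), regulator_class = "TF",
    target_id = "g1", effect = "activation"))
  expect_equal(nrow(kbi$tf_edges), 1)
  expect_error(knowledge_base(tibble::tibble(
    regulator_id = "", regulator_class = "TF", target_id = "g1",
    effect = "activation")), "empty")
  expect_error(knowledge_base(tibble::tibble(
    regulator_id = "TF1", regulator_class = "TF", target_id = "g1",
    effect = "up")), "effect")
})

test_that("expression filtering removes unexpressed endpoints and empty regulators", {
  kb <- kb_toy()
  all_ids <- c("TF1", "TF2", "CMP1", "CMP2", paste0("g", 1:5))
  expect_equal(restrict_to_expressed(kb, all_ids)$tf_edges, kb$tf_edges)
  # TF2's targets g2, g4 unexpressed -> TF2 disappears, as do its CMP edges
  kept <- restrict_to_expressed(kb, c("TF1", "TF2", "CMP1", "g1", "g3", "g5"))
  expect_false("TF2" %in% kept$tf_edges$regulator_id)
  expect_false(any(kept$cmp_edges$tf_id == "TF2"))
  # miRNA regulators are kept regardless of their own expression
  expect_true("miR1" %in% kept$tf_edges$regulator_id)
  # edge count equals an independent re-count
  expressed <- c("TF1", "CMP1", "g1", "g2")
  manual <- sum(kb$tf_edges$target_id %in% expressed &
                  (kb$tf_edges$regulator_id %in% expressed |
                     kb$tf_edges$regulator_class == "miRNA"))
  expect_equal(nrow(restrict_to_expressed(kb, expressed)$tf_edges), manual)
  expect_error(restrict_to_expressed(kb, character(0)), "empty")
})

test_that("sign composition follows the two-layer algebra exhaustively", {
  effects <- c("activation", "inhibition", "unspecified")
  for (a in effects) {
    for (b in effects) {
      got <- regulomix:::compose_signs(a, b)
      want <- if (a == "unspecified" || b == "unspecified") "unspecified"
      else if (a == b) "activation" else "inhibition"
      expect_identical(got, want)
    }
  }
  # commutative over the signed pairs
  expect_identical(regulomix:::compose_signs("activation", "inhibition"),
                   regulomix:::compose_signs("inhibition", "activation"))
})

test_that("composed CMP effects aggregate paths with conflict detection", {
  kb <- kb_toy()
  comp <- compose_cmp_effects(kb)
  row <- function(c, g) comp$effect[comp$cmp_id == c & comp$target_id == g]
  expect_equal(row("CMP1", "g1"), "activation")      # act o act
  expect_equal(row("CMP1", "g3"), "inhibition")      # act o inh
  expect_equal(row("CMP2", "g1"), "inhibition")      # inh o act
  expect_equal(row("CMP2", "g3"), "activation")      # inh o inh
  # CMP1 reaches g2 via TF1 (act o act = act) and TF2 (inh o inh = act):
  # agreeing defined paths keep the sign
  expect_equal(row("CMP1", "g2"), "activation")
  # unspecified-only paths stay unspecified
  expect_equal(row("CMP1", "g4"), "unspecified")
  # conflicting defined paths become ambiguous
  kb2 <- knowledge_base(
    tf_edges = tibble::tibble(
      regulator_id = c("TFa", "TFb"), regulator_class = "TF",
      target_id = "g1", effect = c("activation", "inhibition")),
    cmp_edges = tibble::tibble(cmp_id = "C", tf_id = c("TFa", "TFb"),
                               effect = "activation"))
  expect_equal(compose_cmp_effects(kb2)$effect, "ambiguous")
})

test_that("regulator prediction matches the closed-form hypergeometric", {
  universe <- sprintf("u%02d", 1:20)
  mod <- universe[1:5]
  kb <- knowledge_base(tibble::tibble(
    regulator_id = "TF1", regulator_class = "TF",
    target_id = mod, effect = "activation"))
  res <- predict_regulators(list(m = mod), kb, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, hypergeom_p(5, 5, 5, 20), tolerance = 1e-15)
  expect_equal(res$direction, "activates")
  # zero overlap -> p = 1, ranked last
  kb2 <- knowledge_base(tibble::tibble(
    regulator_id = c(rep("TF1", 5), rep("TF0", 5)), regulator_class = "TF",
    target_id = c(mod, universe[6:10]),
    effect = "activation"))
  res2 <- predict_regulators(list(m = mod), kb2, universe)
  expect_equal(res2$p[res2$regulator_id == "TF0"], 1)
  expect_equal(res2$regulator_id[1], "TF1")
})

test_that("direction calls require a dominant sign", {
  universe <- sprintf("u%02d", 1:30)
  mod <- universe[1:10]
  make_kb <- function(n_act) {
    knowledge_base(tibble::tibble(
      regulator_id = "TF1", regulator_class = "TF", target_id = mod,
      effect = c(rep("activation", n_act), rep("inhibition", 10 - n_act))))
  }
  expect_equal(predict_regulators(list(m = mod), make_kb(7),
                                  universe)$direction, "activates")
  expect_equal(predict_regulators(list(m = mod), make_kb(5),
                                  universe)$direction, "ambiguous")
  expect_equal(predict_regulators(list(m = mod), make_kb(2),
                                  universe)$direction, "inhibits")
})

test_that("removing decoys preserves the planted regulator's p and helps its FDR", {
  sim <- fix_two_module_sim()
  truth <- sim$truth
  universe <- truth$gene_ids
  kb_full <- generate_knowledge_base(truth, n_decoy_tfs = 20,
                                     n_decoy_cmps = 5, seed = 44)
  kb_min <- generate_knowledge_base(truth, n_decoy_tfs = 0, n_decoy_cmps = 0,
                                    seed = 44)
  mod <- list(m1 = truth$module_genes$m1)
  full <- predict_regulators(mod, kb_full, universe)
  lean <- predict_regulators(mod, kb_min, universe)
  p_full <- full$p[full$regulator_id == "TF_m1"]
  p_lean <- lean$p[lean$regulator_id == "TF_m1"]
  expect_equal(p_full, p_lean, tolerance = 1e-12)
  expect_lte(lean$fdr[lean$regulator_id == "TF_m1"],
             full$fdr[full$regulator_id == "TF_m1"])
})

test_that("the planted TF outranks decoys for its module", {
  sim <- fix_two_module_sim()
  truth <- sim$truth
  hits <- 0
  for (i in 1:10) {
    kb <- generate_knowledge_base(truth, n_decoy_tfs = 50, seed = 100 + i)
    res <- predict_regulators(list(m1 = truth$module_genes$m1), kb,
                              truth$gene_ids)
    tf_rows <- res[res$regulator_class == "TF", ]
    hits <- hits + (tf_rows$regulator_id[which.min(tf_rows$fdr)] == "TF_m1")
  }
  expect_equal(hits, 10)
})
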