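#' Construct a signed regulatory knowledge base
#'
#' Holds the two layers of the causal-reasoning system: direct regulator
#' edges (transcription factors and miRNAs onto target genes) and
#' cell-membrane receptor (CMP) edges onto TFs, each carrying an effect sign.
#' Duplicate (regulator, target) rows with conflicting signs collapse to
#' `"unspecified"` with a warning; identical duplicates are merged silently.
#'
#' @param tf_edges Tibble: regulator_id, regulator_class (`"TF"`/`"miRNA"`),
#'   target_id, effect (`"activation"`/`"inhibition"`/`"unspecified"`).
#' @param cmp_edges Tibble: cmp_id, tf_id, effect (may be empty).
#' @return A `knowledge_base` list.
#' @export
knowledge_base <- function(tf_edges, cmp_edges = NULL) {
  tf_edges <- tibble::as_tibble(tf_edges)
  need <- c("regulator_id", "regulator_class", "target_id", "effect")
  if (!all(need %in% names(tf_edges))) {
    abort("tf_edges needs columns regulator_id, regulator_class, target_id, effect")
  }
  check_ids <- function(x, what) {
    if (any(is.na(x)) || any(!nzchar(x))) {
      abort(sprintf("empty %s id in knowledge base", what))
    }
  }
  check_ids(tf_edges$regulator_id, "regulator")
  check_ids(tf_edges$target_id, "target")
  if (!all(tf_edges$regulator_class %in% c("TF", "miRNA"))) {
    abort("regulator_class must be 'TF' or 'miRNA'")
  }
  effects <- c("activation", "inhibition", "unspecified")
  if (!all(tf_edges$effect %in% effects)) {
    abort("effect must be activation, inhibition or unspecified")
  }
  dedup <- function(tbl, key_cols) {
    collapsed <- tbl |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
      dplyr::summarise(
        .conflict = dplyr::n_distinct(.data$effect) > 1,
        effect = if (.conflict[1]) "unspecified" else .data$effect[1],
        .groups = "drop")
    if (any(collapsed$.conflict)) {
      warn(sprintf("%d (regulator, target) pair(s) with conflicting signs set to 'unspecified'",
                   sum(collapsed$.conflict)))
    }
    dplyr::select(collapsed, -".conflict")
  }
  strip_names <- function(tbl) {
    tbl[] <- lapply(tbl, function(col) {
      names(col) <- NULL
      col
    })
    tbl
  }
  tf_edges <- strip_names(dedup(tf_edges, c("regulator_id",
                                            "regulator_class", "target_id")))
  if (is.null(cmp_edges) || nrow(tibble::as_tibble(cmp_edges)) == 0) {
    cmp_edges <- tibble::tibble(cmp_id = character(0), tf_id = character(0),
                                effect = character(0))
  } else {
    cmp_edges <- tibble::as_tibble(cmp_edges)
    if (!all(c("cmp_id", "tf_id", "effect") %in% names(cmp_edges))) {
      abort("cmp_edges needs columns cmp_id, tf_id, effect")
    }
    check_ids(cmp_edges$cmp_id, "CMP")
    check_ids(cmp_edges$tf_id, "TF")
    if (!all(cmp_edges$effect %in% effects)) {
      abort("effect must be activation, inhibition or unspecified")
    }
    cmp_edges <- strip_names(dedup(cmp_edges, c("cmp_id", "tf_id")))
  }
  structure(list(tf_edges = tf_edges, cmp_edges = cmp_edges,
                 expressed_filtered = FALSE),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d regulator->gene edges (%d regulators), %d CMP->TF edges (%d CMPs)%s\n",
              nrow(x$tf_edges), dplyr::n_distinct(x$tf_edges$regulator_id),
              nrow(x$cmp_edges), dplyr::n_distinct(x$cmp_edges$cmp_id),
              if (x$expressed_filtered) " [expressed-filtered]" else ""))
  invisible(x)
}

#' Restrict a knowledge base to expressed genes
#'
#' Removes every edge with an unexpressed endpoint, then drops regulators
#' left without targets (and receptor edges onto dropped TFs).
#'
#' @param kb A [knowledge_base()].
#' @param expressed Character vector of expressed gene/protein ids.
#' @param require_regulator_expressed Also require the regulator itself to be
#'   expressed (default). Disable when the knowledge base names regulators
#'   with identifiers outside the assay's namespace (e.g. the synthetic
#'   knowledge base's abstract TF labels), in which case only target
#'   expression is enforced. miRNA regulators are always exempt, as miRNAs
#'   are not measured in a poly-A mRNA assay.
#' @return A filtered `knowledge_base`.
#' @export
restrict_to_expressed <- function(kb, expressed,
                                  require_regulator_expressed = TRUE) {
  if (!inherits(kb, "knowledge_base")) abort("`kb` must be a knowledge_base")
  if (length(expressed) == 0) abort("empty expressed gene list")
  tf <- kb$tf_edges |>
    dplyr::filter(.data$target_id %in% expressed,
                  !require_regulator_expressed |
                    .data$regulator_id %in% expressed |
                    .data$regulator_class == "miRNA")
  cmp <- kb$cmp_edges |>
    dplyr::filter(!require_regulator_expressed |
                    .data$cmp_id %in% expressed,
                  .data$tf_id %in% unique(tf$regulator_id))
  out <- knowledge_base(tf, cmp)
  out$expressed_filtered <- TRUE
  out
}

# sign algebra for composed paths: unspecified is absorbing, otherwise
# activation = +1, inhibition = -1 multiply
compose_signs <- function(a, b) {
  ifelse(a == "unspecified" | b == "unspecified", "unspecified",
         ifelse(a == b, "activation", "inhibition"))
}

#' Composed CMP effects on genes
#'
#' Propagates each cell-membrane receptor's effect through its downstream
#' TFs onto genes along two-layer canonical paths. A path's sign is the
#' product of its edge signs (unspecified anywhere makes the path
#' unspecified). Per (CMP, gene): if all sign-defined paths agree the
#' composed effect is that sign; conflicting defined signs give
#' `"ambiguous"`; only unspecified paths give `"unspecified"`.
#'
#' @param kb A [knowledge_base()] (ideally expressed-filtered).
#' @return Tibble: cmp_id, target_id, effect in
#'   activation/inhibition/ambiguous/unspecified, n_paths.
#' @export
compose_cmp_effects <- function(kb) {
  if (!inherits(kb, "knowledge_base")) abort("`kb` must be a knowledge_base")
  if (nrow(kb$cmp_edges) == 0) {
    return(tibble::tibble(cmp_id = character(0), target_id = character(0),
                          effect = character(0), n_paths = integer(0)))
  }
  paths <- kb$cmp_edges |>
    dplyr::inner_join(kb$tf_edges, by = c("tf_id" = "regulator_id"),
                      relationship = "many-to-many") |>
    dplyr::mutate(path_effect = compose_signs(.data$effect.x,
                                              .data$effect.y))
  paths |>
    dplyr::group_by(.data$cmp_id, .data$target_id) |>
    dplyr::summarise(
      effect = {
        defined <- setdiff(unique(.data$path_effect), "unspecified")
        if (length(defined) == 0) "unspecified"
        else if (length(defined) == 1) defined
        else "ambiguous"
      },
      n_paths = dplyr::n(), .groups = "drop")
}

#' Predict upstream regulators of gene modules
#'
#' For every regulator with at least `min_targets` expressed targets (TFs and
#' miRNAs through their direct target sets; CMPs through their composed
#' two-layer gene sets, counted regardless of sign), tests the overlap of the
#' regulator's targets with each module by the upper-tail hypergeometric test
#' over the expressed-gene universe, applies Benjamini-Hochberg correction
#' across all regulator-by-module tests, and calls a direction when a
#' dominant sign covers at least `dominance` of the signed overlapping edges.
#'
#' @param modules Named list of module gene sets (or one character vector).
#' @param kb A [knowledge_base()].
#' @param universe Character vector of expressed genes.
#' @param min_targets Minimum expressed target-set size per regulator.
#' @param dominance Fraction of signed overlap edges the majority sign must
#'   reach for a directional call (else `"ambiguous"`).
#' @return Tibble: regulator_id, regulator_class, module_id, overlap,
#'   target_set_size, p, fdr, direction.
#' @export
predict_regulators <- function(modules, kb, universe, min_targets = 3,
                               dominance = 0.6) {
  if (!inherits(kb, "knowledge_base")) abort("`kb` must be a knowledge_base")
  if (length(universe) == 0) abort("empty universe")
  if (is.character(modules)) modules <- list(module = modules)
  modules <- lapply(modules, intersect, universe)
  if (any(lengths(modules) == 0)) abort("module with no genes in universe")

  direct <- kb$tf_edges |>
    dplyr::filter(.data$target_id %in% universe) |>
    dplyr::select(regulator_id = "regulator_id",
                  regulator_class = "regulator_class",
                  target_id = "target_id", effect = "effect")
  composed <- compose_cmp_effects(kb) |>
    dplyr::filter(.data$target_id %in% universe) |>
    dplyr::transmute(regulator_id = .data$cmp_id, regulator_class = "CMP",
                     target_id = .data$target_id, effect = .data$effect)
  edges <- dplyr::bind_rows(direct, composed)
  target_sets <- split(seq_len(nrow(edges)), edges$regulator_id)
  keep <- names(target_sets)[lengths(target_sets) >= min_targets]
  if (length(keep) == 0) {
    return(tibble::tibble(regulator_id = character(0),
                          regulator_class = character(0),
                          module_id = character(0), overlap = integer(0),
                          target_set_size = integer(0), p = numeric(0),
                          fdr = numeric(0), direction = character(0)))
  }
  rows <- purrr::map(keep, function(reg) {
    sub <- edges[target_sets[[reg]], ]
    targets <- sub$target_id
    purrr::imap(modules, function(genes, mid) {
      hit <- sub[sub$target_id %in% genes, ]
      k <- nrow(hit)
      direction <- if (k == 0) NA_character_ else {
        signed <- hit$effect[hit$effect %in% c("activation", "inhibition")]
        if (length(signed) == 0) "ambiguous" else {
          n_act <- sum(signed == "activation")
          frac <- max(n_act, length(signed) - n_act) / length(signed)
          if (frac < dominance) "ambiguous"
          else if (n_act >= length(signed) - n_act) "activates" else "inhibits"
        }
      }
      tibble::tibble(regulator_id = reg,
                     regulator_class = sub$regulator_class[1],
                     module_id = mid, overlap = k,
                     target_set_size = length(targets),
                     p = hypergeom_p(k, length(genes), length(targets),
                                     length(universe)),
                     direction = direction)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(fdr = bh_fdr(.data$p)) |>
    dplyr::relocate("fdr", .after = "p") |>
    dplyr::arrange(.data$module_id, .data$p)
}
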