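#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a module set into one row per gene
#'
#' @param x A `module_set` from [discover_modules()].
#' @param ... Ignored.
#' @return Tibble: cohort, module_id, suffix, gene_id, stability.
#' @export
tidy.module_set <- function(x, ...) {
  x$modules |>
    dplyr::mutate(cohort = x$cohort,
                  suffix = stringr::str_extract(.data$module_id, "[ou]$")) |>
    dplyr::relocate("cohort")
}

#' One-row summary of a module set
#'
#' @param x A `module_set`.
#' @param ... Ignored.
#' @return Tibble: cohort, k_selected, n_modules, n_genes_in_modules,
#'   n_junk_genes, n_filtered_genes, mean_stability.
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    cohort = x$cohort,
    k_selected = x$k_selected,
    n_modules = dplyr::n_distinct(x$modules$module_id),
    n_genes_in_modules = nrow(x$modules),
    n_junk_genes = length(x$junk_genes),
    n_filtered_genes = length(x$filtered_genes),
    mean_stability = mean(x$modules$stability)
  )
}

#' Tidy DAPC posterior memberships into long form
#'
#' @param x A `dapc_result` from [dapc()].
#' @param ... Ignored.
#' @return Tibble: sample, prior, cohort, posterior.
#' @export
tidy.dapc_result <- function(x, ...) {
  post <- tibble::as_tibble(x$posterior)
  post$sample <- rownames(x$posterior) %||%
    sprintf("sample_%d", seq_len(nrow(x$posterior)))
  post$prior <- as.character(x$groups)
  tidyr::pivot_longer(post, cols = -c("sample", "prior"),
                      names_to = "cohort", values_to = "posterior")
}

#' One-row summary of a DAPC fit
#'
#' @param x A `dapc_result`.
#' @param ... Ignored.
#' @return Tibble: n_pcs, n_groups, accuracy.
#' @export
glance.dapc_result <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs, n_groups = nlevels(x$groups),
                 accuracy = x$accuracy)
}

#' Tidy a regulome set into one row per member module
#'
#' @param x A `regulome_set` from [build_regulomes()].
#' @param ... Ignored.
#' @return Tibble joining module assignments with regulome class labels.
#' @export
tidy.regulome_set <- function(x, ...) {
  dplyr::left_join(x$assignments, x$regulomes, by = "regulome_id")
}

#' One-row summary of a regulome set
#'
#' @param x A `regulome_set`.
#' @param ... Ignored.
#' @return Tibble: n_regulomes, n_modules, and one count column per class.
#' @export
glance.regulome_set <- function(x, ...) {
  counts <- table(factor(x$regulomes$class,
                         levels = c("constitutive", "enhanced", "activated",
                                    "pathology_specific")))
  dplyr::bind_cols(
    tibble::tibble(n_regulomes = nrow(x$regulomes),
                   n_modules = nrow(x$assignments)),
    tibble::as_tibble(as.list(counts))
  )
}
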