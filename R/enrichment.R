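#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` genes of a `K`-gene set when sampling `n` genes without
#' replacement from a universe of `N`. Computed in log space via the stable
#' distribution-function kernel.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Set size.
#' @param N Universe size.
#' @return p-value in (0, 1\].
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (any(k < 0) || any(n < 0) || any(K < 0) || any(N < 1)) {
    abort("counts must be non-negative and N >= 1")
  }
  if (any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    abort("inconsistent counts: need k <= min(n, K) and n, K <= N")
  }
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR adjustment with enforced monotonicity.
#'
#' @param p Vector of p-values in (0, 1\].
#' @return Vector of q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment of one or more queries
#'
#' Tests every query gene set against every set of one or more collections
#' with all expressed genes as the universe. Query genes outside the universe
#' are dropped with a warning. FDR is computed within each collection across
#' all (query, set) tests performed, so the correction accounts for the total
#' number of enrichment tests.
#'
#' @param queries A character vector (one query) or named list of character
#'   vectors.
#' @param collections A `gene_set_collection` / named list of character
#'   vectors (one collection), or a named list of such collections.
#' @param universe Character vector of expressed genes.
#' @return Tibble: query_id, collection, set_name, overlap, query_size,
#'   set_size, universe_size, p, fdr.
#' @export
annotate_genesets <- function(queries, collections, universe) {
  if (length(universe) == 0) abort("empty universe")
  if (is.character(queries)) queries <- list(query = queries)
  if (is.null(names(queries))) abort("queries must be named")
  if (length(collections) == 0) abort("empty collection")
  single <- is.character(collections[[1]])
  if (single) collections <- list(collection = collections)
  res <- purrr::imap(collections, function(coll, coll_name) {
    if (length(coll) == 0) abort(sprintf("empty collection '%s'", coll_name))
    sets <- lapply(coll, intersect, universe)
    rows <- purrr::imap(queries, function(q, qid) {
      outside <- setdiff(q, universe)
      if (length(outside) > 0) {
        warn(sprintf("query '%s': %d gene(s) outside universe dropped",
                     qid, length(outside)))
      }
      q <- intersect(q, universe)
      tibble::tibble(
        query_id = qid, collection = coll_name, set_name = names(coll),
        overlap = unname(vapply(sets, function(s) length(intersect(q, s)),
                                integer(1))),
        query_size = length(q),
        set_size = unname(lengths(sets)),
        universe_size = length(universe)
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(p = hypergeom_p(.data$overlap, .data$query_size,
                                  .data$set_size, .data$universe_size)) |>
    dplyr::group_by(.data$collection) |>
    dplyr::mutate(fdr = bh_fdr(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$collection, .data$query_id, .data$p)
}
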