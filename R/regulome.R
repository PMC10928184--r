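#' Inclusion index between two gene sets
#'
#' `|intersect(x, y)| / min(|x|, |y|)`: the overlap of two gene sets scaled
#' by the smaller set, so a small module fully contained in a large one
#' scores 1. Symmetric.
#'
#' @param x,y Non-empty character vectors.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' inclusion_index(letters[1:5], letters[3:10])
inclusion_index <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("empty gene set")
  length(intersect(x, y)) / min(length(unique(x)), length(unique(y)))
}

#' Pairwise inclusion-index matrix over a list of modules
#'
#' @param modules Named list of gene sets.
#' @return Symmetric matrix with unit diagonal.
#' @export
inclusion_matrix <- function(modules) {
  n <- length(modules)
  m <- matrix(1, n, n, dimnames = list(names(modules), names(modules)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- inclusion_index(modules[[i]], modules[[j]])
    }
  }
  m
}

#' Cluster modules across cohorts into regulomes
#'
#' Ward clustering of all modules on distance `1 - inclusion index`, with
#' the number of clusters chosen to maximise the mean silhouette width over
#' K = 2 ... min(n - 1, `k_cap`). If every between-module distance is maximal
#' (no overlap anywhere) the silhouette is degenerate and each module becomes
#' its own regulome, with a warning.
#'
#' @param modules Named list of module gene sets (>= 3 modules).
#' @param k_cap Largest K scanned.
#' @return Tibble (module_id, regulome_id) with attributes `k`,
#'   `silhouette_curve` (tibble: k, mean_width) and `inclusion` (the matrix).
#' @export
cluster_modules <- function(modules, k_cap = 40) {
  if (length(modules) < 3) abort("need at least 3 modules")
  ii <- inclusion_matrix(modules)
  d <- as.dist(1 - ii)
  n <- length(modules)
  if (all(d >= 1 - 1e-12)) {
    warn("all modules disjoint; silhouette degenerate, one regulome per module")
    out <- tibble::tibble(module_id = names(modules),
                          regulome_id = sprintf("R%02d", seq_len(n)))
    attr(out, "k") <- n
    attr(out, "inclusion") <- ii
    return(out)
  }
  hc <- hclust(d, method = "ward.D2")
  ks <- 2:min(n - 1, k_cap)
  widths <- vapply(ks, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k <- ks[which.max(widths)]
  cl <- cutree(hc, k = k)
  out <- tibble::tibble(module_id = names(modules),
                        regulome_id = sprintf("R%02d", cl))
  attr(out, "k") <- k
  attr(out, "silhouette_curve") <- tibble::tibble(k = ks, mean_width = widths)
  attr(out, "inclusion") <- ii
  out
}

#' Intersect genes of a regulome
#'
#' The regulome's core gene set: genes occurring in at least one member
#' module of every cohort represented in the regulome. A single-cohort
#' regulome returns the union of its members' genes.
#'
#' @param member_modules Named list of the member modules' gene sets.
#' @param module_cohorts Named character vector: module_id -> cohort.
#' @return Character vector of intersect genes.
#' @export
intersect_genes <- function(member_modules, module_cohorts) {
  cohorts <- unique(module_cohorts[names(member_modules)])
  per_cohort <- lapply(cohorts, function(co) {
    mods <- names(member_modules)[module_cohorts[names(member_modules)] == co]
    unique(unlist(member_modules[mods]))
  })
  Reduce(intersect, per_cohort)
}

#' Classify a regulome into one of four functional classes
#'
#' Applies the decision rules, in order of precedence:
#' \enumerate{
#'   \item \strong{pathology_specific}: all members come from one cohort (or
#'     the maximal inclusion index with any other-cohort module is below
#'     `cross_cohort_ii_min`) and at least one member is differentially
#'     coexpressed (DC p < `alpha`).
#'   \item \strong{activated}: at least one member DC-significant and no
#'     member conserved in any control cohort.
#'   \item \strong{enhanced}: at least one member DC-significant with
#'     `delta_r2 > 0` and at least one member conserved in a control cohort.
#'   \item \strong{constitutive}: everything else.
#' }
#'
#' @param members Tibble with `module_id` and `cohort` for the regulome's
#'   member modules.
#' @param coex_stats Differential-coexpression tibble covering all members
#'   (columns module_id, delta_r2, p_empirical).
#' @param conservation Conservation tibble (columns module_id, is_control,
#'   conserved); may be empty.
#' @param alpha Significance level for DC calls.
#' @param cross_cohort_ii_min Inclusion-index floor below which other-cohort
#'   overlap does not count as cross-cohort presence.
#' @param max_other_ii Optional named vector: per member module, the maximal
#'   inclusion index with any module of another cohort (used by the rule-1
#'   fallback when members nominally span cohorts).
#' @return A single class label.
#' @export
classify_regulome <- function(members, coex_stats, conservation = NULL,
                              alpha = 0.05, cross_cohort_ii_min = 0.3,
                              max_other_ii = NULL) {
  members <- tibble::as_tibble(members)
  missing <- setdiff(members$module_id, coex_stats$module_id)
  if (length(missing) > 0) {
    abort(sprintf("missing coexpression statistics for module(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cs <- coex_stats[match(members$module_id, coex_stats$module_id), ]
  dc_sig <- cs$p_empirical < alpha
  if (is.null(conservation) || nrow(conservation) == 0) {
    conserved_ctl <- FALSE
  } else {
    ctl <- conservation[conservation$is_control &
                          conservation$module_id %in% members$module_id, ]
    conserved_ctl <- any(ctl$conserved)
  }
  single_cohort <- dplyr::n_distinct(members$cohort) == 1
  isolated <- if (!is.null(max_other_ii)) {
    all(max_other_ii[members$module_id] < cross_cohort_ii_min, na.rm = TRUE)
  } else FALSE
  if ((single_cohort || isolated) && any(dc_sig)) return("pathology_specific")
  if (any(dc_sig) && !conserved_ctl) return("activated")
  if (any(dc_sig & cs$delta_r2 > 0) && conserved_ctl) return("enhanced")
  "constitutive"
}

#' Build and classify regulomes across cohorts
#'
#' Clusters all modules by inclusion index, extracts each regulome's
#' intersect genes, and assigns the four-class label from the
#' differential-coexpression and conservation statistics.
#'
#' @param modules Named list of module gene sets across all cohorts.
#' @param module_cohorts Named character vector: module_id -> cohort.
#' @param coex_stats Combined differential-coexpression tibble.
#' @param conservation Combined conservation tibble (needs `is_control`).
#' @param alpha,cross_cohort_ii_min,k_cap See [classify_regulome()] and
#'   [cluster_modules()].
#' @return A `regulome_set`: list with `assignments` (module -> regulome
#'   tibble), `regulomes` (tibble: regulome_id, class, n_modules, n_cohorts,
#'   n_intersect_genes), `intersect_genes` (named list), `inclusion`
#'   (matrix).
#' @export
build_regulomes <- function(modules, module_cohorts, coex_stats,
                            conservation = NULL, alpha = 0.05,
                            cross_cohort_ii_min = 0.3, k_cap = 40) {
  assignments <- cluster_modules(modules, k_cap = k_cap)
  ii <- attr(assignments, "inclusion")
  max_other <- vapply(names(modules), function(mid) {
    other <- names(modules)[module_cohorts[names(modules)] !=
                              module_cohorts[mid]]
    if (length(other) == 0) 0 else max(ii[mid, other])
  }, numeric(1))
  assignments <- assignments |>
    dplyr::mutate(cohort = unname(module_cohorts[.data$module_id]))
  reg_ids <- sort(unique(assignments$regulome_id))
  ig <- list()
  rows <- purrr::map(reg_ids, function(rid) {
    mem <- assignments[assignments$regulome_id == rid, ]
    sets <- modules[mem$module_id]
    genes <- intersect_genes(sets, module_cohorts)
    ig[[rid]] <<- genes
    cls <- classify_regulome(mem, coex_stats, conservation, alpha = alpha,
                             cross_cohort_ii_min = cross_cohort_ii_min,
                             max_other_ii = max_other)
    tibble::tibble(regulome_id = rid, class = cls,
                   n_modules = nrow(mem),
                   n_cohorts = dplyr::n_distinct(mem$cohort),
                   n_intersect_genes = length(genes))
  })
  structure(list(assignments = assignments,
                 regulomes = dplyr::bind_rows(rows),
                 intersect_genes = ig, inclusion = ii),
            class = "regulome_set")
}

#' @export
print.regulome_set <- function(x, ...) {
  cat(sprintf("<regulome_set> %d regulomes over %d modules\n",
              nrow(x$regulomes), nrow(x$assignments)))
  print(table(x$regulomes$class))
  invisible(x)
}
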