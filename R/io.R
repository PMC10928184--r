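# Tab-separated, UTF-8, unquoted readers/writers for every artifact the
# pipeline touches. Ids are validated against a safe charset so round trips
# are bit-exact.

SAFE_ID <- "^[A-Za-z0-9._-]+$"

check_ids_safe <- function(x, what, where) {
  bad <- which(is.na(x) | !grepl(SAFE_ID, x))
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid %s id at row %d: '%s'",
                  where, what, bad[1], x[bad[1]]))
  }
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a gene counts table
#'
#' First column `gene_id`, remaining columns one integer column per sample.
#'
#' @param path File path.
#' @return `read_counts()`: integer genes x samples matrix with dimnames.
#' @export
read_counts <- function(path) {
  tbl <- read_tsv_strict(path)
  if (names(tbl)[1] != "gene_id") abort("counts: first column must be gene_id")
  check_ids_safe(as.character(tbl$gene_id), "gene", path)
  if (anyDuplicated(tbl$gene_id)) abort("counts: duplicate gene ids")
  if (anyDuplicated(names(tbl)[-1])) abort("counts: duplicate sample ids")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    abort(sprintf("%s: counts must be non-negative integers", path))
  }
  rownames(m) <- tbl$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Integer genes x samples matrix.
#' @export
write_counts <- function(counts, path) {
  counts <- assert_count_matrix(counts)
  write_tsv_plain(data.frame(gene_id = rownames(counts), counts,
                             check.names = FALSE), path)
}

METADATA_COLS <- c("sample_id", "cohort", "condition", "tissue", "age",
                   "seizure_frequency", "duration", "sex", "batch")

#' Read / write sample metadata
#'
#' Required columns: `sample_id`, `cohort`, `condition`
#' (`disease`/`control`); recognised optional columns: tissue, age,
#' seizure_frequency, duration, sex, batch. Unknown columns are rejected by
#' name. When `counts` is supplied, every metadata sample must be present in
#' the counts matrix.
#'
#' @param path File path.
#' @param counts Optional counts matrix for cross-validation.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path, counts = NULL) {
  tbl <- read_tsv_strict(path)
  unknown <- setdiff(names(tbl), METADATA_COLS)
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown metadata column(s): %s", path,
                  paste(unknown, collapse = ", ")))
  }
  need <- c("sample_id", "cohort", "condition")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing metadata column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  check_ids_safe(as.character(tbl$sample_id), "sample", path)
  if (anyDuplicated(tbl$sample_id)) abort("metadata: duplicate sample ids")
  if (!all(tbl$condition %in% c("disease", "control"))) {
    abort(sprintf("%s: condition must be 'disease' or 'control'", path))
  }
  if (!is.null(counts)) {
    absent <- setdiff(tbl$sample_id, colnames(counts))
    if (length(absent) > 0) {
      abort(sprintf("metadata sample(s) absent from counts: %s",
                    paste(absent, collapse = ", ")))
    }
  }
  tbl
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  write_tsv_plain(meta, path)
}

#' Read / write a signed regulatory knowledge base
#'
#' One TSV with columns regulator_id, regulator_class (`TF`/`miRNA`/`CMP`),
#' target_id, effect (`activation`/`inhibition`/`unspecified`). `CMP` rows
#' point at TF ids; the reader splits the two layers.
#'
#' @param path File path.
#' @return `read_kb()`: a [knowledge_base()].
#' @export
read_kb <- function(path) {
  tbl <- read_tsv_strict(path)
  need <- c("regulator_id", "regulator_class", "target_id", "effect")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing KB column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (!all(tbl$regulator_class %in% c("TF", "miRNA", "CMP"))) {
    abort(sprintf("%s: regulator_class must be TF, miRNA or CMP", path))
  }
  if (!all(tbl$effect %in% c("activation", "inhibition", "unspecified"))) {
    abort(sprintf("%s: effect must be activation, inhibition or unspecified",
                  path))
  }
  check_ids_safe(as.character(tbl$regulator_id), "regulator", path)
  check_ids_safe(as.character(tbl$target_id), "target", path)
  is_cmp <- tbl$regulator_class == "CMP"
  knowledge_base(
    tf_edges = tbl[!is_cmp, need],
    cmp_edges = tibble::tibble(cmp_id = tbl$regulator_id[is_cmp],
                               tf_id = tbl$target_id[is_cmp],
                               effect = tbl$effect[is_cmp])
  )
}

#' @rdname read_kb
#' @param kb A [knowledge_base()].
#' @export
write_kb <- function(kb, path) {
  cmp <- kb$cmp_edges
  tbl <- dplyr::bind_rows(
    kb$tf_edges[, c("regulator_id", "regulator_class", "target_id", "effect")],
    tibble::tibble(regulator_id = cmp$cmp_id, regulator_class = "CMP",
                   target_id = cmp$tf_id, effect = cmp$effect)
  )
  write_tsv_plain(tbl, path)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard gene-matrix-transposed layout: one set per line with name,
#' description, then tab-separated members. Duplicate set names are
#' rejected; duplicated members within a set are stored once with a warning.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors
#'   (`gene_set_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("%s: empty GMT file", path))
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("%s: line %d has fewer than 3 fields", path, i))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      abort(sprintf("%s: duplicate set name '%s' at line %d", path, nm, i))
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("set '%s': duplicated member(s) stored once", nm))
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs[nm] <- fields[2]
  }
  structure(sets, class = "gene_set_collection", descriptions = descs)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (descriptions taken from the
#'   `descriptions` attribute, defaulting to `"na"`).
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write the synthetic ground-truth record
#'
#' JSON serialisation of the `ground_truth` object's recoverable fields
#' (module gene sets, directions, r2 targets, cohort placement, regulator and
#' pathway maps).
#'
#' @param path File path.
#' @return `read_ground_truth()`: a list mirroring the `ground_truth` fields.
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname read_ground_truth
#' @param truth A `ground_truth` from [generate_cohorts()].
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    module_genes = truth$module_genes,
    direction = truth$direction,
    module_r2 = truth$module_r2,
    module_cohorts = truth$module_cohorts,
    regulator_map = truth$regulator_map,
    pathway_map = truth$pathway_map
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write module membership tables
#'
#' Columns: module_id, gene_id, stability.
#'
#' @param path File path.
#' @return `read_modules()`: tibble.
#' @export
read_modules <- function(path) {
  tbl <- read_tsv_strict(path)
  need <- c("module_id", "gene_id", "stability")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing module column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  tbl
}

#' @rdname read_modules
#' @param modules Modules tibble (e.g. `module_set$modules`).
#' @export
write_modules <- function(modules, path) {
  write_tsv_plain(modules, path)
}
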