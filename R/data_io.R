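#' Read an expression matrix with sample annotations
#'
#' Loads a genes x samples table (TSV with a header of sample ids, or GCT)
#' together with a mandatory sample-annotation TSV holding columns
#' \code{sample_id, age, tissue}. Duplicate gene identifiers are collapsed by
#' the arithmetic mean of their rows; samples without a parseable age are
#' dropped (and counted in the log). Ages may be numeric years or bracket
#' strings such as \code{"50-59"}; brackets are kept as ordinal ranks for the
#' rank-based correlation downstream.
#'
#' @param path path to the expression table
#' @param annotation path to the sample-annotation TSV
#' @param format \code{"tsv"} or \code{"gct"} (default guessed from the
#'   file extension)
#' @return list with elements \code{expr} (an
#'   \code{\link{expression_matrix}}), \code{annotation} (a
#'   \code{\link{sample_annotation}}) and \code{n_dropped} (samples dropped
#'   for missing age)
#' @export
read_expression <- function(path, annotation, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(annotation)) stop("no such annotation file: ", annotation)
  format <- tolower(format %||% tools::file_ext(path))
  values <- switch(format,
    tsv = , txt = {
      tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
      m <- as.matrix(tab[, -1L, drop = FALSE])
      rownames(m) <- as.character(tab[[1L]])
      storage.mode(m) <- "double"
      m
    },
    gct = read_gct(path),
    stop("unsupported expression format: ", format)
  )
  values <- collapse_duplicate_genes(values)

  ann_tab <- utils::read.delim(annotation, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "age", "tissue")
  miss <- setdiff(need, names(ann_tab))
  if (length(miss))
    stop("annotation is missing required column(s): ", paste(miss, collapse = ", "),
         " (expected sample_id, age, tissue)")
  ann <- sample_annotation(ann_tab$sample_id, ann_tab$age, ann_tab$tissue)

  shared <- intersect(colnames(values), ann$sample_id)
  if (length(shared) == 0L) stop("no samples shared between matrix and annotation")
  values <- values[, shared, drop = FALSE]
  ann <- ann[match(shared, ann$sample_id), , drop = FALSE]

  keep <- !is.na(ann$age_value)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    da_log("io", n_dropped, " sample(s) dropped for missing age")
  if (!any(keep)) stop("no samples with a usable age remain")
  values <- values[, keep, drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  # re-rank ages over the retained samples
  ann$age_rank <- rank(ann$age_value, ties.method = "average")
  rownames(ann) <- NULL

  # drop genes with any missing value (rank correlation with missingness is
  # ambiguous); counted in the log
  bad <- rowSums(is.na(values)) > 0L
  if (any(bad)) {
    da_log("io", sum(bad), " gene(s) dropped for missing expression values")
    values <- values[!bad, , drop = FALSE]
  }

  list(expr = expression_matrix(values), annotation = ann, n_dropped = n_dropped)
}

## Mean-collapse of duplicate gene rows; order-independent and symmetric.
collapse_duplicate_genes <- function(values) {
  if (!anyDuplicated(rownames(values))) return(values)
  ids <- rownames(values)
  collapsed <- rowsum(values, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  collapsed[unique(ids), , drop = FALSE]
}

#' Read a treatment-profile set (z-score profiles) with metadata
#'
#' Loads a genes x profiles matrix of differential-expression z-scores from
#' GCT, GCTX or TSV, plus a sidecar metadata TSV with columns
#' \code{profile_id, drug, cell_line, dose, time, replicate_group}. Profiles
#' with incomplete metadata are dropped (count logged).
#'
#' @param path path to the z-score matrix
#' @param meta path to the profile-metadata TSV
#' @param format \code{"gct"}, \code{"gctx"} or \code{"tsv"} (default guessed
#'   from the extension)
#' @return a \code{\link{treatment_profile_set}}
#' @export
read_profiles <- function(path, meta, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  z <- switch(format,
    gct = read_gct(path),
    gctx = read_gctx(path),
    tsv = , txt = {
      tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
      m <- as.matrix(tab[, -1L, drop = FALSE])
      rownames(m) <- as.character(tab[[1L]])
      storage.mode(m) <- "double"
      m
    },
    stop("unsupported profile format: ", format)
  )
  z <- collapse_duplicate_genes(z)
  meta_tab <- utils::read.delim(meta, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("profile_id", "drug", "cell_line", "dose", "time", "replicate_group")
  miss <- setdiff(need, names(meta_tab))
  if (length(miss))
    stop("profile metadata missing column(s): ", paste(miss, collapse = ", "))
  meta_tab <- meta_tab[meta_tab$profile_id %in% colnames(z), , drop = FALSE]
  complete <- stats::complete.cases(meta_tab[, need]) &
    rowSums(meta_tab[, need] == "" | is.na(meta_tab[, need])) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L)
    da_log("io", n_dropped, " profile(s) dropped for incomplete metadata")
  meta_tab <- meta_tab[complete, , drop = FALSE]
  keep <- intersect(colnames(z), meta_tab$profile_id)
  if (length(keep) == 0L) stop("zero usable profiles after metadata filtering")
  treatment_profile_set(z[, keep, drop = FALSE], meta_tab)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT dialect: set name, description, then member
#' gene ids. Lines with fewer than three fields, empty member lists, or
#' duplicate set names are hard errors.
#'
#' @param path path to a \code{.gmt} file
#' @return a \code{\link{gene_set_collection}}
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[[1L]], " has fewer than 3 fields in ", path)
  names_ <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(lengths(members) == 0L)
  if (length(empty))
    stop("GMT set '", names_[[empty[[1L]]]], "' has an empty member list")
  gene_set_collection(stats::setNames(members, names_),
                      stats::setNames(descs, names_))
}

#' Intersect the gene universes of an expression matrix and a profile set
#'
#' All signatures live on this shared universe: the lexicographically sorted
#' intersection of gene identifiers (exact, case-sensitive matching).
#'
#' @param expr an \code{ExpressionMatrix}
#' @param profiles a \code{TreatmentProfileSet}
#' @return character vector of gene ids (the GeneUniverse)
#' @export
intersect_universe <- function(expr, profiles) {
  u <- sort(intersect(expr$gene_ids, profiles$gene_ids))
  if (length(u) == 0L) stop("empty gene universe: no shared gene ids")
  da_log("universe", length(u), " shared genes")
  u
}

#' Project an expression matrix or profile set onto a gene universe
#'
#' @param x an \code{ExpressionMatrix} or \code{TreatmentProfileSet}
#' @param universe character vector of gene ids (subset of \code{x}'s genes)
#' @return object of the same class restricted to \code{universe}, in
#'   universe order
#' @export
project_universe <- function(x, universe) {
  miss <- setdiff(universe, x$gene_ids)
  if (length(miss))
    stop("universe contains genes absent from the dataset, e.g. ", miss[[1L]])
  if (inherits(x, "ExpressionMatrix")) {
    expression_matrix(x$values[universe, , drop = FALSE])
  } else if (inherits(x, "TreatmentProfileSet")) {
    treatment_profile_set(x$z[universe, , drop = FALSE], x$meta)
  } else stop("cannot project object of class ", class(x)[[1L]])
}
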