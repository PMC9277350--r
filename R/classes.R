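#' Construct an ExpressionMatrix
#'
#' A genes x samples matrix of non-negative expression values (e.g. TPM) with
#' unique gene and sample identifiers. Duplicate gene identifiers must be
#' collapsed before construction (see \code{\link{read_expression}}).
#'
#' @param values numeric matrix, genes in rows; rownames = gene ids,
#'   colnames = sample ids
#' @return an object of class \code{ExpressionMatrix}
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix; collapse first")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values after load")
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Construct a SampleAnnotation table
#'
#' One row per sample with donor age (numeric years or ordinal bracket rank)
#' and a free-text tissue label.
#'
#' @param sample_id,age,tissue vectors of equal length; \code{age} may hold
#'   numeric years or bracket strings such as \code{"50-59"}
#' @return data.frame of class \code{SampleAnnotation} with columns
#'   \code{sample_id, age_value, age_rank, tissue}
#' @export
sample_annotation <- function(sample_id, age, tissue) {
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in annotation")
  parsed <- parse_ages(age)
  out <- data.frame(sample_id = as.character(sample_id),
                    age_value = parsed$age_value,
                    age_rank = parsed$age_rank,
                    tissue = as.character(tissue),
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleAnnotation", "data.frame")
  out
}

#' Construct a TreatmentProfileSet
#'
#' Genes x profiles matrix of signed (moderated z-score scale) differential
#' expression values, plus per-profile metadata identifying drug, cell line,
#' dose, time and replicate group.
#'
#' @param z numeric matrix (genes x profiles); rownames = gene ids,
#'   colnames = profile ids
#' @param meta data.frame with columns \code{profile_id, drug, cell_line,
#'   dose, time, replicate_group}, one row per column of \code{z}
#' @return object of class \code{TreatmentProfileSet}
#' @export
treatment_profile_set <- function(z, meta) {
  z <- as.matrix(z)
  need <- c("profile_id", "drug", "cell_line", "dose", "time", "replicate_group")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("profile metadata missing columns: ", paste(miss, collapse = ", "))
  if (is.null(rownames(z)) || is.null(colnames(z)))
    stop("z matrix needs gene rownames and profile colnames")
  meta <- meta[match(colnames(z), meta$profile_id), need, drop = FALSE]
  if (anyNA(meta$profile_id))
    stop("metadata does not cover every profile in the z matrix")
  if (any(!is.finite(z)))
    stop("z values must be finite")
  rownames(meta) <- NULL
  structure(list(z = z, gene_ids = rownames(z),
                 profile_ids = colnames(z), meta = meta),
            class = "TreatmentProfileSet")
}

#' @export
print.TreatmentProfileSet <- function(x, ...) {
  cat(sprintf("TreatmentProfileSet: %d genes x %d profiles (%d replicate groups, %d drugs)\n",
              nrow(x$z), ncol(x$z),
              length(unique(x$meta$replicate_group)),
              length(unique(x$meta$drug))))
  invisible(x)
}

#' Construct a ternary (+1/0/-1) gene signature
#'
#' The common currency of the framework: per-gene calls over a fixed gene
#' universe, +1 for up / positively age-correlated, -1 for down / negatively
#' age-correlated, 0 otherwise.
#'
#' @param values integer vector in \{-1, 0, +1\} named by gene id
#' @param provenance \code{"aging"} or \code{"drug"}
#' @return object of class \code{TernarySignature}
#' @export
ternary_signature <- function(values, provenance = c("aging", "drug")) {
  provenance <- match.arg(provenance)
  nm <- names(values)
  if (is.null(nm)) stop("signature values must be named by gene id")
  values <- as.integer(values)
  if (!all(values %in% c(-1L, 0L, 1L))) stop("signature values must be in {-1, 0, +1}")
  structure(list(values = stats::setNames(values, nm),
                 universe = nm,
                 provenance = provenance,
                 n_pos = sum(values == 1L),
                 n_neg = sum(values == -1L)),
            class = "TernarySignature")
}

#' @export
print.TernarySignature <- function(x, ...) {
  cat(sprintf("TernarySignature (%s): %d genes, %d up (+1), %d down (-1)\n",
              x$provenance, length(x$values), x$n_pos, x$n_neg))
  invisible(x)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (members)
#' @param descriptions optional character vector parallel to \code{sets}
#' @return object of class \code{GeneSetCollection}
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup)) stop("duplicate gene-set name: ", dup[[1L]])
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  structure(list(sets = sets,
                 descriptions = descriptions %||% stats::setNames(rep("", length(sets)), names(sets))),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (median size %d)\n",
              length(x$sets), as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}
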