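#' Read a GCT 1.2 / 1.3 file into a numeric matrix
#'
#' Returns the value matrix with gene ids as rownames and column ids as
#' colnames. Row/column metadata beyond identifiers (GCT 1.3) is skipped:
#' profile metadata travels in a sidecar table in this package.
#'
#' @param path path to a \code{.gct} file
#' @return numeric matrix
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  ver <- readLines(con, n = 1L)
  if (!grepl("^#1\\.[23]", ver)) stop("not a GCT 1.2/1.3 file: ", path)
  dims <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
  nr <- as.integer(dims[[1L]]); nc <- as.integer(dims[[2L]])
  n_rmeta <- if (grepl("^#1\\.3", ver) && length(dims) >= 4L) as.integer(dims[[3L]]) else 0L
  n_cmeta <- if (grepl("^#1\\.3", ver) && length(dims) >= 4L) as.integer(dims[[4L]]) else 0L
  header <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
  id_cols <- if (grepl("^#1\\.2", ver)) 2L else 1L + n_rmeta
  col_ids <- utils::tail(header, nc)
  if (n_cmeta > 0L) readLines(con, n = n_cmeta)  # column metadata rows
  body <- utils::read.table(con, sep = "\t", header = FALSE,
                            colClasses = c(rep("character", id_cols),
                                           rep("numeric", nc)),
                            quote = "", comment.char = "")
  if (nrow(body) != nr || ncol(body) != id_cols + nc)
    stop("GCT dimension mismatch: header says ", nr, "x", nc, " in ", path)
  values <- as.matrix(body[, (id_cols + 1L):(id_cols + nc), drop = FALSE])
  dimnames(values) <- list(body[[1L]], col_ids)
  values
}

#' Write a numeric matrix as GCT 1.2
#'
#' @param values numeric matrix with row/col names
#' @param path output path
#' @param descriptions optional per-row description column (defaults to the
#'   gene id)
#' @export
write_gct <- function(values, path, descriptions = rownames(values)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
  writeLines(paste(c("NAME", "Description", colnames(values)), collapse = "\t"), con)
  body <- cbind(rownames(values), descriptions,
                format(values, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

find_gctx_helper <- function() {
  helper <- system.file("python", "gctx_convert.py", package = "drugaging")
  python <- Sys.which("python")
  if (helper == "" || python == "")
    stop("GCTX support needs the bundled converter and a `python` with h5py on PATH")
  list(python = python, helper = helper)
}

#' Read a GCTX (HDF5) matrix
#'
#' Converts through the bundled Python/h5py helper (the cmap GCTX layout is
#' HDF5) and parses the resulting GCT text.
#'
#' @param path path to a \code{.gctx} file
#' @return numeric matrix with gene rownames and column ids
#' @export
read_gctx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  h <- find_gctx_helper()
  tmp <- tempfile(fileext = ".gct")
  on.exit(unlink(tmp))
  status <- system2(h$python, c(h$helper, "to-gct", shQuote(path), shQuote(tmp)))
  if (status != 0L || !file.exists(tmp)) stop("GCTX conversion failed for ", path)
  read_gct(tmp)
}

#' Write a numeric matrix as GCTX
#'
#' @inheritParams write_gct
#' @export
write_gctx <- function(values, path) {
  h <- find_gctx_helper()
  tmp <- tempfile(fileext = ".gct")
  on.exit(unlink(tmp))
  write_gct(values, tmp)
  status <- system2(h$python, c(h$helper, "to-gctx", shQuote(tmp), shQuote(path)))
  if (status != 0L) stop("GCTX conversion failed writing ", path)
  invisible(path)
}
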