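`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a structured log line
#'
#' Logging goes through \code{message()} so it can be suppressed or sunk by
#' callers; every pipeline stage reports one line with its counts.
#'
#' @param stage short stage label
#' @param ... values pasted into the message
#' @keywords internal
da_log <- function(stage, ...) {
  message(sprintf("[drugaging:%s] %s", stage, paste0(...)))
}

#' Derive a reproducible sub-seed from a master seed and string keys
#'
#' Used for per-pair permutation substreams so that pairs can be scored in any
#' order (or in parallel) with bit-identical results. The hash is a simple
#' 32-bit polynomial rolling hash of the key string mixed with the master
#' seed; the result is always a valid R integer seed in [0, 2^31 - 2].
#'
#' @param seed master integer seed
#' @param ... character/numeric key components (e.g. drug, tissue)
#' @return a single integer seed
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(key)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

#' Average-rank transform of the rows of a matrix
#' @keywords internal
row_ranks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}

## Parse donor ages that may be numeric years ("43") or GTEx-style decade
## brackets ("40-49"). Returns a data.frame with the numeric display value
## (bracket midpoint) and the ordinal rank value actually used for the
## rank-based correlation. Unparseable entries yield NA in both columns.
parse_ages <- function(age) {
  age <- as.character(age)
  bracket <- grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", age)
  numeric_ok <- suppressWarnings(!is.na(as.numeric(age)))
  value <- rep(NA_real_, length(age))
  value[numeric_ok] <- as.numeric(age[numeric_ok])
  if (any(bracket)) {
    lo <- as.numeric(sub("-.*$", "", age[bracket]))
    hi <- as.numeric(sub("^.*-", "", age[bracket]))
    value[bracket] <- (lo + hi) / 2
  }
  data.frame(age_value = value, age_rank = rank(value, ties.method = "average", na.last = "keep"))
}
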