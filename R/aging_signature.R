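#' Per-gene Spearman correlation with donor age
#'
#' For every gene, computes the Spearman rank correlation between its
#' expression across samples and the donors' ages, with average ranks for
#' ties and a two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom.
#' Genes with zero expression variance get \eqn{\rho = 0, p = 1} so the
#' table stays total and such genes stay at 0 in the signature.
#'
#' @param expr an \code{\link{expression_matrix}}
#' @param annotation a \code{\link{sample_annotation}} covering
#'   \code{expr}'s samples
#' @return data.frame (class \code{CorrelationTable}) with columns
#'   \code{gene, rho, p_value, n}
#' @export
spearman_age_correlation <- function(expr, annotation) {
  idx <- match(expr$sample_ids, annotation$sample_id)
  if (anyNA(idx)) stop("annotation does not cover every sample in the matrix")
  age_rank <- annotation$age_rank[idx]
  n <- length(age_rank)
  if (n < 3L) stop("need at least 3 samples with age for correlation")
  if (length(unique(age_rank)) < 2L) stop("constant age vector: correlation undefined")

  gr <- row_ranks(expr$values)
  gr_c <- gr - rowMeans(gr)
  a_c <- age_rank - mean(age_rank)
  gene_ss <- rowSums(gr_c^2)
  denom <- sqrt(gene_ss * sum(a_c^2))
  rho <- as.vector(gr_c %*% a_c) / denom
  degenerate <- gene_ss == 0
  rho[degenerate] <- 0
  rho <- pmin(1, pmax(-1, rho))

  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) == 1] <- 0
  p[degenerate] <- 1

  out <- data.frame(gene = expr$gene_ids, rho = rho, p_value = p, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("CorrelationTable", "data.frame")
  out
}

#' Build the ternary aging-associated signature
#'
#' Primary rule: a gene is +1 if \code{rho > rho_cut} and
#' \code{p < p_cut}, -1 if \code{rho < -rho_cut} and \code{p < p_cut},
#' otherwise 0. Small tissues can yield very few signature genes under the
#' primary rule; when the total selected falls below \code{min_total} the
#' signature instead takes the \code{fallback_k} genes with the strongest
#' positive correlations (+1) and the \code{fallback_k} with the strongest
#' negative (-1), ranked by rho with lexicographic gene-id tie-breaks.
#'
#' @param corr a \code{CorrelationTable} from
#'   \code{\link{spearman_age_correlation}}
#' @param rho_cut,p_cut primary-rule thresholds (defaults 0.2 and 0.05)
#' @param fallback_k genes taken per direction when the fallback triggers
#'   (default 500)
#' @param min_total fallback trigger: fall back when fewer than this many
#'   genes pass the primary rule (default 1000)
#' @return a \code{\link{ternary_signature}} with provenance \code{"aging"};
#'   attribute \code{fallback} records whether the fallback fired
#' @export
build_aging_signature <- function(corr, rho_cut = 0.2, p_cut = 0.05,
                                  fallback_k = 500, min_total = 1000) {
  pos <- corr$rho > rho_cut & corr$p_value < p_cut
  neg <- corr$rho < -rho_cut & corr$p_value < p_cut
  vals <- integer(nrow(corr))
  vals[pos] <- 1L
  vals[neg] <- -1L
  used_fallback <- FALSE
  if (sum(pos) + sum(neg) < min_total) {
    if (nrow(corr) < 2L * fallback_k)
      stop("universe (", nrow(corr), " genes) smaller than 2*fallback_k = ",
           2L * fallback_k, "; use a smaller fallback_k")
    used_fallback <- TRUE
    ord_desc <- order(-corr$rho, corr$gene)
    ord_asc <- order(corr$rho, corr$gene)
    vals <- integer(nrow(corr))
    pos_idx <- ord_desc[seq_len(fallback_k)]
    # heavily tied rho can make the two directions collide; the positive
    # side wins and the negative side fills from the remaining genes
    neg_idx <- setdiff(ord_asc, pos_idx)[seq_len(fallback_k)]
    vals[pos_idx] <- 1L
    vals[neg_idx] <- -1L
    da_log("aging", "fallback triggered: top ", fallback_k,
           " per direction (primary rule selected ", sum(pos) + sum(neg), ")")
  }
  sig <- ternary_signature(stats::setNames(vals, corr$gene), provenance = "aging")
  attr(sig, "fallback") <- used_fallback
  sig
}

#' Export an RNK-style ranked gene list
#'
#' Writes genes sorted by correlation coefficient, descending, with equal
#' coefficients broken lexicographically by gene id — the two-column
#' tab-separated dialect accepted by ranked-list enrichment tools.
#'
#' @param corr a \code{CorrelationTable}
#' @param path output path
#' @return the path, invisibly
#' @export
export_ranked_list <- function(corr, path) {
  if (nrow(corr) == 0L) stop("empty correlation table")
  ord <- order(-corr$rho, corr$gene)
  utils::write.table(corr[ord, c("gene", "rho")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
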