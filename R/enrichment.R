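#' Fisher's-exact overrepresentation of a gene list against a collection
#'
#' For each gene set, forms the 2x2 table of membership (query vs set) over
#' the shared gene universe and reports the one-sided (enrichment-only)
#' hypergeometric tail p-value \eqn{P(X \ge k)}, the odds ratio from the
#' 2x2 table (with a Haldane correction of 0.5 added to every cell when any
#' cell is zero), and a Benjamini-Hochberg q-value across the sets tested.
#' The background is the shared expression/profile gene universe, not the
#' full genome, since all signatures live on that intersection space.
#'
#' @param query_genes character vector, a subset of \code{universe}
#' @param sets a \code{\link{gene_set_collection}}
#' @param universe character vector of background gene ids
#' @param quadrant optional label attached to every record; sets ending in
#'   \code{"_down"} flip the sign of \code{signed_or} for the signed
#'   red/blue-bar presentation
#' @param keep_zero_hits include sets with no query hits (k = 0, p = 1)?
#'   Default drops them.
#' @return data.frame with columns \code{set_name, quadrant, k, K, n, N,
#'   odds_ratio, signed_or, p_value, q_value}
#' @export
fisher_enrich <- function(query_genes, sets, universe, quadrant = NA_character_,
                          keep_zero_hits = FALSE) {
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0L) stop("empty query gene list")
  extra <- setdiff(query_genes, universe)
  if (length(extra))
    stop("query contains genes outside the universe, e.g. ", extra[[1L]])
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(sets$sets), function(set_name) {
    members <- intersect(sets$sets[[set_name]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query_genes, members))
    if (k == 0L && !keep_zero_hits) return(NULL)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    # 2x2: (in query & in set, in query & out, out & in set, out & out)
    a <- k; b <- n - k; c <- K - k; d <- N - K - (n - k)
    if (any(c(a, b, c, d) == 0L)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c)
    data.frame(set_name = set_name, quadrant = quadrant,
               k = k, K = K, n = n, N = N,
               odds_ratio = or,
               signed_or = if (isTRUE(grepl("_down$", quadrant))) -or else or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(), quadrant = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      odds_ratio = numeric(), signed_or = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Extract the four overlap-quadrant gene lists from an interaction record
#'
#' The shared genes of a scored (drug, tissue) pair partition into four
#' quadrants by direction: drug-up & age-up (\code{concordant_up}),
#' drug-down & age-down (\code{concordant_down}), drug-up & age-down
#' (\code{discordant_up}), drug-down & age-up (\code{discordant_down}).
#'
#' @param record an \code{InteractionRecord}
#' @return named list of four character vectors
#' @export
quadrant_queries <- function(record) {
  record$quadrants[c("concordant_up", "concordant_down",
                     "discordant_up", "discordant_down")]
}

#' Enrich an interaction record's overlap genes
#'
#' Runs \code{\link{fisher_enrich}} either per quadrant (default, the
#' signed-bar presentation) or on the pooled overlap.
#'
#' @param record an \code{InteractionRecord}
#' @param sets a \code{GeneSetCollection}
#' @param universe background gene ids
#' @param pooled pool the four quadrants into one query? (default FALSE)
#' @return data.frame of enrichment records (empty quadrants skipped)
#' @export
enrich_record <- function(record, sets, universe, pooled = FALSE) {
  quads <- quadrant_queries(record)
  if (pooled) {
    pool <- unique(unlist(quads, use.names = FALSE))
    return(fisher_enrich(pool, sets, universe, quadrant = "pooled"))
  }
  out <- lapply(names(quads), function(q) {
    if (length(quads[[q]]) == 0L) return(NULL)
    fisher_enrich(quads[[q]], sets, universe, quadrant = q)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("all overlap quadrants are empty for this record")
  res
}
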