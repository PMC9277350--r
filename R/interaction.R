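check_same_universe <- function(r, z) {
  if (!identical(r$universe, z$universe))
    stop("signatures are not on the same gene universe")
}

#' Specificity score between an aging and a drug signature
#'
#' The fraction of aging-signature genes (nonzero entries of r) that are
#' also drug-signature genes (nonzero entries of z):
#' \deqn{S = \sum_i 1[r_i \neq 0] 1[z_i \neq 0] / \sum_i 1[r_i \neq 0]}
#' Direction is ignored; S measures overlap only and lies in [0, 1].
#'
#' @param r aging \code{\link{ternary_signature}}
#' @param z drug \code{\link{ternary_signature}} on the same universe
#' @return scalar specificity in [0, 1]
#' @export
compute_specificity <- function(r, z) {
  check_same_universe(r, z)
  n_aging <- sum(r$values != 0L)
  if (n_aging == 0L) stop("aging signature has no nonzero genes (S undefined)")
  sum(r$values != 0L & z$values != 0L) / n_aging
}

#' Concordance of shared genes between two ternary signatures
#'
#' Among genes in both signatures, counts those changing in the same
#' direction (drug-up and age-up, or drug-down and age-down) versus
#' opposite directions. The raw concordance ratio
#' \eqn{CR = n_{conc} / n_{disc}} is infinite when there are no discordant
#' genes, which is why all downstream inference uses the adjusted ratio
#' \eqn{adjCR = (n_{conc} + 1) / (n_{disc} + 1)} with a pseudocount of 1 in
#' both numerator and denominator.
#'
#' @inheritParams compute_specificity
#' @return list with \code{n_concordant}, \code{n_discordant}, \code{cr}
#'   (may be \code{Inf}), \code{cr_infinite} flag, \code{adj_cr}, and
#'   \code{quadrants}: gene lists \code{concordant_up} (drug-up, age-up),
#'   \code{concordant_down}, \code{discordant_up} (drug-up, age-down),
#'   \code{discordant_down} (drug-down, age-up)
#' @export
compute_concordance <- function(r, z) {
  check_same_universe(r, z)
  rv <- r$values; zv <- z$values
  prod_sign <- rv * zv
  n_conc <- sum(prod_sign > 0L)
  n_disc <- sum(prod_sign < 0L)
  genes <- r$universe
  quadrants <- list(
    concordant_up = genes[zv == 1L & rv == 1L],
    concordant_down = genes[zv == -1L & rv == -1L],
    discordant_up = genes[zv == 1L & rv == -1L],
    discordant_down = genes[zv == -1L & rv == 1L]
  )
  list(n_concordant = n_conc,
       n_discordant = n_disc,
       cr = if (n_disc == 0L) Inf else n_conc / n_disc,
       cr_infinite = n_disc == 0L,
       adj_cr = (n_conc + 1) / (n_disc + 1),
       quadrants = quadrants)
}

## Sample the null distribution of (n_concordant, n_discordant) under
## independent re-randomization of both label vectors with (n_pos, n_neg)
## preserved. The sign-overlap table of two independently placed label
## vectors is multivariate hypergeometric, so the counts are drawn by
## sequential rhyper calls -- exactly equivalent in distribution to
## shuffling both full vectors, at O(1) per permutation.
sample_null_counts <- function(n, r_pos, r_neg, z_pos, z_neg, n_perm) {
  x_pp <- stats::rhyper(n_perm, r_pos, n - r_pos, z_pos)
  x_pn <- stats::rhyper(n_perm, r_neg, n - r_pos - r_neg, z_pos - x_pp)
  x_np <- stats::rhyper(n_perm, r_pos - x_pp, n - z_pos - (r_pos - x_pp), z_neg)
  x_nn <- stats::rhyper(n_perm, r_neg - x_pn,
                        n - z_pos - (r_pos - x_pp) - (r_neg - x_pn), z_neg - x_np)
  list(concordant = x_pp + x_nn, discordant = x_pn + x_np)
}

#' Permutation test for the adjusted concordance ratio
#'
#' Builds the null by re-randomizing, in each permutation, which genes carry
#' the +1 and -1 labels of both signatures — uniformly over the universe,
#' preserving each signature's (n_pos, n_neg) — and recomputing the adjusted
#' concordance ratio. A normal distribution is fitted to the permuted values
#' by sample mean and standard deviation, and a two-sided p-value
#' \eqn{2\,\min(\Phi(t), 1 - \Phi(t))} with \eqn{t = (obs - \mu)/\sigma}
#' is returned; the direction of the effect is then read from adjCR vs 1.
#' Re-randomizing both signatures and re-randomizing only one give the same
#' null distribution (only the relative placement of labels matters), so
#' \code{permute = "one"} is provided for interface symmetry and documented
#' as coinciding with \code{"both"}.
#'
#' @inheritParams compute_specificity
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed; results are bit-reproducible given
#'   \code{(seed, n_perm)}
#' @param null fit the normal on the raw adjCR scale (\code{"raw"}, default)
#'   or on log(adjCR) (\code{"log"}; a ratio statistic is right-skewed)
#' @param permute \code{"both"} or \code{"one"} (identical null; see above)
#' @return list with \code{p_value}, \code{null_mean}, \code{null_sd},
#'   \code{obs_adj_cr}, \code{n_perm}, \code{seed}, \code{perm_values}
#' @export
permutation_test <- function(r, z, n_perm = 10000, seed = 1L,
                             null = c("raw", "log"),
                             permute = c("both", "one")) {
  check_same_universe(r, z)
  null <- match.arg(null)
  permute <- match.arg(permute)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  obs <- compute_concordance(r, z)$adj_cr
  n <- length(r$values)

  counts <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample_null_counts(n, r$n_pos, r$n_neg, z$n_pos, z$n_neg, n_perm)
  })
  perm_adj_cr <- (counts$concordant + 1) / (counts$discordant + 1)
  stat <- if (null == "log") log(perm_adj_cr) else perm_adj_cr
  obs_stat <- if (null == "log") log(obs) else obs
  mu <- mean(stat)
  sdv <- stats::sd(stat)
  if (!is.finite(sdv) || sdv == 0) {
    warning("degenerate permutation null (sd = 0); p-value set to 1")
    p <- 1
  } else {
    tt <- (obs_stat - mu) / sdv
    p <- min(1, 2 * min(stats::pnorm(tt), stats::pnorm(tt, lower.tail = FALSE)))
  }
  list(p_value = p, null_mean = mu, null_sd = sdv, obs_adj_cr = obs,
       n_perm = n_perm, seed = seed, null_scale = null,
       perm_values = perm_adj_cr)
}

#' Score every matched (drug signature, aging signature) pair
#'
#' Pairs each drug signature's cell line with its matching tissue labels via
#' \code{tissue_cell_map}, then computes the specificity score, concordance
#' counts, adjusted concordance ratio and permutation p-value for each pair.
#' Each pair's permutation stream is seeded from
#' \code{\link{derive_seed}(seed, drug, cell_line, tissue)} so scoring order
#' does not affect results.
#'
#' @param aging_sigs named list: tissue label -> aging
#'   \code{TernarySignature}
#' @param drug_sigs named list: \code{"drug::cell_line"} -> drug
#'   \code{TernarySignature}
#' @param tissue_cell_map data.frame with columns \code{cell_line, tissue}
#' @param n_perm,seed,null passed to \code{\link{permutation_test}}
#' @return list of \code{InteractionRecord}s; see
#'   \code{\link{interaction_table}} for the tabular view
#' @export
score_all_pairs <- function(aging_sigs, drug_sigs, tissue_cell_map,
                            n_perm = 10000, seed = 1L, null = "raw") {
  if (nrow(tissue_cell_map) == 0L) stop("empty tissue-cell map")
  records <- list()
  for (key in names(drug_sigs)) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("drug signature names must be 'drug::cell_line', got: ", key)
    drug <- parts[[1L]]; cell <- parts[[2L]]
    tissues <- tissue_cell_map$tissue[tissue_cell_map$cell_line == cell]
    tissues <- intersect(tissues, names(aging_sigs))
    if (length(tissues) == 0L) {
      da_log("interact", "no matched tissue for cell line '", cell,
             "'; skipping ", drug)
      next
    }
    for (tissue in tissues) {
      r <- aging_sigs[[tissue]]
      z <- drug_sigs[[key]]
      s <- compute_specificity(r, z)
      conc <- compute_concordance(r, z)
      pt <- permutation_test(r, z, n_perm = n_perm,
                             seed = derive_seed(seed, drug, cell, tissue),
                             null = null)
      records[[length(records) + 1L]] <- structure(list(
        drug = drug, cell_line = cell, tissue = tissue,
        s = s,
        n_concordant = conc$n_concordant, n_discordant = conc$n_discordant,
        cr = conc$cr, cr_infinite = conc$cr_infinite, adj_cr = conc$adj_cr,
        p_value = pt$p_value, null_mean = pt$null_mean, null_sd = pt$null_sd,
        quadrants = conc$quadrants, call = NA_character_
      ), class = "InteractionRecord")
    }
  }
  if (length(records) == 0L) stop("no (drug, tissue) pairs could be matched")
  da_log("interact", length(records), " pairs scored")
  records
}

#' Tabular view of interaction records
#'
#' @param records list of \code{InteractionRecord}s
#' @return data.frame, one row per pair (quadrant gene lists omitted)
#' @export
interaction_table <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
    data.frame(drug = rec$drug, cell_line = rec$cell_line, tissue = rec$tissue,
               s = rec$s, n_concordant = rec$n_concordant,
               n_discordant = rec$n_discordant,
               cr = rec$cr, adj_cr = rec$adj_cr, p_value = rec$p_value,
               call = rec$call, stringsAsFactors = FALSE)
  }))
}

#' Call significant aging-accelerating / aging-protective events
#'
#' A pair is called \emph{accelerating} when S > \code{s_min}, adjCR >
#' \code{cr_hi} and p < \code{p_max}; \emph{protective} when S >
#' \code{s_min}, adjCR < \code{cr_lo} and p < \code{p_max}; otherwise
#' \emph{none} (the band [cr_lo, cr_hi] is a dead zone). A
#' Benjamini-Hochberg column is added for information only; calling uses the
#' raw p-values.
#'
#' @param records list of \code{InteractionRecord}s from
#'   \code{\link{score_all_pairs}}
#' @param s_min specificity threshold (default 0.45)
#' @param cr_lo,cr_hi adjusted-concordance-ratio dead zone (defaults 0.9,
#'   1.1)
#' @param p_max permutation p-value threshold (default 0.01)
#' @return list with \code{records} (calls filled in), \code{table}
#'   (full results incl. \code{p_bh}), and \code{edges}: the significant
#'   event edge table (drug, tissue, direction, s, adj_cr, p_value)
#' @export
call_significant <- function(records, s_min = 0.45, cr_lo = 0.9,
                             cr_hi = 1.1, p_max = 0.01) {
  for (i in seq_along(records)) {
    rec <- records[[i]]
    records[[i]]$call <-
      if (rec$s > s_min && rec$p_value < p_max && rec$adj_cr > cr_hi) "accelerating"
      else if (rec$s > s_min && rec$p_value < p_max && rec$adj_cr < cr_lo) "protective"
      else "none"
  }
  tab <- interaction_table(records)
  tab$p_bh <- stats::p.adjust(tab$p_value, method = "BH")
  sig <- tab[tab$call != "none", , drop = FALSE]
  edges <- data.frame(source = sig$drug, target = sig$tissue,
                      direction = sig$call, s = sig$s, adj_cr = sig$adj_cr,
                      p_value = sig$p_value, stringsAsFactors = FALSE)
  da_log("call", nrow(edges), " significant drug-aging events of ",
         nrow(tab), " pairs")
  list(records = records, table = tab, edges = edges)
}
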