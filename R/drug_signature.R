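#' Filter replicate groups by reproducibility
#'
#' Keeps replicate groups whose profiles agree: the median pairwise Spearman
#' correlation across a group's profiles (over all genes) must reach
#' \code{min_rep_corr}. Singleton groups carry no internal evidence of
#' reproducibility and are dropped unless \code{keep_singletons = TRUE}.
#'
#' @param profiles a \code{\link{treatment_profile_set}}
#' @param min_rep_corr minimum median pairwise Spearman rho (default 0.2)
#' @param keep_singletons keep replicate groups of size 1? (default FALSE)
#' @return filtered \code{TreatmentProfileSet}; attribute
#'   \code{group_median_rho} records the per-group medians
#' @export
filter_reproducible <- function(profiles, min_rep_corr = 0.2,
                                keep_singletons = FALSE) {
  groups <- split(seq_len(ncol(profiles$z)), profiles$meta$replicate_group)
  med <- vapply(groups, function(ix) {
    if (length(ix) < 2L) return(NA_real_)
    cm <- stats::cor(profiles$z[, ix, drop = FALSE], method = "spearman")
    stats::median(cm[upper.tri(cm)])
  }, numeric(1))
  keep_group <- ifelse(is.na(med), keep_singletons, med >= min_rep_corr)
  kept_cols <- sort(unlist(groups[keep_group], use.names = FALSE))
  da_log("drug", sum(keep_group), "/", length(groups),
         " replicate groups kept (median pairwise Spearman >= ", min_rep_corr, ")")
  if (length(kept_cols) == 0L)
    stop("no replicate group passed the reproducibility filter")
  out <- treatment_profile_set(profiles$z[, kept_cols, drop = FALSE],
                               profiles$meta[kept_cols, , drop = FALSE])
  attr(out, "group_median_rho") <- med
  out
}

#' Per-gene recurrence of significant change across experiments
#'
#' For one (drug, cell line) pair, counts in what fraction of retained
#' experiments each gene's z-score exceeds \code{z_cut} (up) or falls below
#' \code{-z_cut} (down). Thresholding is strict (\code{z > z_cut}), so a z
#' exactly at the cut does not count. All retained experiments for the pair
#' are pooled across dose and time.
#'
#' @param profiles a \code{TreatmentProfileSet} (typically after
#'   \code{\link{filter_reproducible}})
#' @param drug,cell_line the pair to tabulate
#' @param z_cut significance threshold on |z| (default 1)
#' @return data.frame (class \code{RecurrenceTable}) with columns
#'   \code{gene, frac_up, frac_down, n_experiments}
#' @export
recurrence <- function(profiles, drug, cell_line, z_cut = 1.0) {
  sel <- profiles$meta$drug == drug & profiles$meta$cell_line == cell_line
  if (!any(sel))
    stop("no experiments for drug '", drug, "' in cell line '", cell_line, "'")
  z <- profiles$z[, sel, drop = FALSE]
  n_exp <- ncol(z)
  out <- data.frame(gene = profiles$gene_ids,
                    frac_up = rowMeans(z > z_cut),
                    frac_down = rowMeans(z < -z_cut),
                    n_experiments = n_exp,
                    stringsAsFactors = FALSE)
  class(out) <- c("RecurrenceTable", "data.frame")
  out
}

#' Build the ternary drug-induced signature
#'
#' A gene enters the signature as +1 when it is significantly up in at least
#' \code{frac_cut} of the experiments (non-strict, "20% or more") and up more
#' often than down; symmetrically -1 for down. A gene passing in both
#' directions with an exact tie stays 0.
#'
#' @param rec a \code{RecurrenceTable} from \code{\link{recurrence}}
#' @param frac_cut minimum recurrence fraction (default 0.2)
#' @return a \code{\link{ternary_signature}} with provenance \code{"drug"}
#' @export
build_drug_signature <- function(rec, frac_cut = 0.2) {
  vals <- integer(nrow(rec))
  vals[rec$frac_up >= frac_cut & rec$frac_up > rec$frac_down] <- 1L
  vals[rec$frac_down >= frac_cut & rec$frac_down > rec$frac_up] <- -1L
  ternary_signature(stats::setNames(vals, rec$gene), provenance = "drug")
}
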