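#' Effect size needed for a target Spearman correlation with age
#'
#' The generator plants age effects as \code{effect * standardized(age)} on
#' top of Gaussian noise, so the Pearson correlation is
#' \eqn{effect / \sqrt{effect^2 + noise\_sd^2}}. For bivariate normal data
#' Spearman's rho relates to Pearson's r by
#' \eqn{\rho = (6/\pi) \arcsin(r/2)}; inverting both gives the effect that
#' yields a target Spearman rho in expectation. Verified empirically in the
#' test suite rather than assumed.
#'
#' @param rho target Spearman correlation
#' @param noise_sd residual standard deviation
#' @return the planting coefficient
#' @export
effect_for_rho <- function(rho, noise_sd = 1) {
  r <- 2 * sin(pi * rho / 6)
  noise_sd * r / sqrt(1 - r^2)
}

#' Simulate an age-annotated expression matrix with planted aging genes
#'
#' Donor ages are uniform over 20-71 years (the GTEx-like range). The first
#' \code{n_pos} genes rise with age and the next \code{n_neg} fall:
#' \code{baseline + sign * effect * standardized(age) + N(0, noise_sd)}.
#' All remaining genes are pure noise. With \code{bracket = TRUE} ages are
#' coarsened to decade brackets ("20-29", ...) to exercise the ordinal-age
#' path.
#'
#' @param n_genes,n_samples dimensions
#' @param n_pos,n_neg planted positively / negatively age-correlated genes
#' @param effect planting coefficient (see \code{\link{effect_for_rho}})
#' @param noise_sd residual standard deviation
#' @param seed integer seed (byte-identical output for equal seeds)
#' @param baseline additive expression baseline
#' @param bracket report ages as decade brackets instead of years
#' @param gene_ids optional gene identifiers (default \code{G00001}, ...)
#' @param tissue tissue label written into the annotation
#' @return list with \code{expr}, \code{annotation}, and \code{truth}
#'   (planted \code{pos_genes}/\code{neg_genes}, parameters, seed)
#' @export
simulate_expression <- function(n_genes = 2000, n_samples = 200,
                                n_pos = 150, n_neg = 150,
                                effect = effect_for_rho(0.5), noise_sd = 1,
                                seed = 1L, baseline = 10, bracket = FALSE,
                                gene_ids = NULL, tissue = "synthetic_tissue") {
  if (n_pos + n_neg > n_genes)
    stop("n_pos + n_neg exceeds n_genes: impossible partition")
  if (effect < 0) stop("effect must be >= 0")
  gene_ids <- gene_ids %||% sprintf("G%05d", seq_len(n_genes))
  set.seed(seed)
  age <- stats::runif(n_samples, 20, 71)
  age_std <- as.vector(scale(age))
  signs <- c(rep(1, n_pos), rep(-1, n_neg), rep(0, n_genes - n_pos - n_neg))
  values <- baseline +
    outer(signs * effect, age_std) +
    matrix(stats::rnorm(n_genes * n_samples, sd = max(noise_sd, 1e-12)),
           n_genes, n_samples)
  dimnames(values) <- list(gene_ids, sprintf("S%04d", seq_len(n_samples)))
  ann_age <- if (bracket) {
    lo <- pmin(floor(age / 10) * 10, 70)
    sprintf("%d-%d", lo, lo + 9)
  } else age
  ann <- sample_annotation(colnames(values), ann_age, rep(tissue, n_samples))
  truth <- list(pos_genes = gene_ids[seq_len(n_pos)],
                neg_genes = gene_ids[n_pos + seq_len(n_neg)],
                effect = effect, noise_sd = noise_sd, seed = seed,
                tissue = tissue)
  list(expr = expression_matrix(values), annotation = ann, truth = truth)
}

#' Simulate replicate z-score profiles with planted recurrent genes
#'
#' Experiments come in replicate groups sharing one planted activity
#' pattern: within a group each planted up/down gene is "active" with
#' probability \code{recur_frac}; active genes draw
#' \code{N(+z_effect, 1)} / \code{N(-z_effect, 1)} in every profile of the
#' group, all other gene/profile cells draw \code{N(0, 1)}.
#'
#' With \code{group_sd > 0} every replicate group additionally shares a
#' dense latent response vector drawn \code{N(0, group_sd)} per gene, added
#' to all of its profiles. This emulates the genome-wide treatment response
#' that makes real L1000 replicates correlate with each other well beyond
#' their eventual signature genes; with the default \code{group_sd = 0}
#' null genes are exactly \code{N(0, 1)}, which the closed-form
#' false-call-rate checks rely on.
#'
#' @param up_genes,down_genes planted recurrently up/down gene ids
#' @param gene_ids the full gene id vector of the profile space
#' @param drug,cell_line metadata written into every profile
#' @param n_groups number of replicate groups
#' @param rep_size profiles per replicate group
#' @param recur_frac probability a planted gene is active in a group
#' @param z_effect mean |z| of active planted genes
#' @param seed integer seed
#' @param group_sd standard deviation of the shared per-group latent
#'   response (default 0: none)
#' @param dose,time metadata constants
#' @return a \code{\link{treatment_profile_set}}
#' @export
simulate_profiles <- function(up_genes, down_genes, gene_ids,
                              drug = "drugA", cell_line = "CELL",
                              n_groups = 10, rep_size = 3,
                              recur_frac = 0.6, z_effect = 2, seed = 1L,
                              group_sd = 0, dose = "10uM", time = "24h") {
  if (recur_frac <= 0 || recur_frac > 1) stop("recur_frac must be in (0, 1]")
  stopifnot(all(c(up_genes, down_genes) %in% gene_ids))
  n_genes <- length(gene_ids)
  set.seed(seed)
  cols <- list(); meta <- list()
  sign_vec <- stats::setNames(numeric(n_genes), gene_ids)
  for (g in seq_len(n_groups)) {
    active_up <- up_genes[stats::runif(length(up_genes)) < recur_frac]
    active_dn <- down_genes[stats::runif(length(down_genes)) < recur_frac]
    mu <- sign_vec
    mu[active_up] <- z_effect
    mu[active_dn] <- -z_effect
    if (group_sd > 0) mu <- mu + stats::rnorm(n_genes, sd = group_sd)
    for (rp in seq_len(rep_size)) {
      pid <- sprintf("%s_%s_g%02d_r%d", drug, cell_line, g, rp)
      cols[[pid]] <- mu + stats::rnorm(n_genes)
      meta[[pid]] <- data.frame(profile_id = pid, drug = drug,
                                cell_line = cell_line, dose = dose,
                                time = time,
                                replicate_group = sprintf("%s_%s_g%02d", drug, cell_line, g),
                                stringsAsFactors = FALSE)
    }
  }
  z <- do.call(cbind, cols)
  rownames(z) <- gene_ids
  treatment_profile_set(z, do.call(rbind, meta))
}

#' Combine several profile sets on a shared gene space
#'
#' @param ... \code{TreatmentProfileSet}s with identical gene id vectors
#' @return one combined \code{TreatmentProfileSet}
#' @export
combine_profile_sets <- function(...) {
  sets <- list(...)
  gid <- sets[[1L]]$gene_ids
  for (s in sets) if (!identical(s$gene_ids, gid))
    stop("profile sets disagree on gene ids")
  treatment_profile_set(do.call(cbind, lapply(sets, `[[`, "z")),
                        do.call(rbind, lapply(sets, `[[`, "meta")))
}

#' Noiseless ternary signature from planted gene memberships
#'
#' @param up_genes,down_genes planted memberships (disjoint)
#' @param gene_ids full universe
#' @param provenance \code{"aging"} or \code{"drug"}
#' @return a \code{TernarySignature} encoding the planted truth exactly
#' @export
truth_signature <- function(up_genes, down_genes, gene_ids,
                            provenance = "aging") {
  if (length(intersect(up_genes, down_genes)))
    stop("planted up and down sets must be disjoint")
  vals <- stats::setNames(integer(length(gene_ids)), gene_ids)
  vals[up_genes] <- 1L
  vals[down_genes] <- -1L
  ternary_signature(vals, provenance = provenance)
}

#' Small synthetic study preset
#'
#' One tissue, one cell line, three planted drugs: one concordant with the
#' planted aging signature, one anti-concordant, one independent (planted
#' among null genes). Sizes are chosen so the whole recovery loop runs in
#' seconds: 2,000 genes, 200 donors, 250+250 planted aging genes at
#' Spearman rho about 0.5; per drug, 200+200 planted genes over 10
#' replicate groups of 3 profiles with 60\% recurrence at |z| effect 3 —
#' strong enough that replicate groups agree, the regime the
#' reproducibility filter is designed to keep. The fallback trigger is 100
#' rather than the 1000 used at genome scale, since the 500+500 fallback is
#' half of this universe and should only fire if the primary rule nearly
#' fails.
#'
#' @return named list of generator and scoring parameters
#' @export
small_preset <- function() {
  list(n_genes = 2000, n_samples = 200, n_pos = 250, n_neg = 250,
       effect = effect_for_rho(0.5), noise_sd = 1,
       n_drug_up = 200, n_drug_down = 200,
       n_groups = 10, rep_size = 3, recur_frac = 0.6, z_effect = 3,
       n_perm = 1000,
       rho_cut = 0.2, p_cut = 0.05, fallback_k = 500, min_total = 100,
       z_cut = 1, frac_cut = 0.2, min_rep_corr = 0.2,
       s_min = 0.45, cr_lo = 0.9, cr_hi = 1.1, p_max = 0.01)
}

#' End-to-end recovery harness on planted synthetic data
#'
#' Simulates an expression matrix with planted aging genes and three drugs
#' (concordant / anti-concordant / independent relative to the planted aging
#' signature), runs the full chain — Spearman correlation, aging signature,
#' reproducibility filter, recurrence, drug signatures, specificity,
#' concordance, permutation test, event calling — and compares what is
#' recovered against the planted truth. Expected values (S, concordance
#' counts, adjusted CR) are computed analytically from the planted
#' memberships before any noise enters.
#'
#' @param config parameter list, see \code{\link{small_preset}}
#' @param seed integer seed
#' @return list with \code{truth} (incl. \code{expected_s},
#'   \code{expected_adj_cr} per drug on the noiseless signatures),
#'   \code{noiseless} (planted-signature scores), \code{results} (the
#'   called interaction table) and \code{pass} flags
#' @export
recovery_harness <- function(config = small_preset(), seed = 1L) {
  cfg <- config
  sim <- simulate_expression(cfg$n_genes, cfg$n_samples, cfg$n_pos, cfg$n_neg,
                             cfg$effect, cfg$noise_sd, seed = derive_seed(seed, "expr"))
  gid <- sim$expr$gene_ids
  null_genes <- setdiff(gid, c(sim$truth$pos_genes, sim$truth$neg_genes))

  plant <- list(
    concordant = list(up = sim$truth$pos_genes[seq_len(cfg$n_drug_up)],
                      down = sim$truth$neg_genes[seq_len(cfg$n_drug_down)]),
    anticoncordant = list(up = sim$truth$neg_genes[seq_len(cfg$n_drug_down)],
                          down = sim$truth$pos_genes[seq_len(cfg$n_drug_up)]),
    independent = list(up = null_genes[seq_len(cfg$n_drug_up)],
                       down = null_genes[cfg$n_drug_up + seq_len(cfg$n_drug_down)])
  )

  # analytic expectations on the noiseless planted signatures
  r_truth <- truth_signature(sim$truth$pos_genes, sim$truth$neg_genes, gid, "aging")
  noiseless <- lapply(names(plant), function(d) {
    z_truth <- truth_signature(plant[[d]]$up, plant[[d]]$down, gid, "drug")
    conc <- compute_concordance(r_truth, z_truth)
    list(drug = d, s = compute_specificity(r_truth, z_truth),
         n_concordant = conc$n_concordant, n_discordant = conc$n_discordant,
         adj_cr = conc$adj_cr)
  })
  names(noiseless) <- names(plant)
  n_overlap <- cfg$n_drug_up + cfg$n_drug_down
  expected <- list(
    expected_s = c(concordant = n_overlap / (cfg$n_pos + cfg$n_neg),
                   anticoncordant = n_overlap / (cfg$n_pos + cfg$n_neg),
                   independent = 0),
    expected_adj_cr = c(concordant = (n_overlap + 1) / 1,
                        anticoncordant = 1 / (n_overlap + 1),
                        independent = 1)
  )

  # noisy pipeline
  corr <- spearman_age_correlation(sim$expr, sim$annotation)
  r_hat <- build_aging_signature(corr, cfg$rho_cut, cfg$p_cut,
                                 cfg$fallback_k, cfg$min_total)
  profiles <- do.call(combine_profile_sets, lapply(names(plant), function(d) {
    simulate_profiles(plant[[d]]$up, plant[[d]]$down, gid, drug = d,
                      cell_line = "CELL", n_groups = cfg$n_groups,
                      rep_size = cfg$rep_size, recur_frac = cfg$recur_frac,
                      z_effect = cfg$z_effect, seed = derive_seed(seed, d))
  }))
  kept <- filter_reproducible(profiles, cfg$min_rep_corr)
  drug_sigs <- lapply(names(plant), function(d) {
    build_drug_signature(recurrence(kept, d, "CELL", cfg$z_cut), cfg$frac_cut)
  })
  names(drug_sigs) <- paste0(names(plant), "::CELL")
  map <- data.frame(cell_line = "CELL", tissue = sim$truth$tissue,
                    stringsAsFactors = FALSE)
  aging_sigs <- stats::setNames(list(r_hat), sim$truth$tissue)
  records <- score_all_pairs(aging_sigs, drug_sigs, map,
                             n_perm = cfg$n_perm, seed = seed)
  called <- call_significant(records, cfg$s_min, cfg$cr_lo, cfg$cr_hi, cfg$p_max)
  tab <- called$table

  pass <- list(
    s_exact_on_noiseless = all(vapply(names(plant), function(d)
      isTRUE(all.equal(noiseless[[d]]$s, unname(expected$expected_s[d]))), logical(1))),
    concordant_accelerating = tab$call[tab$drug == "concordant"] == "accelerating",
    anticoncordant_protective = tab$call[tab$drug == "anticoncordant"] == "protective",
    independent_none = tab$call[tab$drug == "independent"] == "none"
  )
  list(truth = c(sim$truth, expected, list(plant = plant)),
       noiseless = noiseless, results = tab, edges = called$edges,
       records = called$records, pass = pass)
}
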