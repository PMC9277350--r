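#' Default run configuration
#'
#' All thresholds of the framework with their default values: Spearman
#' rho cut 0.2 and p cut 0.05 with a 500+500 fallback (trigger: fewer than
#' 1000 primary-rule genes) for the aging signature; |z| > 1 recurrence in
#' at least 20\% of experiments with replicate median Spearman >= 0.2 for
#' the drug signature; S > 0.45, adjusted CR outside [0.9, 1.1] and
#' permutation p < 0.01 over 10,000 permutations for event calling.
#'
#' @param ... overrides for any field
#' @return named list (class \code{RunConfig})
#' @export
default_config <- function(...) {
  cfg <- list(
    expression = NULL, annotation = NULL,
    profiles = NULL, profile_meta = NULL,
    gmt = NULL, tissue_cell_map = NULL, out_dir = NULL,
    rho_cut = 0.2, p_cut = 0.05, fallback_k = 500, min_total = 1000,
    z_cut = 1, frac_cut = 0.2, min_rep_corr = 0.2, keep_singletons = FALSE,
    s_min = 0.45, cr_lo = 0.9, cr_hi = 1.1, p_max = 0.01,
    n_perm = 10000, seed = 1L, null = "raw",
    min_tissue_samples = 3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(x, lo, hi, name) {
    if (!is.numeric(cfg[[x]]) || cfg[[x]] < lo || cfg[[x]] > hi)
      stop("config ", x, " out of range [", lo, ", ", hi, "]")
  }
  chk("rho_cut", 0, 1); chk("p_cut", 0, 1); chk("frac_cut", 0, 1)
  chk("min_rep_corr", -1, 1); chk("s_min", 0, 1)
  chk("cr_lo", 0, Inf); chk("cr_hi", 0, Inf); chk("p_max", 0, 1)
  chk("z_cut", 0, Inf); chk("n_perm", 100, Inf)
  if (cfg$cr_lo > cfg$cr_hi) stop("config cr_lo must be <= cr_hi")
  structure(cfg, class = c("RunConfig", "list"))
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror \code{\link{default_config}}
#' @return validated \code{RunConfig}
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Write a run configuration as YAML
#'
#' @param cfg a \code{RunConfig}
#' @param path output path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

config_hash <- function(cfg) {
  derive_seed(0L, paste(deparse(cfg[order(names(cfg))]), collapse = ""))
}

resolve_expression <- function(cfg) {
  if (is.character(cfg$expression))
    read_expression(cfg$expression, cfg$annotation)
  else if (is.list(cfg$expression) && inherits(cfg$expression$expr, "ExpressionMatrix"))
    cfg$expression
  else stop("config `expression` must be a path or a list(expr, annotation)")
}

resolve_profiles <- function(cfg) {
  if (is.character(cfg$profiles))
    read_profiles(cfg$profiles, cfg$profile_meta)
  else if (inherits(cfg$profiles, "TreatmentProfileSet"))
    cfg$profiles
  else stop("config `profiles` must be a path or a TreatmentProfileSet")
}

resolve_map <- function(cfg) {
  m <- cfg$tissue_cell_map
  if (is.character(m))
    m <- utils::read.delim(m, stringsAsFactors = FALSE)
  if (!all(c("cell_line", "tissue") %in% names(m)))
    stop("tissue_cell_map needs columns cell_line, tissue")
  m
}

#' Run the full drug-aging interaction pipeline
#'
#' Orchestrates every stage from one configuration: load and harmonize the
#' expression and profile datasets onto their shared gene universe; build a
#' per-tissue aging signature (Spearman correlation with donor age, ternary
#' thresholding with fallback); filter profiles by replicate
#' reproducibility and build a per-(drug, cell line) ternary signature from
#' z-score recurrence; score every matched (drug, tissue) pair with the
#' specificity score and permutation-tested adjusted concordance ratio;
#' call significant accelerating/protective events; optionally enrich each
#' called event's overlap quadrants against a GMT collection. All outputs
#' and a JSON provenance manifest are written under \code{out_dir} when
#' given.
#'
#' @param config a \code{RunConfig} from \code{\link{default_config}} or
#'   \code{\link{read_config}}
#' @return list: \code{universe}, \code{aging_sigs}, \code{drug_sigs},
#'   \code{records}, \code{table}, \code{edges}, \code{enrichment},
#'   \code{manifest}
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  eb <- stage("load_expression", resolve_expression(cfg))
  profiles <- stage("load_profiles", resolve_profiles(cfg))
  universe <- stage("universe", intersect_universe(eb$expr, profiles))
  expr <- project_universe(eb$expr, universe)
  profiles <- project_universe(profiles, universe)

  # per-tissue aging signatures
  aging_sigs <- list(); corr_tables <- list()
  for (tis in unique(eb$annotation$tissue)) {
    ann_t <- eb$annotation[eb$annotation$tissue == tis, , drop = FALSE]
    if (nrow(ann_t) < cfg$min_tissue_samples) {
      da_log("aging", "tissue '", tis, "' skipped (", nrow(ann_t), " samples)")
      next
    }
    sub <- expression_matrix(expr$values[, ann_t$sample_id, drop = FALSE])
    ann_t$age_rank <- rank(ann_t$age_value, ties.method = "average")
    corr <- stage(paste0("aging:", tis), spearman_age_correlation(sub, ann_t))
    aging_sigs[[tis]] <- stage(paste0("aging:", tis),
      build_aging_signature(corr, cfg$rho_cut, cfg$p_cut, cfg$fallback_k, cfg$min_total))
    corr_tables[[tis]] <- corr
    da_log("aging", tis, ": ", aging_sigs[[tis]]$n_pos, " up / ",
           aging_sigs[[tis]]$n_neg, " down signature genes")
  }
  if (length(aging_sigs) == 0L) stop("pipeline stage 'aging' failed: no usable tissue")

  # per-(drug, cell) drug signatures
  kept <- stage("reproducibility",
                filter_reproducible(profiles, cfg$min_rep_corr, cfg$keep_singletons))
  pairs <- unique(kept$meta[, c("drug", "cell_line")])
  drug_sigs <- list(); rec_tables <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste0(pairs$drug[i], "::", pairs$cell_line[i])
    rec <- stage(paste0("drug:", key),
                 recurrence(kept, pairs$drug[i], pairs$cell_line[i], cfg$z_cut))
    drug_sigs[[key]] <- build_drug_signature(rec, cfg$frac_cut)
    rec_tables[[key]] <- rec
  }
  da_log("drug", length(drug_sigs), " drug signatures built")

  map <- stage("map", resolve_map(cfg))
  records <- stage("interaction",
                   score_all_pairs(aging_sigs, drug_sigs, map,
                                   n_perm = cfg$n_perm, seed = cfg$seed,
                                   null = cfg$null))
  called <- stage("calling",
                  call_significant(records, cfg$s_min, cfg$cr_lo, cfg$cr_hi, cfg$p_max))

  enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    sets <- if (is.character(cfg$gmt)) read_gmt(cfg$gmt) else cfg$gmt
    sig_recs <- Filter(function(r) r$call != "none", called$records)
    enrichment <- lapply(sig_recs, function(r)
      tryCatch(enrich_record(r, sets, universe), error = function(e) NULL))
    names(enrichment) <- vapply(sig_recs, function(r)
      paste(r$drug, r$tissue, sep = "__"), "")
  }

  manifest <- list(package = "drugaging",
                   version = as.character(utils::packageVersion("drugaging")),
                   seed = cfg$seed, n_perm = cfg$n_perm,
                   config_hash = config_hash(cfg),
                   n_universe = length(universe),
                   n_tissues = length(aging_sigs),
                   n_drug_signatures = length(drug_sigs),
                   n_pairs = length(called$records),
                   n_events = nrow(called$edges))

  result <- list(universe = universe, aging_sigs = aging_sigs,
                 corr_tables = corr_tables, drug_sigs = drug_sigs,
                 rec_tables = rec_tables, records = called$records,
                 table = called$table, edges = called$edges,
                 enrichment = enrichment, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_bundle(result, cfg$out_dir)
  result
}

write_bundle <- function(result, out_dir) {
  dir.create(file.path(out_dir, "aging_sigs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "drug_sigs"), showWarnings = FALSE)
  wt <- function(x, path) utils::write.table(x, path, sep = "\t", quote = FALSE,
                                             row.names = FALSE)
  for (tis in names(result$aging_sigs)) {
    corr <- result$corr_tables[[tis]]
    sig <- result$aging_sigs[[tis]]
    wt(data.frame(gene = corr$gene, rho = corr$rho, p = corr$p_value,
                  call = sig$values[corr$gene]),
       file.path(out_dir, "aging_sigs", paste0(gsub("[^A-Za-z0-9_.-]", "_", tis), ".tsv")))
  }
  for (key in names(result$drug_sigs)) {
    rec <- result$rec_tables[[key]]
    sig <- result$drug_sigs[[key]]
    wt(data.frame(gene = rec$gene, frac_up = rec$frac_up,
                  frac_down = rec$frac_down, call = sig$values[rec$gene]),
       file.path(out_dir, "drug_sigs", paste0(gsub("::", "__", key), ".tsv")))
  }
  utils::write.csv(result$table, file.path(out_dir, "interactions.csv"),
                   row.names = FALSE)
  wt(result$edges, file.path(out_dir, "events_edges.tsv"))
  if (!is.null(result$enrichment)) {
    dir.create(file.path(out_dir, "enrichment"), showWarnings = FALSE)
    for (key in names(result$enrichment)) {
      if (is.null(result$enrichment[[key]])) next
      utils::write.csv(result$enrichment[[key]],
                       file.path(out_dir, "enrichment", paste0(key, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Full-scale synthetic study preset
#'
#' Mirrors the shape (not the content) of a GTEx x LINCS study: about
#' 10,000 shared genes, 17 tissues (13 brain regions, skeletal muscle,
#' kidney cortex, two adipose depots) matched to 4 normal cell lines
#' (NPC = brain, SKL = muscle, HA1E = kidney, ASC = adipose), and 28 drugs
#' each profiled in one cell line, at small per-tissue sample counts so the
#' whole study simulates in seconds.
#'
#' @return named list of study parameters
#' @export
full_scale_preset <- function() {
  brain <- c("amygdala", "anterior_cingulate_cortex", "caudate",
             "cerebellar_hemisphere", "cerebellum", "cortex",
             "frontal_cortex", "hippocampus", "hypothalamus",
             "nucleus_accumbens", "putamen", "spinal_cord", "substantia_nigra")
  list(n_genes = 10000, n_samples_per_tissue = 30,
       n_pos = 300, n_neg = 300,
       effect = effect_for_rho(0.5), noise_sd = 1,
       tissues = c(brain, "muscle_skeletal", "kidney_cortex",
                   "adipose_subcutaneous", "adipose_visceral"),
       tissue_cell_map = data.frame(
         cell_line = c(rep("NPC", length(brain)), "SKL", "HA1E", "ASC", "ASC"),
         tissue = c(brain, "muscle_skeletal", "kidney_cortex",
                    "adipose_subcutaneous", "adipose_visceral"),
         stringsAsFactors = FALSE),
       cell_lines = c("NPC", "SKL", "HA1E", "ASC"),
       n_drugs = 28, n_drug_up = 150, n_drug_down = 150,
       n_groups = 4, rep_size = 2, recur_frac = 0.6, z_effect = 2,
       group_sd = 0.8)
}

#' Simulate a whole multi-tissue, multi-drug study
#'
#' Generates one expression matrix covering every tissue of the preset
#' (shared planted aging genes, tissue-specific noise), one combined
#' profile set covering every (drug, cell line), and the tissue-cell map.
#' One third of the drugs are planted concordant with the aging truth, one
#' third anti-concordant, one third on null genes.
#'
#' @param preset see \code{\link{full_scale_preset}}
#' @param seed integer seed
#' @return list with \code{expression} (list(expr, annotation)),
#'   \code{profiles}, \code{tissue_cell_map}, \code{truth}
#' @export
simulate_study <- function(preset = full_scale_preset(), seed = 1L) {
  p <- preset
  gid <- sprintf("G%05d", seq_len(p$n_genes))
  mats <- list(); anns <- list(); tissue_truth <- list()
  for (ti in seq_along(p$tissues)) {
    tis <- p$tissues[[ti]]
    sim <- simulate_expression(p$n_genes, p$n_samples_per_tissue,
                               p$n_pos, p$n_neg, p$effect, p$noise_sd,
                               seed = derive_seed(seed, "tissue", tis),
                               gene_ids = gid, tissue = tis)
    colnames(sim$expr$values) <- paste0(tis, "_", sim$expr$sample_ids)
    sim$annotation$sample_id <- colnames(sim$expr$values)
    mats[[tis]] <- sim$expr$values
    anns[[tis]] <- sim$annotation
    tissue_truth[[tis]] <- sim$truth
  }
  expr <- expression_matrix(do.call(cbind, mats))
  ann <- do.call(rbind, anns)
  rownames(ann) <- NULL
  class(ann) <- c("SampleAnnotation", "data.frame")

  null_genes <- setdiff(gid, c(tissue_truth[[1L]]$pos_genes,
                               tissue_truth[[1L]]$neg_genes))
  drug_truth <- list(); sets <- list()
  for (d in seq_len(p$n_drugs)) {
    drug <- sprintf("drug%02d", d)
    cell <- p$cell_lines[[(d - 1L) %% length(p$cell_lines) + 1L]]
    kind <- c("concordant", "anticoncordant", "independent")[[(d - 1L) %% 3L + 1L]]
    up_pool <- switch(kind,
                      concordant = tissue_truth[[1L]]$pos_genes,
                      anticoncordant = tissue_truth[[1L]]$neg_genes,
                      independent = null_genes[seq_len(p$n_drug_up)])
    dn_pool <- switch(kind,
                      concordant = tissue_truth[[1L]]$neg_genes,
                      anticoncordant = tissue_truth[[1L]]$pos_genes,
                      independent = null_genes[p$n_drug_up + seq_len(p$n_drug_down)])
    up <- up_pool[seq_len(min(p$n_drug_up, length(up_pool)))]
    dn <- dn_pool[seq_len(min(p$n_drug_down, length(dn_pool)))]
    drug_truth[[drug]] <- list(cell_line = cell, kind = kind, up = up, down = dn)
    sets[[drug]] <- simulate_profiles(up, dn, gid, drug = drug, cell_line = cell,
                                      n_groups = p$n_groups, rep_size = p$rep_size,
                                      recur_frac = p$recur_frac, z_effect = p$z_effect,
                                      group_sd = p$group_sd %||% 0,
                                      seed = derive_seed(seed, "drug", drug))
  }
  profiles <- do.call(combine_profile_sets, sets)
  list(expression = list(expr = expr, annotation = ann),
       profiles = profiles,
       tissue_cell_map = p$tissue_cell_map,
       truth = list(tissues = tissue_truth, drugs = drug_truth, seed = seed))
}

#' Write a simulated study to disk in the package's external formats
#'
#' Expression as GCT + annotation TSV, profiles as GCT + metadata TSV, the
#' tissue-cell map as TSV. Intended for exercising the file-based pipeline
#' path on small studies.
#'
#' @param study output of \code{\link{simulate_study}}
#' @param dir output directory (created)
#' @return named list of file paths
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(expression = file.path(dir, "expression.gct"),
                annotation = file.path(dir, "annotation.tsv"),
                profiles = file.path(dir, "profiles.gct"),
                profile_meta = file.path(dir, "profile_meta.tsv"),
                tissue_cell_map = file.path(dir, "tissue_cell_map.tsv"))
  write_gct(study$expression$expr$values, paths$expression)
  ann <- study$expression$annotation
  utils::write.table(data.frame(sample_id = ann$sample_id, age = ann$age_value,
                                tissue = ann$tissue),
                     paths$annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  write_gct(study$profiles$z, paths$profiles)
  utils::write.table(study$profiles$meta, paths$profile_meta, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$tissue_cell_map, paths$tissue_cell_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
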