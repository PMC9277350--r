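# Programmatic fixtures written to tempfiles at test time.

write_expr_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                               genes = c("G1", "G2", "G3"),
                               samples = c("S1", "S2", "S3", "S4"),
                               ages = c(25, 35, 45, 55),
                               values = NULL, duplicate_gene = FALSE,
                               drop_age_of = NULL) {
  if (is.null(values)) {
    values <- matrix(seq_len(length(genes) * length(samples)),
                     length(genes), dimnames = list(genes, samples))
  }
  tab <- data.frame(gene = rownames(values), values, check.names = FALSE)
  if (duplicate_gene) tab <- rbind(tab, tab[1L, ])  # G1 twice
  expr_path <- file.path(dir, "expr.tsv")
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ages_out <- as.character(ages)
  if (!is.null(drop_age_of)) ages_out[samples == drop_age_of] <- ""
  ann_path <- file.path(dir, "ann.tsv")
  utils::write.table(data.frame(sample_id = samples, age = ages_out, tissue = "muscle"),
                     ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr_path, ann = ann_path, values = values)
}

write_profile_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                  n_genes = 5, n_profiles = 6,
                                  blank_drug_of = NULL) {
  z <- matrix(round(stats::rnorm(n_genes * n_profiles), 6), n_genes,
              dimnames = list(sprintf("G%d", seq_len(n_genes)),
                              sprintf("P%d", seq_len(n_profiles))))
  meta <- data.frame(profile_id = colnames(z), drug = "drugA", cell_line = "NPC",
                     dose = "10uM", time = "24h",
                     replicate_group = rep(c("rg1", "rg2"), each = n_profiles / 2))
  if (!is.null(blank_drug_of)) meta$drug[meta$profile_id == blank_drug_of] <- ""
  zp <- file.path(dir, "profiles.gct")
  mp <- file.path(dir, "meta.tsv")
  write_gct(z, zp)
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(z = zp, meta = mp, values = z, meta_df = meta)
}

write_gmt_fixture <- function(lines,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "sets.gmt")
  writeLines(lines, path)
  path
}
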