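#!/usr/bin/env Rscript
# Codon-level combined consequences of same-codon MNVs: category tallies
# per gene and per individual, constraint enrichment, and frame-restoring
# indel pairs (none are planted by the SNV-only generator; the scan is
# still exercised).

suppressPackageStartupMessages({
  library(mnvscan)
  library(dplyr)
})

sim <- "results/sim"
out <- "results"

recs <- read_mnv_tsv(file.path(out, "mnv_records.tsv"))
ref_seq <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
ref <- structure(list(
  contigs = setNames(as.character(ref_seq), names(ref_seq)),
  transcripts = read_transcripts_tsv(file.path(sim, "transcripts.tsv"))
), class = "ReferenceBundle")

ann <- annotate_coding_mnvs(recs, ref)
utils::write.table(ann[, setdiff(names(ann), "carriers")],
                   file.path(out, "coding_mnvs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(ann), " coding MNVs annotated; categories: ",
        paste(names(table(ann$category)), table(ann$category),
              collapse = ", "))

if (any(!ann$category %in% "cross_codon")) {
  tal <- per_gene_tallies(ann)
  utils::write.table(tal, file.path(out, "coding_per_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- per_sample_tallies(ann, n_samples = 200L)
  utils::write.table(ps, file.path(out, "coding_per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("mean changed-interpretation MNVs per individual: ",
          signif(ps$mean_per_individual[
            ps$category == "changed_interpretation"], 3))

  constrained <- ref$transcripts$gene[ref$transcripts$loeuf_decile <= 2L]
  enough <- table(ann$category)
  test_cat <- names(enough)[which.max(enough)]
  if (length(constrained) && enough[[test_cat]] >= 2 &&
      test_cat != "cross_codon") {
    fe <- tryCatch(constraint_enrichment(ann, constrained, test_cat),
                   error = function(e) NULL)
    if (!is.null(fe)) {
      message("constraint enrichment for ", test_cat, ": OR = ",
              signif(fe$odds_ratio, 3), ", p = ", signif(fe$p_value, 3))
    }
  }
}

fri <- find_frame_restoring_indel_pairs(file.path(sim, "cohort.vcf"))
message(nrow(fri), " frame-restoring indel pairs (SNV-only cohort)")
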