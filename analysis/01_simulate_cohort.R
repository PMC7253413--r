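#!/usr/bin/env Rscript
# Build the synthetic study population: a reference genome with repeat
# tracts, genes and annotated intervals; a phased 200-sample cohort with
# MNVs planted by mechanism; and 12 trio families.  All later analysis
# steps read the files written here.

suppressPackageStartupMessages(library(mnvscan))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(1)

ann_spec <- list(
  list(category = "tss", n_intervals = 40L, interval_length = 900L,
       methylation = 0.05),
  list(category = "enhancer", n_intervals = 40L, interval_length = 900L,
       methylation = 0.30),
  list(category = "intron", n_intervals = 40L, interval_length = 900L,
       methylation = 0.60),
  list(category = "coding_like", n_intervals = 40L,
       interval_length = 900L, methylation = 0.85)
)
genes <- lapply(1:20, function(i) {
  list(gene = sprintf("GENE%02d", i), cds_len = 300L,
       strand = if (i %% 2L) "+" else "-")
})

ref <- generate_reference(
  length = 500000L,
  repeat_spec = default_repeat_spec(200L),
  gene_spec = genes,
  annotation_spec = ann_spec,
  seed = 11L
)
write_reference_fasta(ref, file.path(out, "reference.fa"))
write_transcripts_tsv(ref$transcripts, file.path(out, "transcripts.tsv"))
write_bed(ref$annotations, file.path(out, "annotations.bed"))

spec <- cohort_spec(
  n_samples = 200L, n_events = 1500L,
  mechanism_mix = c(independent_snv = 0.74, pol_zeta = 0.2,
                    slippage = 0.06)
)
co <- plant_cohort(ref, spec, seed = 12L, out_dir = out)
message("cohort: ", length(co$samples), " samples, ",
        nrow(co$truth), " planted events (",
        paste(names(table(co$truth$mechanism)),
              table(co$truth$mechanism), collapse = ", "), ")")

tri <- plant_trios(ref, n_trios = 12L, seed = 13L, out_dir = out)
utils::write.table(tri$truth, file.path(out, "trio_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("trios: ", nrow(tri$truth), " planted het pairs in 12 families")
message("written under ", out)
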