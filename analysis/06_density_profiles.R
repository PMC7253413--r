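#!/usr/bin/env Rscript
# MNV density per substitution pattern across the annotation interval
# sets, its relation to the per-category methylation level, and the
# origin-class composition of each region.

suppressPackageStartupMessages({
  library(mnvscan)
  library(dplyr)
})

sim <- "results/sim"
out <- "results"

recs <- read_mnv_tsv(file.path(out, "mnv_records.tsv"))
ref_seq <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
ref <- structure(list(contigs = setNames(as.character(ref_seq),
                                         names(ref_seq))),
                 class = "ReferenceBundle")
ann <- read_bed(file.path(sim, "annotations.bed"))

adj <- recs %>% filter(d == 1L)
top <- names(sort(table(adj$pattern), decreasing = TRUE))[1:6]
dens <- mnv_density(adj, ann, ref, patterns = top)
utils::write.table(dens, file.path(out, "mnv_density.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cm <- tryCatch(correlate_density_methylation(dens),
               error = function(e) NULL)
if (!is.null(cm)) {
  utils::write.table(cm, file.path(out, "density_methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("density-methylation correlations: ",
          paste(sprintf("%s r=%.2f", cm$pattern, cm$r), collapse = "; "),
          " (uniform planting: no systematic trend expected)")
}

fr <- origin_fractions_by_region(adj, ann)
utils::write.table(fr, file.path(out, "origin_fractions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("origin-class fractions per category written; genome-wide: ",
        paste(sprintf("%s %.2f",
                      sub("frac_", "",
                          names(fr)[startsWith(names(fr), "frac_")]),
                      unlist(origin_fractions_by_region(adj)[1,
                        startsWith(names(fr), "frac_")])),
              collapse = ", "))
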