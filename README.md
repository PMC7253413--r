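# mnvscan

Multi-nucleotide variants (MNVs) are pairs of nearby variants on the same
haplotype of the same individual.  They matter twice over: two SNVs in one
codon can combine into an amino-acid change that neither variant causes
alone (gained or rescued nonsense, changed missense), and the spectrum of
MNV substitution patterns records which mutational process made them --
combinations of independent single-nucleotide events (dominated by CpG
deamination), single-generation doublet errors of DNA polymerase zeta
(the GA>TT / GC>AA signature), or polymerase slippage in repeat tracts
(AA>TT, AT>TA, TA>AT).

`mnvscan` is an R package for the population-scale analysis of MNVs from
phased cohort VCFs:

* **Discovery** -- a windowed scanner over every pair of genotypes within
  `d` bp in every individual, with phase-set-aware cis/trans logic,
  stringent genotype QC (FILTER PASS, non-LCR, GQ >= 20, DP >= 10,
  allele balance > 0.2), haplotype-level allele counting (`ac_mnv`,
  `n_hom`, `n_indiv`) and reverse-complement collapsing of the 144
  ordered adjacent patterns into 78 canonical classes.
* **Phasing evaluation** -- deterministic phase-by-transmission for trio
  children, scored against read-based phase: sensitivity, cis
  specificity and concordance per distance bin.
* **Coding impact** -- strand-aware codon mapping, combined versus
  individual consequences via the standard genetic code, per-gene and
  per-individual tallies, constraint enrichment (Fisher's exact test),
  and frame-restoring indel pairs (two frameshifts within 30 bp whose
  net length change is a multiple of 3).
* **Mechanism inference** -- one-step classification (`ac1 == ac2`),
  repetitive-context classification from gapped repeat-unit counts in
  the +/-4 bp window, a two-path mutation-rate null model
  `p(WX>YZ) ∝ mu(WX>YX)·mu(YX>YZ) + mu(WX>WZ)·mu(WZ>YZ)` with an excess
  factor `q` per pattern (the fraction not explained by independent
  SNVs), and Watterson-style mutation rates
  `mu_MNV = (n_mnv_sites/n_snv_sites) · mu_SNV`.
* **Density profiling** -- per-pattern MNV density
  `D = N(WX>YZ|I)/N(WX|I)` across annotation interval sets, normalised
  to the genome-wide value, with methylation-level correlations and
  origin-class fractions per region.
* **Synthetic cohorts** -- a generator that builds reference contigs
  (repeat tracts, stop-free genes, annotations), plants MNVs of known
  mechanism on explicit haplotypes, and emits phased VCF / PED / BED /
  FASTA plus a truth manifest, so the entire pipeline is testable
  without access to restricted human callsets.

## Worked example

```r
library(mnvscan)

ref  <- generate_reference(length = 60000,
                           repeat_spec = default_repeat_spec(30), seed = 7)
spec <- cohort_spec(n_samples = 50, n_events = 120,
                    mechanism_mix = c(independent_snv = 0.6,
                                      pol_zeta = 0.2, slippage = 0.2))
co   <- plant_cohort(ref, spec, seed = 11)

recs <- scan_mnvs(co$vcf, max_dist = 10)
nrow(recs)
#> [1] 120

# every planted cis event recovered, with exact haplotype counts
tr <- subset(co$truth, mechanism != "trans")
m  <- match(paste(tr$pos1, tr$pos2), paste(recs$pos1, recs$pos2))
mean(!is.na(m)); all(tr$ac_mnv == recs$ac_mnv[m])
#> [1] 1
#> [1] TRUE

# planted slippage events are exactly the repetitive-context records
table(classify_repeat_context(recs[m, ], ref), tr$mechanism)
#>        independent_snv pol_zeta slippage
#>  FALSE              66       27        0
#>  TRUE                0        0       27
```

`nrow(recs) == 120` says the scanner found one record per planted cis
event and emitted none of the planted trans pairs; the `ac_mnv` equality
confirms haplotype-level allele counts survive the VCF round trip; the
final table shows the repeat-context classifier separating slippage
events from the other mechanisms with no errors on clean contexts.

The `analysis/` directory holds the numbered study drivers
(`01_simulate_cohort.R` ... `06_density_profiles.R`); each is a thin
script over the package functions that prints what it found and writes
its tables under `results/`.

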