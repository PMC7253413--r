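---
title: "Multi-nucleotide variants in phased cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-nucleotide variants in phased cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnvscan)
```

## The problem

A multi-nucleotide variant (MNV) is a pair (or cluster) of nearby variants
sitting on the same haplotype of the same individual.  MNVs matter for two
reasons.  First, when two SNVs fall in one codon, the combined amino-acid
change can differ from either individual annotation -- two missense calls
can jointly be a nonsense variant ("gained nonsense") or a nonsense call
can be cancelled by its neighbour ("rescued nonsense") -- so codon-blind
annotation pipelines mis-annotate them.  Second, the spectrum of MNVs
carries the fingerprints of distinct mutational processes: CpG-deamination
driven combinations of independent SNVs, single-generation doublet errors
by the error-prone translesion polymerase zeta (the GA>TT and GC>AA
signature), and polymerase slippage at repeat junctions.

`mnvscan` implements the full analysis chain over phased multi-sample
VCFs: cis-pair discovery, trio-based validation of read-based phasing,
codon-level re-annotation, mechanism inference with a mutation-rate null
model, per-generation rate estimation, and density profiling across
genomic annotations.  Because population-scale human callsets cannot be
bundled, a first-class synthetic-cohort generator plants MNVs of known
mechanism into simulated diploid cohorts; every claim the test-suite makes
is checked against that ground truth.

## Discovery model

Variant pairs within a window (10 bp for genome-style scans; 2 bp is the
exome-style convention) are checked in every individual for co-occurrence
of the alternate alleles on one haplotype.  The phase logic is:

* two heterozygous calls are comparable only when both are phased *and*
  share a phase set (PS); they are cis when the alt alleles sit on the
  same side;
* a homozygous-alt call occupies both haplotypes, so het x hom pairs need
  only the het's phase and hom x hom pairs need none -- zygosity forces
  cis;
* a homozygous MNV carrier contributes two haplotypes to `ac_mnv` and is
  counted in `n_hom`.

Genotype QC follows stringent short-read convention: site FILTER PASS,
outside a low-complexity mask, GQ >= 20, DP >= 10, and allele balance
> 0.2 for heterozygous calls; a pair is dropped wherever either member
fails.  Substitution patterns are collapsed with their reverse
complements (the same mutational event read on the other strand); of the
16 x 9 = 144 ordered adjacent patterns, 78 canonical classes remain, 12
of them self-complementary.

The scanner is verified against a brute-force all-pairs, all-samples
enumeration written independently in the test-suite, on one hundred
small random cohorts with trans pairs, unphased genotypes and fragmented
phase sets planted.

## Trio phasing

Phase-by-transmission is implemented as deterministic logic for child
het/het pairs: each child alternate allele is assigned a parental origin
whenever the parents' genotype configuration forces the assignment; cis
means both alternates trace to one parent.  Pairs where both parents are
heterozygous at a site are inherently uninformative, and Mendelian
inconsistencies flag the pair out of scoring.  We deliberately do not
re-implement a statistical phasing HMM: on error-free genotypes the
deterministic rule is exact, which is what makes it usable as an oracle
for the read-based phase.  Phasing sensitivity is the fraction of het
pairs with read-based phase assigned.  Because the reported specificity
denominator is ambiguous in the field, the concordance table reports
both cis-restricted specificity and all-pair concordance, per distance
bin (1-10 bp individually, 10 bp bins beyond).

## Coding impact

Codon mapping is strand-aware over ordered CDS intervals; the standard
genetic code (table 1) is used, with no selenocysteine or start/splice
modelling -- the categories are codon-level by design.  The decision
table, given the amino acids A1, A2 (each SNV alone) and AM (the MNV):

| category | rule |
|---|---|
| gained_nonsense | AM is stop, neither A1 nor A2 is |
| rescued_nonsense | AM not stop, A1 or A2 is |
| gained_missense | A1 and A2 both synonymous, AM not |
| unchanged | AM equals A1 or A2 |
| changed_missense | AM differs from both, AM and one of A1/A2 missense |
| other_changed | remainder (e.g. stop-lost combinations) |

The boundary between `changed_missense` and `other_changed` is a
judgement call; the rule is isolated in `classify_codon_change()` so it
can be revised in one place.  Cross-codon pairs are counted but not
categorized.  The whole classifier is checked exhaustively -- all 64
reference codons x 3 offset pairs x 9 alternate pairs -- against an
independent mutate-whole-CDS / translate / diff oracle, and a
minus-strand transcript must reproduce its plus-strand mirror exactly.

Rescued-nonsense records carry a `fully_rescued` flag: the rescue holds
in every carrier only when the MNV allele count equals the allele count
of the nonsense-introducing SNV; per-gene tallies use this restriction by
default.  Frame-restoring indel pairs are defined as two in-cis indels
within 30 bp, each individually frameshifting, whose summed length change
is a multiple of 3; pairs of individually in-frame indels do not
"restore" anything and are excluded.

## Mechanism inference

**One-step MNVs.** If the two constituent SNVs arose in one generation
(as a doublet error), no carrier can hold one allele without the other,
so the cohort allele counts match: `ac1 == ac2`.  Strict mode adds
`ac_mnv/ac1 >= 0.9` to guard against coincidental equality.

**Repeat contexts.**  The repeat unit of an MNV is its own reference or
alternate pair (gapped when the variants are d > 1 apart); units are
counted in the +/-4 bp window, counting overlaps, so e.g. the d = 2 event
TATATAT -> TAAAAAT has reference and alternate unit counts of 3 and 3.
A context is repetitive when both the reference and the alternative
window hold more than one unit and either holds more than two; for
adjacent MNVs whose pair is a mononucleotide run the thresholds on that
side rise by one (the overlap-counting correction).  Note this
both-context rule means a CA>TG inside a CA microsatellite is *not*
repetitive -- the TG product breaks the repeat -- which is exactly why the
repeat-dominated patterns are the unit swaps AA>TT, AT>TA and TA>AT.

**The null model and the excess factor q.**  Under independent SNVs, an
adjacent MNV WX>YZ must pass through one of two intermediates,

    p(WX>YZ) ∝ mu(WX>YX)·mu(YX>YZ) + mu(WX>WZ)·mu(WZ>YZ),

each mu a 3-mer-context SNV rate, the second step's context containing
the first step's product.  Outer flanks are marginalised over the
genome's base composition by default (an exact per-site mode takes true
flanks).  The expected count of pattern p is `E_p = C · p_null(p) ·
N_dinuc(p) · n`, with one global scale C fitted by least squares in log
space over a calibration set of patterns with no known doublet mechanism
(all but the pol-zeta signature and the repeat-class patterns); the log
fit keeps the heavy-tailed spectrum from letting a few CpG patterns
dominate.  The non-SNV excess is then `q(p) = max(0, 1 - E_p /
N_nonrepeat(p))`, and each pattern's observed MNVs split into repeat,
SNV-combination and "other" fractions that sum to one.  Parameter
recovery is tested on cohorts with planted doublet excesses spanning 0
to 0.75.

**Mutation rates.**  Assuming no recurrent mutation, one-step adjacent
MNV sites relate to SNV sites as their mutation rates do
(Watterson-style), so `mu_MNV = (n_mnv_sites / n_snv_sites) · mu_SNV`
with `mu_SNV = 1.2e-8` per bp per generation by default.  Pattern rates
redistribute the global rate by each pattern's share of one-step sites,
normalised by its reference-dinucleotide availability and an explicit
`coverage_factor` (default 1; the correction is a user-supplied scalar so
results stay reproducible).  The redistribution conserves the global
expectation: the sum over patterns of rate x opportunity equals the
global rate x total opportunity.

**Predicted mechanism per pattern** follows an ordered rule: the
pol-zeta signature patterns first; then "repeat" where the
repetitive-context fraction exceeds 10%; otherwise a label derived from
the possible single-step path compositions (Ti at CpG, Ti, Ti at CpG +
Tv, Ti + Tv, Tv combination), where a CpG transition is a C>T with a 3'
G or G>A with a 5' C arising within the dinucleotide along either path.

## Density profiling

The density of pattern WX>YZ in an interval set I is the observed count
divided by the count of WX opportunities in I, normalised by the
genome-wide density so `d_norm = 1` means genome-average behaviour.
Because patterns are strand-collapsed, opportunities count both WX and
its reverse complement (self-complementary pairs once); the convention is
stated here because the alternative (single-strand counting) scales all
densities by a pattern-dependent factor.  Overlapping categories are
scored independently.  Methylation enters as a per-category fraction of
methylated CpGs; the package reports the per-pattern Pearson correlation
of `d_norm` with methylation across categories (at least three categories
required; degenerate inputs are flagged, not silently dropped).

## The synthetic cohort: what it emulates, and what it does not

Each sample is two explicit haplotype strings of variant placements, so
cis/trans ground truth is unambiguous; genotypes, phase sets, GQ/DP/AD
and the VCF itself are derived views.  Planted events follow the three
mechanisms: independent-SNV events draw their pattern in proportion to
the null model itself (so the q estimator's calibration assumption holds
by construction), with independently drawn extra carriers making
`ac1 != ac2` common; pol-zeta events are doublets with the GA>TT / GC>AA
motifs and equal allele counts; slippage events are unit swaps planted
inside the reference's repeat tracts (dinucleotide tracts give TA>AT
/ AT>TA; mononucleotide junction tracts, written as T-runs abutting
A-runs, give AA>TT).  Planted trans pairs and unphased-genotype noise
exercise the scanner's rejection paths, and a nested phase-set
fragmentation option lowers phasing sensitivity monotonically by
construction.

Default study conditions: 1000 diploid samples, 1500 adjacent events,
mechanism mix 0.8/0.1/0.1 (independent/pol-zeta/slippage), reflecting a
spectrum dominated by SNV combinations with visible doublet components.
Allele counts are `1 + Geometric(p = 0.5)`, capped at 20 -- population
MNVs are overwhelmingly rare variants; no published generative
allele-frequency model exists for this setting, so the choice is recorded
in the cohort metadata rather than hidden.  The default rate table is
synthetic but keeps the established hierarchy (CpG transitions ~1.2e-7,
other transitions 1e-8, transversions 2.5e-9 per site per generation).

What the generator does **not** emulate: sequencing reads (no FASTQ/BAM,
no error model -- QC failures are constructed directly in tests),
recombination inside windows, sex chromosomes (autosome-only diploid
model, avoiding zygosity differences), population structure, recurrent
mutation, and regional mutation-rate variation beyond the 3-mer context.
Passing tests therefore demonstrate correctness of the *logic* under
clean phasing and a context-homogeneous rate model, not robustness to
read-level artefacts or rate heterogeneity in real cohorts.

## Numerical and design choices

* Distance convention: `d = pos2 - pos1`; "within 2 bp" means d <= 2;
  coordinates are 1-based inclusive internally, 0-based half-open at BED
  interfaces.
* Pairs failing QC in an individual draw no evidence from that
  individual; sites failing site-level filters are dropped entirely.
* SNV pairs and indel pairs are scanned in separate passes; mixed pairs
  are out of scope.
* Cohort allele counts (`ac1`, `ac2`) count all alt alleles in the
  callset, not only QC-passing carriers, matching how released cohort
  ACs are computed; `ac_mnv` and `n_indiv` are both reported since the
  haplotype/individual unit choice is a genuine ambiguity.
* `estimate_q` needs a non-empty calibration set and errors on an
  all-zero spectrum; densities with zero opportunity are flagged `NA`
  rather than dropped.
* The q-model scale C could alternatively be fitted by total-count
  matching; the log-least-squares choice is isolated in `estimate_q()`.
* Odds ratios are plain cross-products (ad/bc), with a flagged Haldane
  0.5 correction only on zero cells; p-values come from the exact
  hypergeometric test.
* Test and example problem sizes (10^5-10^6 bp contigs, 200-1000
  samples, 1500-2200 events) are chosen so the full chain runs in
  minutes while keeping per-pattern counts large enough for the
  stochastic recovery checks; the acceptance script states the size `n`
  it used next to every quantity it reports.

## Known limitations

The per-pattern rate reconstruction distributes the global rate by
one-step share and opportunity; absolute per-pattern constants depend on
that reconstruction and on the coverage factor, so they should be read
as model-conditional.  The q estimator's truncation at zero biases
per-pattern estimates slightly upward near q = 0 (visible as a small
positive median on null spectra).  Indel-rate modelling as a function of
repeat length is out of scope, which limits what can be said about the
absolute slippage fraction; the repeat classifier is a context rule, not
a rate model.
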