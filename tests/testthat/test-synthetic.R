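test_that("reference generation honours placements and is deterministic", {
  ref <- generate_reference(
    length = 10000L,
    repeat_spec = list(list(unit = "TA", copies = 6L, position = 500L)),
    seed = 1L
  )
  expect_equal(substr(ref$contigs[["chr1"]], 500, 511),
               "TATATATATATA")
  ref2 <- generate_reference(
    length = 10000L,
    repeat_spec = list(list(unit = "TA", copies = 6L, position = 500L)),
    seed = 1L
  )
  expect_identical(ref$contigs, ref2$contigs)
  # byte-identical FASTA for a fixed seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference_fasta(ref, f1); write_reference_fasta(ref2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # overlapping placements are rejected
  expect_error(
    generate_reference(
      length = 10000L,
      repeat_spec = list(list(unit = "TA", copies = 6L, position = 500L),
                         list(unit = "CA", copies = 6L, position = 505L)),
      seed = 1L
    ),
    "placement error"
  )
})

test_that("generated CDS translates without internal stops, both strands", {
  ref <- generate_reference(
    length = 10000L,
    gene_spec = list(list(gene = "GP", cds_len = 300L, strand = "+"),
                     list(gene = "GM", cds_len = 300L, strand = "-"),
                     list(gene = "GX", cds_len = 300L, strand = "+",
                          n_exons = 3L)),
    seed = 5L
  )
  for (i in seq_len(nrow(ref$transcripts))) {
    tx <- ref$transcripts[i, ]
    pieces <- mapply(function(s, e) {
      substr(ref$contigs[[tx$contig]], s, e)
    }, tx$cds_starts[[1]], tx$cds_ends[[1]])
    cds <- paste(pieces, collapse = "")
    if (tx$strand == "-") cds <- revcomp(cds)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("planted cohorts are deterministic and conserve allele counts", {
  ref <- tiny_reference(repeats = default_repeat_spec(16L))
  spec <- cohort_spec(n_samples = 30L, n_events = 40L,
                      mechanism_mix = c(independent_snv = 0.5,
                                        pol_zeta = 0.3, slippage = 0.2))
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  co1 <- plant_cohort(ref, spec, seed = 3L, out_dir = d1)
  co2 <- plant_cohort(ref, spec, seed = 3L, out_dir = d2)
  expect_identical(readLines(co1$vcf), readLines(co2$vcf))
  expect_identical(co1$truth, co2$truth)

  # planted ACs equal ACs recomputed from the emitted VCF
  v <- read_phased_vcf(co1$vcf)
  key <- paste(v$sites$contig, v$sites$pos)
  tr <- co1$truth
  i1 <- match(paste(tr$contig, tr$pos1), key)
  i2 <- match(paste(tr$contig, tr$pos2), key)
  expect_equal(v$sites$ac[i1], tr$ac1)
  expect_equal(v$sites$ac[i2], tr$ac2)
  # emitted REF alleles match the reference sequence
  expect_equal(
    substring(ref$contigs[[1]], v$sites$pos, v$sites$pos),
    v$sites$ref
  )
  # the in-memory genotype view equals the parsed file
  g <- co1$genotypes
  expect_equal(g$sites$pos, v$sites$pos)
  expect_equal(g$sites$ac, v$sites$ac)
  expect_equal(unname(g$hap1), unname(v$hap1))
  expect_equal(unname(g$hap2), unname(v$hap2))
  expect_equal(unname(g$phased), unname(v$phased))
  expect_equal(unname(g$ps), unname(v$ps))
})

test_that("doublet mechanisms have equal ACs and the right signatures", {
  ref <- tiny_reference(repeats = default_repeat_spec(60L))
  spec <- cohort_spec(n_samples = 40L, n_events = 80L,
                      mechanism_mix = c(independent_snv = 0,
                                        pol_zeta = 0.5, slippage = 0.5),
                      trans_rate = 0)
  co <- plant_cohort(ref, spec, seed = 8L)
  tr <- co$truth
  expect_true(all(tr$ac1 == tr$ac2 & tr$ac2 == tr$ac_mnv))
  pz <- tr[tr$mechanism == "pol_zeta", ]
  expect_true(all(pz$pattern %in% c("GA>TT", "GC>AA")))
  # every planted slippage event satisfies the repeat-context classifier;
  # no other planted event does (clean contexts)
  flags <- classify_repeat_context(tr, ref)
  expect_equal(flags, tr$mechanism == "slippage")
})

test_that("mechanism mix converges at n = 1000 within binomial error", {
  ref <- generate_reference(length = 500000L,
                            repeat_spec = default_repeat_spec(250L),
                            seed = 21L)
  mix <- c(independent_snv = 0.5, pol_zeta = 0.3, slippage = 0.2)
  spec <- cohort_spec(n_samples = 20L, n_events = 1000L,
                      mechanism_mix = mix, trans_rate = 0)
  co <- plant_cohort(ref, spec, seed = 22L, write_vcf = FALSE)
  n <- nrow(co$truth)
  for (m in names(mix)) {
    ph <- mean(co$truth$mechanism == m)
    se <- sqrt(mix[[m]] * (1 - mix[[m]]) / n)
    expect_lt(abs(ph - mix[[m]]), 4 * se + 0.01)
  }
})

test_that("capacity and specification errors are raised", {
  ref <- tiny_reference(repeats = list())   # no tracts at all
  spec <- cohort_spec(n_samples = 10L, n_events = 10L,
                      mechanism_mix = c(independent_snv = 0,
                                        pol_zeta = 0, slippage = 1))
  expect_error(plant_cohort(ref, spec, seed = 1L), "capacity error")
  expect_error(cohort_spec(mechanism_mix = c(independent_snv = 0.5,
                                             pol_zeta = 0.1,
                                             slippage = 0.1)),
               "sum to 1")
})

test_that("unphased noise disappears at rate zero", {
  ref <- tiny_reference()
  spec <- cohort_spec(n_samples = 25L, n_events = 30L,
                      noise_unphased_rate = 0)
  co <- plant_cohort(ref, spec, seed = 4L)
  v <- read_phased_vcf(co$vcf)
  expect_true(all(v$phased))
  spec2 <- cohort_spec(n_samples = 25L, n_events = 30L,
                       noise_unphased_rate = 0.5)
  co2 <- plant_cohort(ref, spec2, seed = 4L)
  v2 <- read_phased_vcf(co2$vcf)
  het <- (v2$hap1 + v2$hap2) == 1L
  expect_gt(sum(!v2$phased[het]), 0L)
})
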