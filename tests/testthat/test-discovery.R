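test_that("genotype QC applies the GQ/DP/AB and site thresholds", {
  # GQ below 20 fails even with perfect balance
  expect_false(qc_pass(19L, 30L, 0.5, TRUE))
  expect_true(qc_pass(99L, 30L, 0.5, TRUE))
  expect_false(qc_pass(99L, 9L, 0.5, TRUE))
  expect_false(qc_pass(99L, 30L, 0.2, TRUE))    # AB must exceed 0.2
  expect_true(qc_pass(99L, 30L, NA, FALSE))     # AB ignored for hom
  expect_false(qc_pass(NA_integer_, 30L, 0.5, TRUE))  # missing GQ fails
  expect_false(qc_pass(99L, 30L, 0.5, TRUE, in_lcr = TRUE))
  expect_false(qc_pass(99L, 30L, 0.5, TRUE, filter_pass = FALSE))
})

test_that("scanner emits cis pairs and haplotype-counts carriers", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "mini.vcf")
  sites <- tibble::tibble(pos = c(100L, 101L), ref = c("C", "A"),
                          alt = c("T", "G"))
  # S01 cis, S02 trans, S03 hom-hom, S04 het site1 only
  write_mini_vcf(vcf, 1000L, sites, list(
    c("0|1:10", "0|1:10", "1|1:10", "0|1:10"),
    c("0|1:10", "1|0:10", "1|1:10", "0|0:10")
  ))
  recs <- scan_mnvs(vcf, max_dist = 2L)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$ac_mnv, 3L)       # 1 (cis het) + 2 (hom-hom)
  expect_equal(recs$n_hom, 1L)
  expect_equal(recs$n_indiv, 2L)
  expect_setequal(recs$carriers[[1]], c("S01", "S03"))
  expect_equal(recs$pattern, canonical_pattern("CA", "TG"))
  expect_equal(recs$ac1, 5L)          # cohort ACs count all alt alleles
  expect_equal(recs$ac2, 4L)

  # trans-only cohort yields nothing
  write_mini_vcf(vcf, 1000L, sites, list(c("0|1:10"), c("1|0:10")))
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 2L)), 0L)

  # different phase sets: pair is unphased, no record
  write_mini_vcf(vcf, 1000L, sites, list(c("0|1:10"), c("0|1:99")))
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 2L)), 0L)

  # hom x het without phase still counts (zygosity forces cis)
  write_mini_vcf(vcf, 1000L, sites, list(c("1/1"), c("0/1")))
  recs <- scan_mnvs(vcf, max_dist = 2L)
  expect_equal(recs$ac_mnv, 1L)
})

test_that("window, QC and LCR filters drop pairs", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "mini.vcf")
  sites <- tibble::tibble(pos = c(100L, 111L), ref = c("C", "A"),
                          alt = c("T", "G"))
  write_mini_vcf(vcf, 1000L, sites, list(c("0|1:10"), c("0|1:10")))
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 10L)), 0L)  # d = 11
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 11L)), 1L)

  # low GQ at one member drops the pair entirely
  sites2 <- tibble::tibble(pos = c(100L, 101L), ref = c("C", "A"),
                           alt = c("T", "G"))
  write_mini_vcf(vcf, 1000L, sites2, list(c("0|1:10"), c("0|1:10")),
                 gq = c(99L, 19L))
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 2L)), 0L)
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 2L, qc = FALSE)), 1L)

  # a site inside the low-complexity mask is removed
  write_mini_vcf(vcf, 1000L, sites2, list(c("0|1:10"), c("0|1:10")))
  lcr <- tibble::tibble(contig = "chr1", start = 95L, end = 100L)
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 2L, lcr = lcr)), 0L)

  # non-PASS site is removed
  write_mini_vcf(vcf, 1000L, sites2, list(c("0|1:10"), c("0|1:10")),
                 filter = c("RF", "PASS"))
  expect_equal(nrow(scan_mnvs(vcf, max_dist = 2L)), 0L)
})

test_that("malformed input is rejected with the offending site", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS01",
    "chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t1|2"
  ), vcf)
  expect_error(read_phased_vcf(vcf), "multiallelic record at chr1:100")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS01",
    "chr1\t100\t.\tCAG\tCTG\t.\tPASS\t.\tGT\t0|1"
  ), vcf)
  expect_error(read_phased_vcf(vcf), "non-minimal")
})

test_that("scanner equals brute force on random small cohorts", {
  set.seed(77)
  for (rep in 1:12) {
    ref <- generate_reference(length = 1000L, seed = 1000L + rep)
    spec <- cohort_spec(
      n_samples = 5L, n_events = 6L,
      mechanism_mix = c(independent_snv = 1, pol_zeta = 0, slippage = 0),
      trans_rate = 0.3, noise_unphased_rate = 0.3,
      ps_fragment_length = sample(c(Inf, 50), 1),
      distance_weights = stats::setNames(rep(1, 10), 1:10)
    )
    co <- plant_cohort(ref, spec, seed = 2000L + rep)
    got <- scan_mnvs(co$vcf, max_dist = 10L)
    want <- brute_force_mnvs(co$vcf, max_dist = 10L)
    got <- got[order(got$pos1, got$pos2), ]
    want <- want[order(want$pos1, want$pos2), ]
    expect_equal(got$pos1, want$pos1)
    expect_equal(got$pos2, want$pos2)
    expect_equal(got$ac_mnv, want$ac_mnv)
    expect_equal(got$n_hom, want$n_hom)
    expect_equal(got$n_indiv, want$n_indiv)
  }
})

test_that("planted truth is recovered exactly under full phase sets", {
  ref <- tiny_reference(repeats = default_repeat_spec(20L))
  spec <- cohort_spec(n_samples = 40L, n_events = 60L,
                      mechanism_mix = c(independent_snv = 0.6,
                                        pol_zeta = 0.2, slippage = 0.2),
                      trans_rate = 0.1)
  co <- plant_cohort(ref, spec, seed = 55L)
  recs <- scan_mnvs(co$vcf, max_dist = 10L)
  tr <- co$truth[co$truth$mechanism != "trans", ]
  m <- match(paste(tr$pos1, tr$pos2), paste(recs$pos1, recs$pos2))
  expect_false(anyNA(m))                       # 100% recall
  expect_equal(recs$ac_mnv[m], tr$ac_mnv)      # exact haplotype counts
  expect_equal(recs$n_hom[m], tr$n_hom)
  expect_equal(recs$pattern[m], tr$pattern)
  # planted trans pairs are never emitted
  trn <- co$truth[co$truth$mechanism == "trans", ]
  expect_false(any(paste(trn$pos1, trn$pos2) %in%
                     paste(recs$pos1, recs$pos2)))
})

test_that("raw pattern counts are strand-symmetric before collapsing", {
  ref <- generate_reference(length = 300000L, seed = 61L)
  spec <- cohort_spec(n_samples = 30L, n_events = 1500L,
                      mechanism_mix = c(independent_snv = 1, pol_zeta = 0,
                                        slippage = 0),
                      trans_rate = 0)
  co <- plant_cohort(ref, spec, seed = 62L, write_vcf = FALSE)
  recs <- scan_mnvs(co$genotypes, max_dist = 1L)
  raw <- paste0(recs$ref1, recs$ref2, ">", recs$alt1, recs$alt2)
  mate <- paste0(revcomp(paste0(recs$ref1, recs$ref2)), ">",
                 revcomp(paste0(recs$alt1, recs$alt2)))
  tab <- table(raw)
  # pooled over the frequent orientations, forward/reverse counts agree
  big <- names(tab)[tab >= 30]
  for (p in big) {
    m <- mate[match(p, raw)]
    n1 <- sum(raw == p); n2 <- sum(raw == m)
    if (p == m) next
    expect_lt(abs(n1 - n2) / sqrt(n1 + n2), 4)
  }
})
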