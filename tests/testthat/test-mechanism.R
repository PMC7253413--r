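test_that("one-step classification follows the allele-count rule", {
  expect_true(is_one_step(5L, 5L, 5L))
  expect_false(is_one_step(5L, 7L, 5L))
  # equal ACs but incomplete MNV support: one-step in base mode only
  expect_true(is_one_step(10L, 10L, 8L))
  expect_false(is_one_step(10L, 10L, 8L, strict = TRUE))
  expect_true(is_one_step(10L, 10L, 9L, strict = TRUE))
  expect_error(is_one_step(0L, 5L, 0L), "positive")
})

test_that("repeat unit counting matches the worked example and a naive
           oracle", {
  # TATATAT -> TAAAAAT (d = 2): both unit counts are 3
  expect_equal(repeat_unit_count("TATATAT", "TT", 2L), 3L)
  expect_equal(repeat_unit_count("TAAAAAT", "AA", 2L), 3L)
  expect_equal(repeat_unit_count("CACACACACA", "CA", 1L), 5L)
  expect_equal(repeat_unit_count("ACGTCAGTCC", "CA", 1L), 1L)
  set.seed(12)
  for (rep in 1:400) {
    ctx <- paste(sample(c("A", "C", "G", "T"), sample(6:14, 1),
                        replace = TRUE), collapse = "")
    unit <- paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")
    d <- sample(1:3, 1)
    expect_equal(repeat_unit_count(ctx, unit, d),
                 naive_repeat_count(ctx, unit, d))
  }
})

test_that("repetitive-context rule applies thresholds and mono bump", {
  mk <- function(seqs, pos1, d, r, a) {
    list(contig = "chr1", pos1 = pos1, d = d,
         ref1 = substr(r, 1, 1), ref2 = substr(r, 2, 2),
         alt1 = substr(a, 1, 1), alt2 = substr(a, 2, 2))
  }
  # a TA>AT unit swap keeps both the reference and the alternative
  # context repetitive: classified as a repeat context
  ref1 <- c(chr1 = "TTTTTATATATATATTTT")
  rec <- list(contig = "chr1", pos1 = 9L, d = 1L, ref1 = "T", ref2 = "A",
              alt1 = "A", alt2 = "T")
  expect_true(in_repeat_context(tibble::as_tibble(rec), ref1))
  # CA>TG inside a CA run destroys the repeat in the alternative
  # context (a single TG unit): both-context rule rejects it
  ref1b <- c(chr1 = "TTTTCACACACACATTTT")
  recb <- list(contig = "chr1", pos1 = 9L, d = 1L, ref1 = "C", ref2 = "A",
               alt1 = "T", alt2 = "G")
  expect_false(in_repeat_context(tibble::as_tibble(recb), ref1b))
  ref2 <- c(chr1 = "GGGGACGTCAGTCCGGGG")
  rec2 <- list(contig = "chr1", pos1 = 9L, d = 1L, ref1 = "C", ref2 = "A",
               alt1 = "T", alt2 = "G")
  expect_false(in_repeat_context(tibble::as_tibble(rec2), ref2))
  # mononucleotide pair raises the thresholds by one unit: an AA pair in
  # a run of four A's with a non-repetitive alt context stays below the
  # raised threshold (ref count 3 needs > 3)
  ref3 <- c(chr1 = "GCTGAAAACGTCGATG")
  rec3 <- list(contig = "chr1", pos1 = 5L, d = 1L, ref1 = "A", ref2 = "A",
               alt1 = "T", alt2 = "T")
  expect_false(in_repeat_context(tibble::as_tibble(rec3), ref3))
  # the same pair in a long poly-A/T junction clears the raised bars
  ref4 <- c(chr1 = "TTTTTTAAAAAAAAAA")
  rec4 <- list(contig = "chr1", pos1 = 7L, d = 1L, ref1 = "A", ref2 = "A",
               alt1 = "T", alt2 = "T")
  expect_true(in_repeat_context(tibble::as_tibble(rec4), ref4))
})

test_that("predicted mechanism follows the ordered assignment", {
  expect_equal(predicted_mechanism("GA>TT"), "pol_zeta")
  expect_equal(predicted_mechanism("GC>AA", 0.5), "pol_zeta")
  expect_equal(predicted_mechanism("AA>TT", 0.30), "repeat")
  # below the repeat threshold the pattern falls back to its SNV paths
  expect_equal(predicted_mechanism("AA>TT", 0.05), "Tv combination")
  # CA>TG has the CpG path CA -> CG -> TG
  expect_equal(predicted_mechanism("CA>TG", 0), "Ti at CpG")
  # TA>GC: both paths are double transversions
  expect_equal(predicted_mechanism("TA>GC", 0), "Tv combination")
  # AT>GC: A>G Ti then T>C Ti, no CpG
  expect_equal(predicted_mechanism("AT>GC", 0), "Ti")
})

test_that("q estimation recovers a pure null spectrum", {
  rt <- default_rate_table()
  ref <- generate_reference(length = 200000L, seed = 71L)
  nw <- null_pattern_weights(rt, ref)
  set.seed(72)
  C <- 4e12
  stats <- nw
  stats$n_obs <- rpois(nrow(nw), C * nw$null_weight)
  stats$n_one_step <- 0L
  stats$n_repeat <- 0L
  q <- estimate_q(stats, n_individuals = 1)
  big <- q$n_obs >= 50
  # no planted excess: q is near zero for well-measured patterns
  expect_lt(stats::median(q$q_hat[big], na.rm = TRUE), 0.1)
  expect_true(all(q$frac_repeat == 0 | is.na(q$frac_repeat)))
  sums <- q$frac_repeat + q$frac_snv_combination + q$frac_other
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("q estimation recovers planted excesses", {
  rt <- default_rate_table()
  ref <- generate_reference(length = 200000L, seed = 73L)
  nw <- null_pattern_weights(rt, ref)
  C <- 4e12
  for (excess in c(0.25, 0.5, 0.75)) {
    set.seed(100 + round(100 * excess))
    stats <- nw
    lam <- C * nw$null_weight
    pz <- stats$pattern %in% c("GA>TT", "GC>AA")
    lam[pz] <- lam[pz] / (1 - excess)   # doublet error inflates counts
    stats$n_obs <- rpois(nrow(nw), lam)
    stats$n_one_step <- 0L
    stats$n_repeat <- 0L
    q <- estimate_q(stats, n_individuals = 1)
    for (p in c("GA>TT", "GC>AA")) {
      row <- q[q$pattern == p, ]
      se <- sqrt(row$expected_null) / row$n_obs
      expect_lt(abs(row$q_hat - excess), 3 * se + 0.05)
    }
  }
})

test_that("rate estimation reproduces the Watterson-style scaling", {
  # ratio of MNV to SNV sites times the SNV rate
  sp <- tibble::tibble(pattern = c("CA>TG", "GA>TT"), n = c(75L, 25L))
  nd <- c("CA>TG" = 2e5, "GA>TT" = 1e5)
  est <- estimate_rates(245L, 100000L, sp, nd, mu_snv = 1.2e-8)
  expect_equal(est$mu_mnv_global, 2.45e-3 * 1.2e-8)
  expect_equal(signif(est$mu_mnv_global, 3), 2.94e-11)
  # conservation: per-pattern expectations sum to the global expectation
  expect_equal(sum(est$per_pattern$expected_per_generation),
               est$mu_mnv_global * sum(nd))
  # share-weighted redistribution
  expect_equal(est$per_pattern$rate[1] / est$per_pattern$rate[2],
               (75 / 25) * (1e5 / 2e5))
  # degenerate inputs
  est0 <- estimate_rates(0L, 1000L, sp, nd)
  expect_true(all(est0$per_pattern$rate == 0))
  expect_error(estimate_rates(10L, 0L, sp, nd), "positive")
})

test_that("pol-zeta doublets enrich one-step MNVs above background", {
  ref <- generate_reference(length = 400000L,
                            repeat_spec = default_repeat_spec(60L),
                            seed = 81L)
  spec <- cohort_spec(n_samples = 200L, n_events = 900L,
                      mechanism_mix = c(independent_snv = 0.75,
                                        pol_zeta = 0.2, slippage = 0.05))
  co <- plant_cohort(ref, spec, seed = 82L, write_vcf = FALSE)
  recs <- scan_mnvs(co$genotypes, max_dist = 1L)
  one <- is_one_step(recs$ac1, recs$ac2, recs$ac_mnv)
  pz <- recs$pattern %in% c("GA>TT", "GC>AA")
  ft <- stats::fisher.test(table(pz, one), alternative = "greater")
  expect_gt(mean(one[pz]), mean(one[!pz]))
  expect_lt(ft$p.value, 1e-4)
})
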