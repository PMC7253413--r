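# build a contig holding one plus-strand gene whose CDS is given exactly
cds_reference <- function(cds, pad = 100L) {
  seqs <- paste0(strrep("A", pad), cds, strrep("A", pad))
  ref <- list(
    contigs = c(chr1 = seqs),
    transcripts = tibble::tibble(
      gene = "G", tx = "G.t1", contig = "chr1", strand = "+",
      cds_starts = list(pad + 1L),
      cds_ends = list(pad + nchar(cds)),
      loeuf_decile = 1L
    ),
    annotations = tibble::tibble(), lcr = tibble::tibble(),
    repeats = tibble::tibble(), seed = 0L
  )
  class(ref) <- "ReferenceBundle"
  ref
}

test_that("codon mapping is strand-aware", {
  ref <- cds_reference("ATGCACTCATAA")        # M H S *
  tx <- ref$transcripts[1, ]
  expect_equal(codon_of(101L, tx, ref)[c("codon_index", "offset")],
               list(codon_index = 0L, offset = 0L))
  expect_equal(codon_of(104L, tx, ref),
               list(codon_index = 1L, offset = 0L, ref_codon = "CAC"))
  expect_null(codon_of(99L, tx, ref))          # outside CDS
  # minus strand: offset 0 is the 3'-most genomic base
  mref <- cds_reference(as.character(revcomp("ATGCACTCATAA")))
  mtx <- mref$transcripts[1, ]; mtx$strand <- "-"
  co <- codon_of(112L, mtx, mref)
  expect_equal(co$codon_index, 0L)
  expect_equal(co$offset, 0L)
  expect_equal(co$ref_codon, "ATG")
})

test_that("worked codon-change examples classify correctly", {
  # CAC(H): C>T at offset 0 -> TAC(Y); C>A at offset 2 -> CAA(Q);
  # together TAA = stop
  ref <- cds_reference("ATGCACTAA")
  tx <- ref$transcripts[1, ]
  out <- combined_consequence(
    list(pos = 104L, ref = "C", alt = "T"),
    list(pos = 106L, ref = "C", alt = "A"), tx, ref
  )
  expect_equal(out$aa_ref, "H"); expect_equal(out$aa1, "Y")
  expect_equal(out$aa2, "Q"); expect_equal(out$aa_mnv, "*")
  expect_equal(out$category, "gained_nonsense")

  # TCA(S): T>A -> ACA(T); C>G -> TGA(stop); MNV AGA(R): rescued
  ref <- cds_reference("ATGTCATAA")
  tx <- ref$transcripts[1, ]
  out <- combined_consequence(
    list(pos = 104L, ref = "T", alt = "A"),
    list(pos = 105L, ref = "C", alt = "G"), tx, ref
  )
  expect_equal(out$category, "rescued_nonsense")
  expect_equal(out$aa_mnv, "R")

  # CTG(L): two synonymous changes combining to TTA(L): unchanged
  ref <- cds_reference("ATGCTGTAA")
  tx <- ref$transcripts[1, ]
  out <- combined_consequence(
    list(pos = 104L, ref = "C", alt = "T"),
    list(pos = 106L, ref = "G", alt = "A"), tx, ref
  )
  expect_equal(out$category, "unchanged")
  expect_true(all(c(out$aa1, out$aa2, out$aa_mnv) == "L"))

  # different codons -> cross_codon, no further categorization
  ref <- cds_reference("ATGCACGGGTAA")
  tx <- ref$transcripts[1, ]
  out <- combined_consequence(
    list(pos = 106L, ref = "C", alt = "T"),
    list(pos = 107L, ref = "G", alt = "A"), tx, ref
  )
  expect_equal(out$category, "cross_codon")

  # reference mismatch is a data-integrity error
  expect_error(
    combined_consequence(list(pos = 104L, ref = "T", alt = "G"),
                         list(pos = 105L, ref = "A", alt = "G"), tx, ref),
    "reference mismatch"
  )
})

test_that("classification equals whole-CDS translate-diff, exhaustively", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                  collapse = "")
  offsets <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  mismatch <- 0L
  for (codon in codons) {
    cds <- paste0("ATG", codon, "GGGTAA")   # embed mid-CDS
    ref <- cds_reference(cds)
    tx <- ref$transcripts[1, ]
    for (off in offsets) {
      b1 <- substr(codon, off[1] + 1L, off[1] + 1L)
      b2 <- substr(codon, off[2] + 1L, off[2] + 1L)
      for (a1 in setdiff(bases, b1)) for (a2 in setdiff(bases, b2)) {
        got <- combined_consequence(
          list(pos = 104L + off[1], ref = b1, alt = a1),
          list(pos = 104L + off[2], ref = b2, alt = a2), tx, ref
        )
        want <- brute_force_consequence(cds, 1L, off[1], off[2], a1, a2)
        if (got$category != want$category ||
            got$aa_mnv != want$aa_mnv) {
          mismatch <- mismatch + 1L
        }
      }
    }
  }
  expect_equal(mismatch, 0L)
})

test_that("a transcript and its reverse-complement mirror agree", {
  set.seed(9)
  cds <- paste0("ATG", paste(sample(c("CAC", "TCA", "CTG", "GGA", "TAT"),
                                    20, TRUE), collapse = ""), "TAA")
  ref_p <- cds_reference(cds)
  tx_p <- ref_p$transcripts[1, ]
  ref_m <- cds_reference(as.character(revcomp(cds)))
  tx_m <- ref_m$transcripts[1, ]; tx_m$strand <- "-"
  L <- nchar(cds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:40) {
    i <- sample(seq_len(L - 1L), 1L)
    j <- i + sample(1:2, 1L)
    if (j > L) next
    b1 <- substr(cds, i, i); b2 <- substr(cds, j, j)
    a1 <- sample(setdiff(names(comp), b1), 1L)
    a2 <- sample(setdiff(names(comp), b2), 1L)
    got_p <- combined_consequence(
      list(pos = 100L + i, ref = b1, alt = a1),
      list(pos = 100L + j, ref = b2, alt = a2), tx_p, ref_p
    )
    # mirrored coordinates on the minus-strand gene
    mi <- 100L + (L - j + 1L); mj <- 100L + (L - i + 1L)
    got_m <- combined_consequence(
      list(pos = mi, ref = comp[[b2]], alt = comp[[a2]]),
      list(pos = mj, ref = comp[[b1]], alt = comp[[a1]]), tx_m, ref_m
    )
    expect_equal(got_m$category, got_p$category)
    expect_equal(got_m$aa_mnv, got_p$aa_mnv)
  }
})

test_that("per-gene tallies respect the fully-rescued filter", {
  recs <- tibble::tibble(
    gene = c("G1", "G1", "G1", "G2"),
    category = c("gained_nonsense", "gained_nonsense",
                 "rescued_nonsense", "changed_missense"),
    fully_rescued = c(FALSE, FALSE, FALSE, FALSE),
    carriers = list("S1", "S1", "S2", "S3")
  )
  tal <- per_gene_tallies(recs, fully_rescued_only = FALSE)
  expect_equal(tal$gained_nonsense[tal$gene == "G1"], 2L)
  expect_equal(tal$rescued_nonsense[tal$gene == "G1"], 1L)
  # a rescue not shared by every nonsense carrier is excluded
  tal2 <- per_gene_tallies(recs, fully_rescued_only = TRUE)
  expect_equal(tal2$rescued_nonsense[tal2$gene == "G1"], 0L)
  expect_true(tal$has_nonsense_change[tal$gene == "G1"])
  expect_false(tal$has_nonsense_change[tal$gene == "G2"])
})

test_that("per-sample means count carriers of changed interpretations", {
  recs <- tibble::tibble(
    gene = "G", category = c("changed_missense", "gained_nonsense",
                             "unchanged"),
    fully_rescued = FALSE,
    carriers = list(c("S1", "S2"), "S1", c("S1", "S2", "S3"))
  )
  ps <- per_sample_tallies(recs, n_samples = 3L)
  expect_equal(
    ps$mean_per_individual[ps$category == "changed_interpretation"], 1
  )
  expect_equal(
    ps$mean_per_individual[ps$category == "gained_nonsense"], 1 / 3
  )
  empty <- per_sample_tallies(recs[0, ], n_samples = 5L)
  expect_true(all(empty$mean_per_individual == 0))
})

test_that("constraint enrichment: odds ratio and hypergeometric p", {
  mk <- function(a, b, c_, d) {
    tibble::tibble(
      gene = c(rep("CG", a), rep("NG", b), rep("CG", c_), rep("NG", d)),
      category = c(rep("rescued_nonsense", a + b),
                   rep("changed_missense", c_ + d)),
      fully_rescued = TRUE
    )
  }
  res <- constraint_enrichment(mk(10L, 90L, 20L, 380L), "CG")
  expect_equal(res$odds_ratio, (10 * 380) / (90 * 20))
  expect_equal(round(res$odds_ratio, 3), 2.111)
  # brute-force central hypergeometric two-sided tail sum
  tot <- 500L; k <- 30L; n_cat <- 100L
  probs <- dhyper(0:k, n_cat, tot - n_cat, k)
  p_manual <- sum(probs[probs <= dhyper(10L, n_cat, tot - n_cat, k) *
                          (1 + 1e-7)])
  expect_equal(res$p_value, p_manual, tolerance = 1e-6)
  # identical proportions: OR 1, p 1
  res2 <- constraint_enrichment(mk(10L, 90L, 30L, 270L), "CG")
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p_value, 1)
  # zero cell: Haldane correction is applied and flagged
  res3 <- constraint_enrichment(mk(0L, 100L, 30L, 270L), "CG")
  expect_true(res3$haldane_corrected)
  expect_error(constraint_enrichment(mk(10L, 90L, 20L, 380L), "CG",
                                     category = "gained_nonsense"),
               "no records")
})

test_that("frame-restoring indel pairs follow the length-change rule", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "indels.vcf")
  sites <- tibble::tibble(
    pos = c(100L, 112L, 200L, 203L, 300L, 335L),
    ref = c("CAGCT", "A", "CAGC", "T", "GTTAC", "G"),
    alt = c("C", "ATTTCTGA", "C", "TGCA", "G", "GTCACTGA")
  )
  gts <- list(c("0|1:1"), c("0|1:1"), c("0|1:1"), c("0|1:1"),
              c("0|1:1"), c("0|1:1"))
  write_mini_vcf(vcf, 1000L, sites, gts)
  pairs <- find_frame_restoring_indel_pairs(vcf, max_dist = 30L)
  # 4 bp deletion + 7 bp insertion, 12 bp apart: net +3 reported
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$pos1, 100L)
  expect_equal(pairs$net_length, 3L)
  # pair at 200/203 is 3bp-del + 3bp-ins: each in-frame, excluded;
  # pair at 300/335 exceeds 30 bp, excluded
})

test_that("coding annotation flags full rescues through allele counts", {
  # CAC codon; SNV2 C>A at offset 2 -> CAA; SNV1 C>T -> TAC... build a
  # codon where one SNV is nonsense: TAC: T>A? use TCA with C>G -> TGA
  ref <- cds_reference("ATGTCATAA")
  recs <- tibble::tibble(
    contig = "chr1", pos1 = 104L, pos2 = 105L,
    ref1 = "T", alt1 = "A", ref2 = "C", alt2 = "G",
    d = 1L, pattern = canonical_pattern("TC", "AG"),
    ac1 = 5L, ac2 = 5L, ac_mnv = 5L, n_hom = 0L, n_indiv = 5L,
    dlen1 = 0L, dlen2 = 0L, carriers = list(sprintf("S%d", 1:5))
  )
  ann <- annotate_coding_mnvs(recs, ref)
  expect_equal(ann$category, "rescued_nonsense")
  expect_true(ann$fully_rescued)      # ac_mnv equals the nonsense SNV's AC
  recs$ac_mnv <- 4L
  ann2 <- annotate_coding_mnvs(recs, ref)
  expect_false(ann2$fully_rescued)
})
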