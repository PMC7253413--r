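#' Genotype/site quality-control filter
#'
#' A call passes QC iff the site FILTER is `PASS`, the site lies outside
#' the low-complexity mask, GQ >= 20, DP >= 10, and - for heterozygous
#' calls - the allele balance exceeds 0.2.  Missing GQ or DP fails.
#'
#' @param gq,dp integer vectors (Phred genotype quality, depth).
#' @param ab numeric allele balance (alt-read fraction); only consulted for
#'   het calls.
#' @param het logical; whether the call is heterozygous.
#' @param filter_pass logical; site FILTER == "PASS".
#' @param in_lcr logical; site falls in the low-complexity mask.
#' @param min_gq,min_dp,min_ab thresholds (defaults 20, 10, 0.2).
#' @return logical vector.
#' @export
qc_pass <- function(gq, dp, ab, het, filter_pass = TRUE, in_lcr = FALSE,
                    min_gq = 20L, min_dp = 10L, min_ab = 0.2) {
  ok <- filter_pass & !in_lcr &
    !is.na(gq) & gq >= min_gq &
    !is.na(dp) & dp >= min_dp
  ok & (!het | (!is.na(ab) & ab > min_ab))
}

.AUTOSOME_EXCLUDE <- c("X", "Y", "chrX", "chrY", "MT", "chrM", "chrMT")

# cis haplotype count of a variant pair for every sample, given parsed
# genotype matrices at the two row indices.  Returns an integer vector
# (0/1/2 haplotypes carrying both alts) and attributes for trans calls.
.cis_haplotypes <- function(v, i1, i2, qc_ok) {
  n <- length(v$samples)
  a11 <- v$hap1[i1, ]; a21 <- v$hap2[i1, ]
  a12 <- v$hap1[i2, ]; a22 <- v$hap2[i2, ]
  ph1 <- v$phased[i1, ]; ph2 <- v$phased[i2, ]
  ps1 <- v$ps[i1, ]; ps2 <- v$ps[i2, ]

  alt1 <- !is.na(a11) & (a11 + a21 > 0L)
  alt2 <- !is.na(a12) & (a12 + a22 > 0L)
  hom1 <- !is.na(a11) & a11 == 1L & a21 == 1L
  hom2 <- !is.na(a12) & a12 == 1L & a22 == 1L
  het1 <- !is.na(a11) & (a11 + a21 == 1L)
  het2 <- !is.na(a12) & (a12 + a22 == 1L)

  cis <- integer(n)
  carrier <- alt1 & alt2 & qc_ok
  if (!any(carrier)) return(cis)

  # hom x hom: both haplotypes carry both alts (no phase needed)
  sel <- carrier & hom1 & hom2
  cis[sel] <- 2L

  # het x hom / hom x het: the het's alt haplotype is in cis, its ref
  # haplotype is not; no phase needed on either side
  sel <- carrier & ((het1 & hom2) | (hom1 & het2))
  cis[sel] <- 1L

  # het x het: needs both phased, same phase set, same side
  hh <- carrier & het1 & het2
  same_set <- hh & ph1 & ph2 & !is.na(ps1) & !is.na(ps2) & ps1 == ps2
  same_side <- same_set & (a11 == a12)
  cis[same_side] <- 1L
  cis
}

#' Scan a phased cohort VCF for in-cis variant pairs (MNVs)
#'
#' Re-implementation of windowed MNV discovery: every pair of variant
#' records within `max_dist` bp is checked, for every individual, for
#' co-occurrence of the two alternate alleles on one haplotype.  Pairs in
#' which either call fails QC in an individual do not draw evidence from
#' that individual; sites failing the site-level filters are dropped
#' entirely.  Haplotype counting: an individual homozygous for the MNV
#' contributes two haplotypes to `ac_mnv` and increments `n_hom`;
#' hom x hom pairs are counted as cis without phase information (zygosity
#' forces it) and het x hom pairs require only the het's phase.
#'
#' @param vcf path to a decomposed, normalized, phased multi-sample VCF.
#' @param max_dist window size in bp (10 for genome-style scans, 2 for
#'   exome-style).
#' @param variant_type `"SNV"` (default) or `"indel"`: both members of a
#'   pair must be of the selected class; mixed pairs are not scanned.
#' @param lcr optional low-complexity mask (tibble `contig`/`start`/`end`,
#'   1-based inclusive, or a path to a BED file).
#' @param autosomes_only drop records on X/Y/MT contigs.
#' @param qc apply the genotype-level QC of [qc_pass()] (site-level FILTER
#'   and LCR filters always apply).
#' @return tibble with one row per distinct in-cis pair:
#'   `contig`, `pos1`, `pos2`, `ref1`, `alt1`, `ref2`, `alt2`, `d`,
#'   `pattern` (canonical, SNV pairs only), `ac1`, `ac2` (cohort allele
#'   counts of the constituents), `ac_mnv` (haplotypes carrying both alts
#'   in cis), `n_hom`, `n_indiv`, `dlen1`, `dlen2` (indel length changes)
#'   and a `carriers` list-column of carrier sample ids.
#' @export
scan_mnvs <- function(vcf, max_dist = 10L, variant_type = c("SNV", "indel"),
                      lcr = NULL, autosomes_only = FALSE, qc = TRUE) {
  variant_type <- match.arg(variant_type)
  v <- if (is.list(vcf)) vcf else read_phased_vcf(vcf)
  sites <- v$sites

  if (is.character(lcr)) lcr <- read_bed(lcr)
  in_lcr <- rep(FALSE, nrow(sites))
  if (!is.null(lcr) && nrow(lcr)) {
    site_gr <- GenomicRanges::GRanges(
      sites$contig,
      IRanges::IRanges(sites$pos, sites$pos + nchar(sites$ref) - 1L)
    )
    hits <- GenomicRanges::findOverlaps(site_gr, .intervals_to_granges(lcr))
    in_lcr[unique(S4Vectors::queryHits(hits))] <- TRUE
  }

  keep_type <- if (variant_type == "SNV") {
    sites$type == "SNV"
  } else {
    sites$type %in% c("insertion", "deletion")
  }
  keep <- keep_type & sites$filter %in% "PASS" & !in_lcr
  if (autosomes_only) keep <- keep & !(sites$contig %in% .AUTOSOME_EXCLUDE)

  idx <- which(keep)
  # genotype QC is a per-record property; compute it once
  het_mat <- (v$hap1 + v$hap2) == 1L
  qc_rec <- if (qc) {
    m <- qc_pass(as.vector(v$gq), as.vector(v$dp), as.vector(v$ab),
                 as.vector(het_mat))
    matrix(m, nrow(het_mat))
  } else {
    matrix(TRUE, nrow(het_mat), ncol(het_mat))
  }

  i1s <- integer(0); i2s <- integer(0)
  for (ct in unique(sites$contig[idx])) {
    ci <- idx[sites$contig[idx] == ct]
    ci <- ci[order(sites$pos[ci])]
    pos <- sites$pos[ci]
    for (a in seq_along(ci)) {
      b <- a + 1L
      while (b <= length(ci) && pos[b] - pos[a] <= max_dist) {
        if (pos[b] > pos[a]) {
          i1s <- c(i1s, ci[a]); i2s <- c(i2s, ci[b])
        }
        b <- b + 1L
      }
    }
  }

  ac_mnv <- integer(length(i1s)); n_hom <- integer(length(i1s))
  n_indiv <- integer(length(i1s)); carriers <- vector("list", length(i1s))
  hit <- logical(length(i1s))
  for (k in seq_along(i1s)) {
    i1 <- i1s[k]; i2 <- i2s[k]
    cis <- .cis_haplotypes(v, i1, i2, qc_rec[i1, ] & qc_rec[i2, ])
    if (any(cis > 0L)) {
      hit[k] <- TRUE
      ac_mnv[k] <- sum(cis); n_hom[k] <- sum(cis == 2L)
      n_indiv[k] <- sum(cis > 0L)
      carriers[[k]] <- v$samples[cis > 0L]
    }
  }

  i1s <- i1s[hit]; i2s <- i2s[hit]
  snv_pair <- sites$type[i1s] == "SNV" & sites$type[i2s] == "SNV"
  d <- sites$pos[i2s] - sites$pos[i1s]
  pat <- rep(NA_character_, length(i1s))
  if (any(snv_pair)) {
    pat[snv_pair] <- canonical_pattern(
      paste0(sites$ref[i1s[snv_pair]], sites$ref[i2s[snv_pair]]),
      paste0(sites$alt[i1s[snv_pair]], sites$alt[i2s[snv_pair]]),
      d[snv_pair]
    )
  }
  tibble(
    contig = sites$contig[i1s],
    pos1 = sites$pos[i1s], pos2 = sites$pos[i2s],
    ref1 = sites$ref[i1s], alt1 = sites$alt[i1s],
    ref2 = sites$ref[i2s], alt2 = sites$alt[i2s],
    d = as.integer(d), pattern = pat,
    ac1 = sites$ac[i1s], ac2 = sites$ac[i2s],
    ac_mnv = ac_mnv[hit], n_hom = n_hom[hit], n_indiv = n_indiv[hit],
    dlen1 = nchar(sites$alt[i1s]) - nchar(sites$ref[i1s]),
    dlen2 = nchar(sites$alt[i2s]) - nchar(sites$ref[i2s]),
    carriers = carriers[hit]
  )
}

#' Write an MNV table as TSV
#'
#' Columns mirror released population MNV tables (carrier lists are
#' serialised with `;`).
#'
#' @param records MNV tibble from [scan_mnvs()].
#' @param path output path.
#' @export
write_mnv_tsv <- function(records, path) {
  flat <- records
  if (!is.null(flat$carriers)) {
    flat$carriers <- vapply(flat$carriers, paste, character(1),
                            collapse = ";")
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mnv_tsv
#' @return [read_mnv_tsv()] returns the MNV tibble (carriers re-split).
#' @export
read_mnv_tsv <- function(path) {
  out <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!is.null(out$carriers)) {
    out$carriers <- strsplit(as.character(out$carriers), ";", fixed = TRUE)
  }
  out
}
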