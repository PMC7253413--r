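.GENETIC_CODE <- Biostrings::GENETIC_CODE

.translate_codon <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

# genomic positions of a transcript's CDS in translation order
# (ascending for +, descending for -)
.cds_positions <- function(tx) {
  pos <- unlist(mapply(seq, tx$cds_starts[[1]], tx$cds_ends[[1]],
                       SIMPLIFY = FALSE))
  if (tx$strand == "-") rev(pos) else pos
}

.contig_seq <- function(ref, contig) {
  if (inherits(ref, "ReferenceBundle")) ref$contigs[[contig]] else
    ref[[contig]]
}

#' Locate a variant within a transcript's codons
#'
#' Strand-aware mapping of a genomic position to (codon index, offset,
#' reference codon).  For minus-strand transcripts codons are read on the
#' reverse complement, so offset 0 is the 3'-most genomic base of the
#' codon.
#'
#' @param pos 1-based genomic position of the variant.
#' @param tx one-row transcript tibble (see [read_transcripts_tsv()]).
#' @param ref `ReferenceBundle` or named character vector of contig
#'   sequences.
#' @return list with `codon_index` (0-based), `offset` (0/1/2),
#'   `ref_codon`; `NULL` when the position is not in the CDS.
#' @export
codon_of <- function(pos, tx, ref) {
  cds <- .cds_positions(tx)
  i <- match(pos, cds)
  if (is.na(i)) return(NULL)
  ci <- (i - 1L) %/% 3L
  seqs <- .contig_seq(ref, tx$contig)
  codon_pos <- cds[(ci * 3L + 1L):(ci * 3L + 3L)]
  bases <- substring(seqs, codon_pos, codon_pos)
  if (tx$strand == "-") bases <- unname(.COMP[bases])
  list(codon_index = ci, offset = (i - 1L) %% 3L,
       ref_codon = paste(bases, collapse = ""))
}

#' Classify a codon change given the three mutant amino acids
#'
#' Decision table over the amino acids (or `*` for stop) produced by SNV1
#' alone, SNV2 alone, and the combined MNV, relative to the reference
#' amino acid:
#' * `gained_nonsense`: the MNV is a stop but neither single SNV is.
#' * `rescued_nonsense`: at least one single SNV is a stop but the MNV is
#'   not.
#' * `gained_missense`: both single SNVs are synonymous yet the MNV
#'   changes the amino acid.
#' * `unchanged`: the MNV amino acid equals one of the single-SNV amino
#'   acids (the combined effect is already captured by an individual
#'   annotation).
#' * `changed_missense`: the MNV amino acid differs from both single-SNV
#'   amino acids, and the MNV and at least one constituent are missense.
#' * `other_changed`: everything else (e.g. stop-lost combinations).
#'
#' @param aa_ref,aa1,aa2,aa_mnv single-letter amino acids, `*` = stop.
#' @return category string.
#' @export
classify_codon_change <- function(aa_ref, aa1, aa2, aa_mnv) {
  stop_ <- "*"
  missense <- function(aa) aa != aa_ref && aa != stop_
  if (aa_mnv == stop_ && aa1 != stop_ && aa2 != stop_) {
    return("gained_nonsense")
  }
  if (aa_mnv != stop_ && (aa1 == stop_ || aa2 == stop_)) {
    return("rescued_nonsense")
  }
  if (aa1 == aa_ref && aa2 == aa_ref && aa_mnv != aa_ref) {
    return("gained_missense")
  }
  if (aa_mnv %in% c(aa1, aa2)) return("unchanged")
  if (missense(aa_mnv) && (missense(aa1) || missense(aa2))) {
    return("changed_missense")
  }
  "other_changed"
}

#' Combined codon consequence of a same-transcript SNV pair
#'
#' Translates the reference codon, each single-mutant codon, and the
#' double-mutant codon with the standard genetic code and applies
#' [classify_codon_change()].  Pairs falling in different codons are
#' returned with category `cross_codon` and no further annotation.
#'
#' @param v1,v2 lists with `pos`, `ref`, `alt` (plus-strand alleles),
#'   ordered by position; both must be SNVs inside the transcript CDS.
#' @param tx one-row transcript tibble.
#' @param ref reference bundle or named contig sequences.
#' @return one-row tibble (`gene`, `tx`, `codon_index`, `ref_codon`,
#'   codons and amino acids for SNV1/SNV2/MNV, `category`), or `NULL` if
#'   either variant is outside the CDS.
#' @export
combined_consequence <- function(v1, v2, tx, ref) {
  seqs <- .contig_seq(ref, tx$contig)
  for (v in list(v1, v2)) {
    have <- substring(seqs, v$pos, v$pos)
    if (have != v$ref) {
      stop("reference mismatch at ", tx$contig, ":", v$pos, " (VCF says ",
           v$ref, ", reference has ", have, ")")
    }
  }
  c1 <- codon_of(v1$pos, tx, ref)
  c2 <- codon_of(v2$pos, tx, ref)
  if (is.null(c1) || is.null(c2)) return(NULL)

  if (c1$codon_index != c2$codon_index) {
    return(tibble(
      gene = tx$gene, tx = tx$tx, codon_index = NA_integer_,
      ref_codon = NA_character_, codon1 = NA_character_,
      codon2 = NA_character_, codon_mnv = NA_character_,
      aa_ref = NA_character_, aa1 = NA_character_, aa2 = NA_character_,
      aa_mnv = NA_character_, category = "cross_codon"
    ))
  }

  alt_of <- function(v) if (tx$strand == "-") unname(.COMP[v$alt]) else v$alt
  mutate_codon <- function(codon, offsets, alts) {
    b <- strsplit(codon, "")[[1]]
    b[offsets + 1L] <- alts
    paste(b, collapse = "")
  }
  codon1 <- mutate_codon(c1$ref_codon, c1$offset, alt_of(v1))
  codon2 <- mutate_codon(c1$ref_codon, c2$offset, alt_of(v2))
  codon_m <- mutate_codon(c1$ref_codon, c(c1$offset, c2$offset),
                          c(alt_of(v1), alt_of(v2)))
  aa_ref <- .translate_codon(c1$ref_codon)
  aa1 <- .translate_codon(codon1)
  aa2 <- .translate_codon(codon2)
  aa_m <- .translate_codon(codon_m)

  tibble(
    gene = tx$gene, tx = tx$tx, codon_index = c1$codon_index,
    ref_codon = c1$ref_codon, codon1 = codon1, codon2 = codon2,
    codon_mnv = codon_m, aa_ref = aa_ref, aa1 = aa1, aa2 = aa2,
    aa_mnv = aa_m, category = classify_codon_change(aa_ref, aa1, aa2, aa_m)
  )
}

#' Annotate the coding consequence of scanned MNVs
#'
#' Joins an MNV table against the canonical transcripts of a reference
#' bundle and computes the combined codon consequence for every SNV pair
#' whose two variants fall inside one transcript's CDS.  The
#' `fully_rescued` flag marks rescued-nonsense MNVs whose allele count
#' equals the allele count of the nonsense-introducing SNV (the rescue
#' applies to every carrier of that nonsense variant).
#'
#' @param records MNV tibble from [scan_mnvs()] (SNV pairs).
#' @param transcripts transcript tibble; defaults to `ref$transcripts`.
#' @param ref reference bundle.
#' @return tibble: MNV columns plus the consequence columns of
#'   [combined_consequence()] and `fully_rescued`.
#' @export
annotate_coding_mnvs <- function(records, ref, transcripts = NULL) {
  if (is.null(transcripts)) transcripts <- ref$transcripts
  out <- list()
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    if (!is.na(rec$dlen1) && (rec$dlen1 != 0L || rec$dlen2 != 0L)) next
    for (t in seq_len(nrow(transcripts))) {
      tx <- transcripts[t, ]
      if (tx$contig != rec$contig) next
      cons <- combined_consequence(
        list(pos = rec$pos1, ref = rec$ref1, alt = rec$alt1),
        list(pos = rec$pos2, ref = rec$ref2, alt = rec$alt2),
        tx, ref
      )
      if (is.null(cons)) next
      row <- dplyr::bind_cols(rec, cons)
      row$fully_rescued <- FALSE
      if (cons$category == "rescued_nonsense") {
        ac_nonsense <- c(rec$ac1[[1]], rec$ac2[[1]])[
          c(cons$aa1, cons$aa2) == "*"]
        row$fully_rescued <- all(rec$ac_mnv == ac_nonsense)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    return(tibble(gene = character(), category = character(),
                  fully_rescued = logical()))
  }
  bind_rows(out)
}

#' Per-gene tallies of MNV consequence categories
#'
#' @param records annotated coding MNVs from [annotate_coding_mnvs()].
#' @param fully_rescued_only count only fully-rescued nonsense MNVs in the
#'   `rescued_nonsense` column (default `TRUE`).
#' @return tibble: one row per gene with counts per category and a flag
#'   for genes carrying any gained or rescued nonsense.
#' @export
per_gene_tallies <- function(records, fully_rescued_only = TRUE) {
  recs <- filter(records, .data$category != "cross_codon")
  if (fully_rescued_only) {
    recs <- filter(recs, .data$category != "rescued_nonsense" |
                     .data$fully_rescued)
  }
  recs %>%
    count(.data$gene, .data$category) %>%
    tidyr_pivot(.data$category, .data$n) %>%
    mutate(has_nonsense_change =
             rowSums(cbind(.data$gained_nonsense, .data$rescued_nonsense))
           > 0L)
}

# minimal wide pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(df, names_from, values_from) {
  cats <- c("unchanged", "changed_missense", "gained_nonsense",
            "rescued_nonsense", "gained_missense", "other_changed")
  wide <- unique(df["gene"])
  nm <- dplyr::pull(df, {{ names_from }})
  vl <- dplyr::pull(df, {{ values_from }})
  for (cat in cats) {
    v <- stats::setNames(vl[nm == cat], df$gene[nm == cat])
    wide[[cat]] <- as.integer(ifelse(is.na(v[wide$gene]), 0L,
                                     v[wide$gene]))
  }
  as_tibble(wide)
}

#' Mean per-individual counts of MNV consequence categories
#'
#' Counts, for every sample of the cohort, the MNVs of each category it
#' carries, and averages across the cohort.  `changed_interpretation`
#' aggregates every category whose combined annotation differs from the
#' individual annotations (everything but `unchanged` and `cross_codon`).
#'
#' @param records annotated coding MNVs (with `carriers` list-column).
#' @param n_samples cohort size.
#' @return tibble with `category` and `mean_per_individual`.
#' @export
per_sample_tallies <- function(records, n_samples) {
  cats <- c("changed_missense", "gained_nonsense", "rescued_nonsense",
            "gained_missense", "other_changed", "unchanged")
  rows <- lapply(cats, function(cat) {
    recs <- records[records$category == cat, ]
    tibble(category = cat,
           mean_per_individual =
             sum(lengths(recs$carriers)) / n_samples)
  })
  changed <- sum(lengths(
    records$carriers[!records$category %in% c("unchanged", "cross_codon")]
  )) / n_samples
  bind_rows(rows) %>%
    bind_rows(tibble(category = "changed_interpretation",
                     mean_per_individual = changed))
}

#' Enrichment of an MNV category in constrained genes
#'
#' Two-sided Fisher's exact test of the 2x2 table (category vs all other
#' categories) x (gene constrained vs not).  The odds ratio is the plain
#' cross-product ad/bc; a Haldane correction of 0.5 is applied (and
#' flagged) only when a cell is zero.
#'
#' @param records annotated coding MNVs.
#' @param constrained_genes character vector of constrained gene ids
#'   (e.g. the top two LOEUF deciles).
#' @param category category to test (default `"rescued_nonsense"`).
#' @return list: `table` (2x2), `odds_ratio`, `p_value`,
#'   `haldane_corrected`, `prop_category`, `prop_others`.
#' @export
constraint_enrichment <- function(records, constrained_genes,
                                  category = "rescued_nonsense") {
  recs <- filter(records, .data$category != "cross_codon")
  in_cat <- recs$category == category
  if (!any(in_cat)) stop("no records in category ", category)
  cons <- recs$gene %in% constrained_genes
  a <- sum(in_cat & cons); b <- sum(in_cat & !cons)
  c_ <- sum(!in_cat & cons); d <- sum(!in_cat & !cons)
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(c(category, "others"),
                                c("constrained", "not_constrained")))
  haldane <- any(tab == 0L)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, p_value = p,
       haldane_corrected = haldane,
       prop_category = a / (a + b), prop_others = c_ / (c_ + d))
}

#' Frame-restoring indel pairs
#'
#' In-cis indel pairs within `max_dist` bp in which each indel alone
#' shifts the reading frame (length change not a multiple of 3) while the
#' summed length change restores it (multiple of 3) - e.g. a 4 bp deletion
#' plus a 7 bp insertion yielding a net one-amino-acid insertion.
#'
#' @param vcf path to the phased VCF (or parsed list).
#' @param max_dist maximum pair distance (default 30 bp, the practical
#'   limit of read-based phasing).
#' @param ... passed to [scan_mnvs()] (`lcr`, `qc`, ...).
#' @return MNV-style tibble restricted to frame-restoring pairs, with
#'   `net_length` added.
#' @export
find_frame_restoring_indel_pairs <- function(vcf, max_dist = 30L, ...) {
  pairs <- scan_mnvs(vcf, max_dist = max_dist, variant_type = "indel", ...)
  keep <- pairs$dlen1 %% 3L != 0L & pairs$dlen2 %% 3L != 0L &
    (pairs$dlen1 + pairs$dlen2) %% 3L == 0L
  out <- pairs[keep, ]
  out$net_length <- out$dlen1 + out$dlen2
  out
}
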