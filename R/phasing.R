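#' A single-sample genotype call
#'
#' Light-weight record of one genotype used by the phasing and QC logic.
#'
#' @param sample sample id.
#' @param a1,a2 allele indices (0 = ref, 1 = alt).
#' @param phased logical; whether the `a1|a2` order is haplotype-resolved.
#' @param ps phase-set id (only meaningful when `phased`).
#' @param gq Phred-scaled genotype quality.
#' @param dp read depth.
#' @param ab alternate-read fraction; only defined for heterozygous calls.
#' @return list of class `genotype_call`.
#' @export
genotype_call <- function(sample, a1, a2, phased = FALSE, ps = NA_integer_,
                          gq = NA_integer_, dp = NA_integer_,
                          ab = NA_real_) {
  het <- !is.na(a1) && !is.na(a2) && (a1 + a2 == 1L)
  if (!het) ab <- NA_real_
  if (!phased) ps <- NA_integer_
  structure(list(sample = sample, a1 = as.integer(a1), a2 = as.integer(a2),
                 phased = isTRUE(phased), ps = as.integer(ps),
                 gq = as.integer(gq), dp = as.integer(dp),
                 ab = as.numeric(ab)),
            class = "genotype_call")
}

# haplotype sides (1 and/or 2) known to carry the alt allele; NULL if the
# call carries no alt, NA if the sides cannot be resolved
.alt_sides <- function(g) {
  if (is.na(g$a1) || is.na(g$a2)) return(NA)
  n_alt <- (g$a1 == 1L) + (g$a2 == 1L)
  if (n_alt == 0L) return(integer(0))
  if (n_alt == 2L) return(c(1L, 2L))          # hom alt: both sides
  if (!g$phased) return(NA)                    # unresolved het
  if (g$a1 == 1L) 1L else 2L
}

#' Relative phase of a variant pair from read-based phasing
#'
#' Classifies two genotype calls of the same sample as `cis` (the alternate
#' alleles sit on the same haplotype), `trans` (opposite haplotypes) or
#' `unphased`.  Heterozygous calls are only comparable when both are phased
#' in the same phase set; homozygous-alt calls occupy both haplotypes, so
#' they resolve without phase information.
#'
#' @param g1,g2 `genotype_call` objects from the same sample, ordered by
#'   position.
#' @return character scalar: `"cis"`, `"trans"` or `"unphased"`.
#' @export
read_based_pair_phase <- function(g1, g2) {
  if (!identical(g1$sample, g2$sample)) {
    stop("read_based_pair_phase: calls come from different samples")
  }
  s1 <- .alt_sides(g1); s2 <- .alt_sides(g2)
  if (length(s1) == 0L || length(s2) == 0L) return("unphased")
  both_het_phased <- g1$phased && g2$phased &&
    length(s1) == 1L && length(s2) == 1L
  if (both_het_phased && (is.na(g1$ps) || is.na(g2$ps) || g1$ps != g2$ps)) {
    return("unphased")
  }
  if (anyNA(s1) || anyNA(s2)) {
    # one call unresolved; a hom-alt partner still resolves the pair
    if (!anyNA(s1) && length(s1) == 2L) return("cis")
    if (!anyNA(s2) && length(s2) == 2L) return("cis")
    return("unphased")
  }
  if (length(intersect(s1, s2)) > 0L) "cis" else "trans"
}

# parental origins of the two alleles of an unphased child genotype;
# returns "father"/"mother" for the alt allele of a het call, "ambiguous",
# or "violation"
.transmission_origin <- function(child, father, mother) {
  if (anyNA(child)) return("ambiguous")
  can_give <- function(par, allele) anyNA(par) || allele %in% par
  ass <- list(c(child[1], child[2]), c(child[2], child[1]))
  ok <- vapply(ass, function(a) {
    can_give(father, a[1]) && can_give(mother, a[2])
  }, logical(1))
  if (!any(ok)) return("violation")
  if (sum(child) != 1L) return("ambiguous")    # only het calls informative
  origins <- vapply(ass[ok], function(a) {
    if (a[1] == 1L) "father" else "mother"
  }, character(1))
  origins <- unique(origins)
  if (length(origins) == 1L) origins else "ambiguous"
}

#' Relative phase of a child's het variant pair by transmission
#'
#' Deterministic phase-by-transmission for a pair of heterozygous sites in
#' a trio child: each child alternate allele is assigned a parental origin
#' when the parental genotype configuration forces it at that site (for
#' example, one parent homozygous reference).  The pair is `cis` when both
#' alternates trace to the same parent, `trans` otherwise, and
#' `uninformative` when either site cannot be assigned - notably when both
#' parents are heterozygous.  A Mendelian inconsistency at either site
#' yields `violation` and the pair is excluded from concordance scoring.
#'
#' @param child1,child2 integer pairs `c(a1, a2)` of the child's (unordered)
#'   genotypes at site 1 and 2; both must be heterozygous.
#' @param father1,father2,mother1,mother2 parental genotypes at the two
#'   sites, `c(a1, a2)` or `NULL`/`NA` when missing (treated as able to
#'   transmit anything, hence uninformative).
#' @return character scalar: `"cis"`, `"trans"`, `"uninformative"` or
#'   `"violation"`.
#' @export
phase_by_transmission <- function(child1, child2, father1, father2,
                                  mother1, mother2) {
  norm <- function(g) if (is.null(g)) c(NA_integer_, NA_integer_) else g
  if (sum(child1) != 1L || sum(child2) != 1L) {
    stop("phase_by_transmission requires the child het at both sites")
  }
  o1 <- .transmission_origin(child1, norm(father1), norm(mother1))
  o2 <- .transmission_origin(child2, norm(father2), norm(mother2))
  if (o1 == "violation" || o2 == "violation") return("violation")
  if (o1 == "ambiguous" || o2 == "ambiguous") return("uninformative")
  if (o1 == o2) "cis" else "trans"
}

#' Distance bin labels for phasing summaries
#'
#' Distances 1-10 bp are binned individually; beyond that, 10 bp-wide bins
#' (11-20, 21-30, ...).
#'
#' @param d integer distances.
#' @return factor of bin labels ordered by distance.
#' @export
distance_bin <- function(d) {
  lab <- ifelse(d <= 10L, as.character(d),
                paste0((d - 1L) %/% 10L * 10L + 1L, "-",
                       ((d - 1L) %/% 10L + 1L) * 10L))
  lev <- c(as.character(1:10),
           unique(lab[d > 10L][order(d[d > 10L])]))
  factor(lab, levels = unique(lev))
}

#' Concordance of read-based and trio-based phasing
#'
#' Summarises, per distance bin: phasing sensitivity (fraction of het pairs
#' with read-based phase assigned), cis specificity (fraction of read-cis
#' pairs that trio phasing also calls cis, among trio-informative pairs)
#' and overall concordance (fraction of trio-informative, read-assigned
#' pairs whose relations agree).  Pairs with a Mendelian violation are
#' excluded up front.
#'
#' @param pairs tibble with columns `d`, `read_phase`
#'   (`cis`/`trans`/`unphased`) and `trio_phase`
#'   (`cis`/`trans`/`uninformative`/`violation`).
#' @return tibble: `distance_bin`, `n_pairs`, `sensitivity`,
#'   `specificity_cis`, `concordance_all`; empty input gives an empty
#'   table.
#' @export
phasing_concordance <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble(distance_bin = factor(), n_pairs = integer(),
                  sensitivity = numeric(), specificity_cis = numeric(),
                  concordance_all = numeric()))
  }
  pairs <- filter(pairs, .data$trio_phase != "violation")
  pairs$bin <- distance_bin(pairs$d)
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  pairs %>%
    group_by(distance_bin = .data$bin) %>%
    summarise(
      n_pairs = n(),
      sensitivity = frac(sum(.data$read_phase != "unphased"), n()),
      specificity_cis = frac(
        sum(.data$read_phase == "cis" & .data$trio_phase == "cis"),
        sum(.data$read_phase == "cis" &
              .data$trio_phase %in% c("cis", "trans"))
      ),
      concordance_all = frac(
        sum(.data$read_phase == .data$trio_phase &
              .data$trio_phase %in% c("cis", "trans")),
        sum(.data$read_phase != "unphased" &
              .data$trio_phase %in% c("cis", "trans"))
      ),
      .groups = "drop"
    )
}

#' Evaluate phasing on a trio cohort
#'
#' Runs the full read-vs-trio comparison over the het variant pairs listed
#' in a truth manifest (or any pair table): extracts the child's read-based
#' relative phase from the VCF, applies [phase_by_transmission()] with the
#' parental genotypes, and returns the per-pair table suitable for
#' [phasing_concordance()].
#'
#' @param vcf path to the trio VCF.
#' @param ped pedigree tibble (see [read_ped()]) or path to a PED file.
#' @param pairs tibble with columns `child`, `contig`, `pos1`, `pos2`.
#' @return input `pairs` with `read_phase` and `trio_phase` columns added.
#' @export
evaluate_trio_pairs <- function(vcf, ped, pairs) {
  if (is.character(ped)) ped <- read_ped(ped)
  v <- read_phased_vcf(vcf)
  key <- paste(v$sites$contig, v$sites$pos)
  sidx <- stats::setNames(seq_along(v$samples), v$samples)
  kids <- ped[ped$pat != "0", ]
  fathers <- stats::setNames(kids$pat, kids$iid)
  mothers <- stats::setNames(kids$mat, kids$iid)

  get_call <- function(i, s) {
    genotype_call(v$samples[s], v$hap1[i, s], v$hap2[i, s],
                  phased = v$phased[i, s], ps = v$ps[i, s],
                  gq = v$gq[i, s], dp = v$dp[i, s], ab = v$ab[i, s])
  }
  gt_pair <- function(i, s) c(v$hap1[i, s], v$hap2[i, s])

  read_phase <- character(nrow(pairs))
  trio_phase <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i1 <- match(paste(pairs$contig[r], pairs$pos1[r]), key)
    i2 <- match(paste(pairs$contig[r], pairs$pos2[r]), key)
    ch <- sidx[[pairs$child[r]]]
    fa <- sidx[[fathers[[pairs$child[r]]]]]
    mo <- sidx[[mothers[[pairs$child[r]]]]]
    read_phase[r] <- read_based_pair_phase(get_call(i1, ch),
                                           get_call(i2, ch))
    trio_phase[r] <- phase_by_transmission(
      gt_pair(i1, ch), gt_pair(i2, ch),
      gt_pair(i1, fa), gt_pair(i2, fa),
      gt_pair(i1, mo), gt_pair(i2, mo)
    )
  }
  pairs$read_phase <- read_phase
  pairs$trio_phase <- trio_phase
  pairs
}
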