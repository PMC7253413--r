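#' Specification of randomly placed repeat tracts
#'
#' Convenience builder for the `repeat_spec` argument of
#' [generate_reference()].  Dinucleotide units (e.g. `"TA"`) produce tandem
#' tracts `unit x copies`; mononucleotide units (e.g. `"A"`) produce a
#' slippage-prone junction tract written as `copies` complement bases
#' followed by `copies` unit bases (e.g. `TTTTTAAAAA`), the context in which
#' slippage generates AA>TT-type doublets.
#'
#' @param n_tracts number of tracts.
#' @param units character vector of 1-2 bp repeat units to cycle through.
#' @param copies repeat-unit copies per tract.
#' @return list of `list(unit=, copies=)` entries (positions auto-assigned).
#' @export
default_repeat_spec <- function(n_tracts = 200L, units = c("TA", "AT", "A"),
                                copies = 8L) {
  lapply(seq_len(n_tracts), function(i) {
    list(unit = units[((i - 1L) %% length(units)) + 1L], copies = copies)
  })
}

.tract_length <- function(unit, copies) {
  if (nchar(unit) == 1L) 2L * copies else nchar(unit) * copies
}

.tract_seq <- function(unit, copies) {
  if (nchar(unit) == 1L) {
    paste0(strrep(unname(.COMP[unit]), copies), strrep(unit, copies))
  } else {
    strrep(unit, copies)
  }
}

.random_cds <- function(n_codon) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  paste0("ATG",
         paste(sample(sense, n_codon - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

#' Generate a synthetic reference bundle
#'
#' Builds a random reference contig with requested repeat tracts and
#' protein-coding genes planted at fixed or random positions, together with
#' transcript models, optional annotation interval sets with methylation
#' levels, and an optional low-complexity mask.  Deterministic for a fixed
#' seed.
#'
#' Gene CDSs are start-codon + stop-free sense codons + stop codon, so
#' translation never hits an internal stop.  Minus-strand genes are written
#' as the reverse complement of the coding sequence.
#'
#' @param length contig length in bp (>= 1000).
#' @param repeat_spec list of `list(unit, copies, position = NULL)`; units
#'   are 1-2 bp; see [default_repeat_spec()].
#' @param gene_spec list of `list(gene, cds_len, strand = "+",
#'   start = NULL, n_exons = 1, loeuf_decile = NULL)`; `cds_len` must be a
#'   multiple of 3 and >= 9.
#' @param annotation_spec optional list of `list(category, n_intervals,
#'   interval_length, methylation)` describing annotation interval sets.
#' @param lcr optional tibble (`contig`, `start`, `end`, 1-based inclusive)
#'   low-complexity mask.
#' @param seed integer RNG seed.
#' @param contig_name contig id (default `"chr1"`).
#' @return object of class `ReferenceBundle`: list with `contigs` (named
#'   character), `transcripts`, `annotations`, `lcr`, `repeats`, `seed`.
#' @export
generate_reference <- function(length = 100000L, repeat_spec = list(),
                               gene_spec = list(), annotation_spec = NULL,
                               lcr = NULL, seed = 1L,
                               contig_name = "chr1") {
  stopifnot(length >= 1000L)
  set.seed(seed)
  chars <- sample(.BASES, length, replace = TRUE)
  occupied <- logical(length)

  place <- function(width, at = NULL) {
    if (!is.null(at)) {
      if (at < 1L || at + width - 1L > length) {
        stop("placement error: feature of width ", width, " at position ",
             at, " exceeds contig bounds")
      }
      if (any(occupied[at:(at + width - 1L)])) {
        stop("placement error: overlapping repeat/gene placement at ", at)
      }
      return(at)
    }
    for (try in 1:2000) {
      cand <- sample.int(length - width - 20L, 1L) + 10L
      if (!any(occupied[cand:(cand + width - 1L)])) return(cand)
    }
    stop("placement error: no free position for feature of width ", width)
  }

  repeats <- list()
  for (rs in repeat_spec) {
    if (!nchar(rs$unit) %in% 1:2) stop("repeat units must be 1-2 bp")
    w <- .tract_length(rs$unit, rs$copies)
    at <- place(w, rs$position)
    chars[at:(at + w - 1L)] <- strsplit(.tract_seq(rs$unit, rs$copies),
                                        "")[[1]]
    occupied[max(1L, at - 10L):min(length, at + w + 9L)] <- TRUE
    repeats[[length(repeats) + 1L]] <- tibble(
      contig = contig_name, start = at, end = at + w - 1L,
      unit = rs$unit, copies = rs$copies
    )
  }
  repeats <- if (length(repeats)) bind_rows(repeats) else {
    tibble(contig = character(), start = integer(), end = integer(),
           unit = character(), copies = integer())
  }

  transcripts <- list()
  for (gs in gene_spec) {
    if (gs$cds_len %% 3L != 0L || gs$cds_len < 9L) {
      stop("gene CDS length must be a multiple of 3 and >= 9")
    }
    strand <- if (is.null(gs$strand)) "+" else gs$strand
    n_exons <- if (is.null(gs$n_exons)) 1L else as.integer(gs$n_exons)
    intron_len <- 50L
    width <- gs$cds_len + (n_exons - 1L) * intron_len
    at <- place(width, gs$start)
    cds <- .random_cds(gs$cds_len %/% 3L)
    genomic_cds <- if (strand == "+") cds else revcomp(cds)
    # split the genomic-orientation CDS into exon chunks left to right
    cut <- floor(seq(0L, gs$cds_len, length.out = n_exons + 1L))
    starts <- integer(n_exons); ends <- integer(n_exons)
    offset <- at
    for (e in seq_len(n_exons)) {
      exon_len <- cut[e + 1L] - cut[e]
      seg <- substr(genomic_cds, cut[e] + 1L, cut[e + 1L])
      chars[offset:(offset + exon_len - 1L)] <- strsplit(seg, "")[[1]]
      starts[e] <- offset; ends[e] <- offset + exon_len - 1L
      offset <- offset + exon_len + intron_len
    }
    occupied[max(1L, at - 10L):min(length, at + width + 9L)] <- TRUE
    transcripts[[length(transcripts) + 1L]] <- tibble(
      gene = gs$gene, tx = paste0(gs$gene, ".t1"), contig = contig_name,
      strand = strand, cds_starts = list(starts), cds_ends = list(ends),
      loeuf_decile = if (is.null(gs$loeuf_decile)) {
        sample.int(10L, 1L)
      } else {
        as.integer(gs$loeuf_decile)
      }
    )
  }
  transcripts <- if (length(transcripts)) bind_rows(transcripts) else {
    tibble(gene = character(), tx = character(), contig = character(),
           strand = character(), cds_starts = list(), cds_ends = list(),
           loeuf_decile = integer())
  }

  annotations <- tibble(contig = character(), start = integer(),
                        end = integer(), category = character(),
                        methylation = numeric())
  if (!is.null(annotation_spec)) {
    rows <- list()
    for (as_ in annotation_spec) {
      w <- as.integer(as_$interval_length)
      st <- sort(sample.int(length - w - 1L, as_$n_intervals))
      rows[[length(rows) + 1L]] <- tibble(
        contig = contig_name, start = st, end = st + w - 1L,
        category = as_$category,
        methylation = if (is.null(as_$methylation)) NA_real_ else
          as_$methylation
      )
    }
    annotations <- bind_rows(rows)
  }

  if (is.null(lcr)) {
    lcr <- tibble(contig = character(), start = integer(), end = integer())
  }

  out <- list(
    contigs = stats::setNames(paste(chars, collapse = ""), contig_name),
    transcripts = transcripts, annotations = annotations, lcr = lcr,
    repeats = repeats, seed = seed
  )
  class(out) <- "ReferenceBundle"
  validate_reference(out)
  out
}

#' Validate a reference bundle's invariants
#' @param ref `ReferenceBundle`.
#' @return `ref`, invisibly; errors on violation.
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "ReferenceBundle"))
  for (nm in names(ref$contigs)) {
    s <- ref$contigs[[nm]]
    if (nchar(s) == 0L) stop("empty contig ", nm)
    if (grepl("[^ACGT]", s)) stop("contig ", nm, " has non-ACGT characters")
  }
  for (i in seq_len(nrow(ref$transcripts))) {
    len <- sum(ref$transcripts$cds_ends[[i]] -
                 ref$transcripts$cds_starts[[i]] + 1L)
    if (len %% 3L != 0L) {
      stop("transcript ", ref$transcripts$tx[i],
           ": CDS length not divisible by 3")
    }
  }
  bounds_ok <- function(tb) {
    all(tb$start >= 1L) &&
      all(tb$end <= nchar(ref$contigs[tb$contig]))
  }
  if (nrow(ref$annotations) && !bounds_ok(ref$annotations)) {
    stop("annotation interval out of contig bounds")
  }
  if (nrow(ref$lcr) && !bounds_ok(ref$lcr)) {
    stop("LCR interval out of contig bounds")
  }
  invisible(ref)
}

#' Cohort-generation parameters
#'
#' Bundles the knobs of [plant_cohort()].  Defaults describe the cohort the
#' package's own analyses run on: 1000 diploid samples, adjacent (1 bp)
#' MNV events dominated by independent-SNV combinations with smaller
#' polymerase-zeta and slippage components, geometric allele counts, full
#' per-contig phase sets and no genotyping noise.
#'
#' @param n_samples diploid samples in the cohort.
#' @param n_events planted cis MNV events.
#' @param mechanism_mix named probabilities over
#'   `independent_snv` / `pol_zeta` / `slippage`; must sum to 1.
#' @param ac_geom_prob geometric parameter for planted allele counts
#'   (AC = 1 + Geom(p)); documented in the cohort metadata.
#' @param ac_cap upper bound on planted allele counts.
#' @param max_distance largest pos2 - pos1 for independent events.
#' @param distance_weights named numeric over distances `1..max_distance`
#'   for independent events; default all mass on 1 (adjacent MNVs, the
#'   focus of the mechanism analyses).  Doublet mechanisms are always
#'   adjacent.
#' @param trans_rate fraction (of `n_events`) of additional variant pairs
#'   planted in trans, which a correct scanner must never emit.
#' @param noise_unphased_rate probability that a heterozygous genotype
#'   loses its phase information (emulates incomplete read-based phasing).
#' @param ps_fragment_length phase-set block length in bp; `Inf` gives one
#'   phase set per contig, finite values fragment phase sets so pairs
#'   spanning a block boundary are unphased relative to each other.
#' @param rate_table SNV rate table driving the pattern mix of
#'   independent-SNV events.
#' @param clean_contexts when `TRUE` (default) independent and pol-zeta
#'   events are only planted at sites whose +/-4 bp context is not
#'   repetitive, so planted slippage events are the only
#'   repetitive-context MNVs.
#' @param methylation_response slope b >= 0: the relative planting weight of
#'   a CpG-class independent event at a position with annotation methylation
#'   level m is `1 + b * m`.  0 (default) plants uniformly.
#' @param gq,dp constant genotype quality / depth written for every call.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1000L, n_events = 1500L,
                        mechanism_mix = c(independent_snv = 0.8,
                                          pol_zeta = 0.1, slippage = 0.1),
                        ac_geom_prob = 0.5, ac_cap = 20L,
                        max_distance = 10L, distance_weights = c("1" = 1),
                        trans_rate = 0.02, noise_unphased_rate = 0,
                        ps_fragment_length = Inf,
                        rate_table = default_rate_table(),
                        clean_contexts = TRUE, methylation_response = 0,
                        gq = 99L, dp = 30L) {
  mechanism_mix <- mechanism_mix[c("independent_snv", "pol_zeta",
                                   "slippage")]
  mechanism_mix[is.na(mechanism_mix)] <- 0
  names(mechanism_mix) <- c("independent_snv", "pol_zeta", "slippage")
  if (abs(sum(mechanism_mix) - 1) > 1e-8) {
    stop("mechanism_mix probabilities must sum to 1")
  }
  stopifnot(n_samples >= 1L, n_events >= 0L, ac_geom_prob > 0,
            ac_geom_prob <= 1, max_distance >= 1L,
            noise_unphased_rate >= 0, noise_unphased_rate <= 1,
            methylation_response >= 0)
  structure(
    list(n_samples = as.integer(n_samples), n_events = as.integer(n_events),
         mechanism_mix = mechanism_mix, ac_geom_prob = ac_geom_prob,
         ac_cap = as.integer(ac_cap), max_distance = as.integer(max_distance),
         distance_weights = distance_weights, trans_rate = trans_rate,
         noise_unphased_rate = noise_unphased_rate,
         ps_fragment_length = ps_fragment_length, rate_table = rate_table,
         clean_contexts = clean_contexts,
         methylation_response = methylation_response,
         gq = as.integer(gq), dp = as.integer(dp)),
    class = "cohort_spec"
  )
}

.hap_sample <- function(h) (h + 1L) %/% 2L
.hap_side <- function(h) 2L - (h %% 2L)

# positions i (1-based) with chars[i] == first base, chars[i + d] == second
.dinuc_positions <- function(chars, dinuc, d = 1L) {
  n <- length(chars)
  b1 <- substr(dinuc, 1, 1); b2 <- substr(dinuc, 2, 2)
  idx <- which(chars[seq_len(n - d)] == b1)
  idx[chars[idx + d] == b2]
}

#' Plant a phased cohort with MNVs of known mechanism
#'
#' Each sample is represented as two explicit haplotypes; genotypes are
#' derived from them, so the cis/trans truth is exact.  Events are planted
#' by mechanism:
#' * `independent_snv` - two SNVs on a shared haplotype whose adjacent
#'   substitution pattern is drawn in proportion to the independent-SNV
#'   null model (path probability x reference dinucleotide count) of
#'   `spec$rate_table`; the two constituent allele counts are drawn
#'   independently, so AC1 and AC2 can differ.
#' * `pol_zeta` - doublets with the polymerase-zeta motif (GA>TT or GC>AA
#'   after canonicalization) placed on the same haplotypes at every carrier:
#'   AC1 = AC2 = AC_mnv.
#' * `slippage` - doublets planted inside repeat tracts of the reference
#'   (TA>AT / AT>TA in dinucleotide tracts, AA>TT at mononucleotide
#'   junctions), with equal allele counts.
#'
#' Additional pairs in trans and unphased genotype noise are controlled by
#' `spec`.  The emitted VCF carries phased GT plus PS/GQ/DP/AD.
#'
#' @param ref `ReferenceBundle` from [generate_reference()].
#' @param spec `cohort_spec`.
#' @param seed integer RNG seed.
#' @param out_dir output directory (created if needed; default a fresh
#'   tempdir subdirectory).
#' @param write_vcf emit the VCF file (default `TRUE`).  When `FALSE`,
#'   only the in-memory genotype view is returned, which large simulation
#'   studies use to avoid file round-trips.
#' @return list with `vcf` (path, `NA` when not written), `truth`
#'   (tibble: the planted-event manifest with mechanism labels, positions,
#'   alleles, canonical pattern, planted AC1/AC2/AC_mnv, n_hom and
#'   in-repeat flag), `samples`, `genotypes` (parsed-genotype list
#'   equivalent to [read_phased_vcf()] output, accepted directly by
#'   [scan_mnvs()]), `metadata` (path to a key=value description of the
#'   generative model).
#' @export
plant_cohort <- function(ref, spec, seed = 1L, out_dir = NULL,
                         write_vcf = TRUE) {
  stopifnot(inherits(ref, "ReferenceBundle"), inherits(spec, "cohort_spec"))
  set.seed(seed)
  if (is.null(out_dir)) {
    out_dir <- file.path(tempfile("cohort"), "")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  contig <- names(ref$contigs)[1]
  chars <- strsplit(ref$contigs[[contig]], "")[[1]]
  L <- length(chars)
  blocked <- logical(L)
  blocked[seq_len(min(20L, L))] <- TRUE
  blocked[max(1L, L - 20L):L] <- TRUE
  # never plant non-slippage events into (or adjacent to) repeat tracts
  if (nrow(ref$repeats)) {
    for (i in seq_len(nrow(ref$repeats))) {
      lo <- max(1L, ref$repeats$start[i] - 12L)
      hi <- min(L, ref$repeats$end[i] + 12L)
      blocked[lo:hi] <- TRUE
    }
  }

  # per-position methylation level (0 outside annotated intervals)
  meth <- numeric(L)
  ann <- ref$annotations
  if (nrow(ann)) {
    ann2 <- ann[ann$contig == contig & !is.na(ann$methylation), ]
    for (i in seq_len(nrow(ann2))) {
      rng <- ann2$start[i]:ann2$end[i]
      meth[rng] <- pmax(meth[rng], ann2$methylation[i])
    }
  }

  n2 <- 2L * spec$n_samples
  draw_ac <- function() {
    min(1L + stats::rgeom(1L, spec$ac_geom_prob), spec$ac_cap, n2)
  }

  nw <- null_pattern_weights(spec$rate_table, ref)
  pats <- pattern_components(nw$pattern)
  cpg_class <- pattern_origin_classes()$cpg
  cpg_pattern <- pats$pattern %in% cpg_class

  dinuc_index <- new.env(parent = emptyenv())
  get_positions <- function(dinuc, d) {
    key <- paste0(dinuc, ".", d)
    if (is.null(dinuc_index[[key]])) {
      dinuc_index[[key]] <- .dinuc_positions(chars, dinuc, d)
    }
    dinuc_index[[key]]
  }

  # per-pattern strand-orientation choices and weights, computed once
  orient_cache <- lapply(seq_len(nrow(nw)), function(i) {
    o1 <- c(pats$ref[i], pats$alt[i])
    o2 <- c(.rc2(pats$ref[i]), .rc2(pats$alt[i]))
    orients <- unique(list(o1, o2))
    weights <- vapply(orients, function(o) {
      p <- null_path_probability(o[1], o[2], spec$rate_table)$p_null
      p * max(1L, length(get_positions(o[1], 1L)))
    }, numeric(1))
    list(orients = orients, weights = weights)
  })

  pick_site <- function(ref2, alt2, d, check_clean, meth_weight) {
    cand <- get_positions(ref2, d)
    for (try in 1:400) {
      if (!length(cand)) break
      p1 <- cand[sample.int(length(cand), 1L)]
      p2 <- p1 + d
      if (p1 < 6L || p2 > L - 5L) next
      if (any(blocked[p1:p2])) next
      if (check_clean &&
          .context_repetitive(chars, p1, d, ref2, alt2)) next
      if (meth_weight > 0) {
        w <- 1 + meth_weight * meth[p1]
        wmax <- 1 + meth_weight
        if (stats::runif(1) > w / wmax) next
      }
      return(p1)
    }
    NA_integer_
  }

  block_site <- function(p1, p2) {
    lo <- max(1L, p1 - 14L); hi <- min(L, p2 + 14L)
    blocked[lo:hi] <<- TRUE
  }

  n_mech <- stats::rmultinom(1L, spec$n_events, spec$mechanism_mix)[, 1]
  mech_labels <- rep(names(n_mech), n_mech)
  mech_labels <- sample(mech_labels)

  # slippage needs repeat tracts; sample them without replacement
  tracts <- ref$repeats[ref$repeats$contig == contig, ]
  if (n_mech[["slippage"]] > nrow(tracts)) {
    stop("capacity error: ", n_mech[["slippage"]],
         " slippage events requested but only ", nrow(tracts),
         " repeat tracts available")
  }
  tract_order <- sample.int(nrow(tracts))
  tract_ptr <- 0L

  events <- list()
  variants <- list()     # each: contig, pos, ref, alt, carriers (hap ids)

  add_event <- function(mechanism, p1, d, ref2, alt2, in_repeat) {
    p2 <- p1 + d
    ac_mnv <- draw_ac()
    carriers <- sample.int(n2, ac_mnv)
    extra1 <- integer(0); extra2 <- integer(0)
    if (mechanism == "independent_snv") {
      free <- setdiff(seq_len(n2), carriers)
      e1 <- min(stats::rgeom(1L, spec$ac_geom_prob), length(free) %/% 2L)
      e2 <- min(stats::rgeom(1L, spec$ac_geom_prob),
                length(free) %/% 2L)
      if (e1 > 0L) extra1 <- sample(free, e1)
      if (e2 > 0L) extra2 <- sample(setdiff(free, extra1), e2)
    }
    c1 <- sort(c(carriers, extra1)); c2 <- sort(c(carriers, extra2))
    variants[[length(variants) + 1L]] <<- list(
      pos = p1, ref = substr(ref2, 1, 1), alt = substr(alt2, 1, 1),
      carriers = c1)
    variants[[length(variants) + 1L]] <<- list(
      pos = p2, ref = substr(ref2, 2, 2), alt = substr(alt2, 2, 2),
      carriers = c2)
    smp <- .hap_sample(carriers)
    events[[length(events) + 1L]] <<- list(
      mechanism = mechanism, contig = contig, pos1 = p1, pos2 = p2,
      d = d, ref1 = substr(ref2, 1, 1), alt1 = substr(alt2, 1, 1),
      ref2 = substr(ref2, 2, 2), alt2 = substr(alt2, 2, 2),
      pattern = canonical_pattern(ref2, alt2, d),
      ac1 = length(c1), ac2 = length(c2), ac_mnv = ac_mnv,
      n_hom = sum(duplicated(smp)),
      n_indiv = length(unique(smp)),
      in_repeat = in_repeat
    )
    block_site(p1, p2)
  }

  dw <- spec$distance_weights
  dists <- as.integer(names(dw))
  stopifnot(all(dists >= 1L), all(dists <= spec$max_distance))

  polzeta_orient <- list(c("GA", "TT"), c("TC", "AA"),
                         c("GC", "AA"), c("GC", "TT"))

  for (mech in mech_labels) {
    if (mech == "independent_snv") {
      d <- dists[sample.int(length(dists), 1L, prob = dw)]
      if (d == 1L) {
        i <- sample.int(nrow(nw), 1L, prob = nw$null_weight)
        oc <- orient_cache[[i]]
        o <- oc$orients[[sample.int(length(oc$orients), 1L,
                                    prob = oc$weights)]]
        mw <- if (pats$pattern[i] %in% cpg_class) {
          spec$methylation_response
        } else {
          0
        }
        p1 <- pick_site(o[1], o[2], 1L, spec$clean_contexts, mw)
        if (is.na(p1)) next
        add_event(mech, p1, 1L, o[1], o[2], FALSE)
      } else {
        # spaced pair: any free site, alternates drawn from the rate table
        p1 <- NA_integer_
        for (try in 1:400) {
          cand <- sample.int(L - d - 10L, 1L) + 5L
          if (!any(blocked[cand:(cand + d)])) { p1 <- cand; break }
        }
        if (is.na(p1)) next
        p2 <- p1 + d
        draw_alt <- function(p) {
          ctx <- paste0(chars[p - 1L], chars[p], chars[p + 1L])
          alts <- setdiff(.BASES, chars[p])
          mus <- vapply(alts, function(a) mu_rate(spec$rate_table, ctx, a),
                        numeric(1))
          alts[sample.int(3L, 1L, prob = mus)]
        }
        ref2 <- paste0(chars[p1], chars[p2])
        alt2 <- paste0(draw_alt(p1), draw_alt(p2))
        if (spec$clean_contexts &&
            .context_repetitive(chars, p1, d, ref2, alt2)) next
        add_event(mech, p1, d, ref2, alt2, FALSE)
      }
    } else if (mech == "pol_zeta") {
      o <- polzeta_orient[[sample.int(4L, 1L)]]
      p1 <- pick_site(o[1], o[2], 1L, spec$clean_contexts, 0)
      if (is.na(p1)) next
      add_event(mech, p1, 1L, o[1], o[2], FALSE)
    } else if (mech == "slippage") {
      tract_ptr <- tract_ptr + 1L
      tr <- tracts[tract_order[tract_ptr], ]
      if (nchar(tr$unit) == 2L) {
        # swap one interior unit: TA -> AT etc.
        j <- sample(2:(tr$copies - 2L), 1L)
        p1 <- tr$start + 2L * (j - 1L)
        ref2 <- tr$unit
        alt2 <- paste0(substr(tr$unit, 2, 2), substr(tr$unit, 1, 1))
      } else {
        # mono junction T...TA...A: first two bases of the unit run
        p1 <- tr$start + tr$copies
        ref2 <- strrep(tr$unit, 2L)
        alt2 <- strrep(unname(.COMP[tr$unit]), 2L)
      }
      add_event(mech, p1, 1L, ref2, alt2, TRUE)
    }
  }

  # trans pairs: two SNVs on opposite haplotypes of one sample
  n_trans <- round(spec$trans_rate * spec$n_events)
  for (k in seq_len(n_trans)) {
    p1 <- NA_integer_
    for (try in 1:400) {
      cand <- sample.int(L - 12L, 1L) + 5L
      if (!any(blocked[cand:(cand + 1L)])) { p1 <- cand; break }
    }
    if (is.na(p1)) next
    p2 <- p1 + 1L
    s <- sample.int(spec$n_samples, 1L)
    ref2 <- paste0(chars[p1], chars[p2])
    alt2 <- paste0(sample(setdiff(.BASES, chars[p1]), 1L),
                   sample(setdiff(.BASES, chars[p2]), 1L))
    variants[[length(variants) + 1L]] <- list(
      pos = p1, ref = substr(ref2, 1, 1), alt = substr(alt2, 1, 1),
      carriers = 2L * s - 1L)
    variants[[length(variants) + 1L]] <- list(
      pos = p2, ref = substr(ref2, 2, 2), alt = substr(alt2, 2, 2),
      carriers = 2L * s)
    events[[length(events) + 1L]] <- list(
      mechanism = "trans", contig = contig, pos1 = p1, pos2 = p2, d = 1L,
      ref1 = substr(ref2, 1, 1), alt1 = substr(alt2, 1, 1),
      ref2 = substr(ref2, 2, 2), alt2 = substr(alt2, 2, 2),
      pattern = canonical_pattern(ref2, alt2, 1L),
      ac1 = 1L, ac2 = 1L, ac_mnv = 0L, n_hom = 0L, n_indiv = 0L,
      in_repeat = FALSE
    )
    block_site(p1, p2)
  }

  fld <- function(nm) vapply(events, `[[`, events[[1]][[nm]], nm)
  truth <- if (length(events)) {
    tibble(
      mechanism = fld("mechanism"), contig = fld("contig"),
      pos1 = fld("pos1"), pos2 = fld("pos2"), d = fld("d"),
      ref1 = fld("ref1"), alt1 = fld("alt1"),
      ref2 = fld("ref2"), alt2 = fld("alt2"), pattern = fld("pattern"),
      ac1 = fld("ac1"), ac2 = fld("ac2"), ac_mnv = fld("ac_mnv"),
      n_hom = fld("n_hom"), n_indiv = fld("n_indiv"),
      in_repeat = fld("in_repeat")
    )
  } else {
    tibble(mechanism = character(), contig = character(),
           pos1 = integer(), pos2 = integer(), d = integer(),
           ref1 = character(), alt1 = character(), ref2 = character(),
           alt2 = character(), pattern = character(), ac1 = integer(),
           ac2 = integer(), ac_mnv = integer(), n_hom = integer(),
           n_indiv = integer(), in_repeat = logical())
  }
  truth$event_id <- seq_len(nrow(truth))

  # genotype matrices
  nv <- length(variants)
  pos <- vapply(variants, `[[`, numeric(1), "pos")
  hap1 <- matrix(0L, nv, spec$n_samples)
  hap2 <- matrix(0L, nv, spec$n_samples)
  for (i in seq_len(nv)) {
    h <- variants[[i]]$carriers
    s <- .hap_sample(h); side <- .hap_side(h)
    hap1[i, s[side == 1L]] <- 1L
    hap2[i, s[side == 2L]] <- 1L
  }
  phased <- matrix(TRUE, nv, spec$n_samples)
  het <- (hap1 + hap2) == 1L
  if (spec$noise_unphased_rate > 0) {
    flip <- het & matrix(stats::runif(nv * spec$n_samples) <
                           spec$noise_unphased_rate, nv)
    phased[flip] <- FALSE
  }
  Lps <- spec$ps_fragment_length
  ps_val <- if (is.infinite(Lps)) rep(1L, nv) else {
    as.integer((pos - 1L) %/% Lps * Lps + 1L)
  }
  ps <- matrix(rep(ps_val, spec$n_samples), nv)
  ps[!phased | !het] <- NA_integer_
  gq <- matrix(spec$gq, nv, spec$n_samples)
  dp <- matrix(spec$dp, nv, spec$n_samples)

  sites <- tibble(
    contig = contig, pos = as.integer(pos),
    ref = vapply(variants, `[[`, character(1), "ref"),
    alt = vapply(variants, `[[`, character(1), "alt")
  )
  samples <- sprintf("S%04d", seq_len(spec$n_samples))
  vcf_path <- NA_character_
  if (write_vcf) {
    vcf_path <- file.path(out_dir, "cohort.vcf")
    .write_vcf(vcf_path, ref$contigs, sites, samples, hap1, hap2, phased,
               ps, gq, dp)
  }

  # parsed-genotype view equivalent to read_phased_vcf() on the emitted
  # VCF, so downstream stages can run without file round-trips
  o <- order(pos)
  ab <- matrix(NA_real_, nv, spec$n_samples)
  ab[het] <- 0.5
  genotypes <- list(
    sites = tibble(
      contig = contig, pos = as.integer(pos[o]),
      ref = sites$ref[o], alt = sites$alt[o], type = "SNV",
      filter = "PASS",
      ac = as.integer(rowSums(hap1 == 1L) + rowSums(hap2 == 1L))[o],
      an = 2L * spec$n_samples
    ),
    samples = samples,
    phased = phased[o, , drop = FALSE],
    hap1 = hap1[o, , drop = FALSE], hap2 = hap2[o, , drop = FALSE],
    ps = ps[o, , drop = FALSE], gq = gq[o, , drop = FALSE],
    dp = dp[o, , drop = FALSE], ab = ab[o, , drop = FALSE]
  )

  meta_path <- file.path(out_dir, "cohort_metadata.txt")
  writeLines(c(
    sprintf("n_samples=%d", spec$n_samples),
    sprintf("n_events=%d", spec$n_events),
    sprintf("mechanism_mix=%s",
            paste(sprintf("%s:%g", names(spec$mechanism_mix),
                          spec$mechanism_mix), collapse = ",")),
    "allele_count_model=1+Geometric(p); free modelling choice, no",
    "  generative allele-frequency model is implied by the cohort design",
    sprintf("ac_geom_prob=%g", spec$ac_geom_prob),
    sprintf("ac_cap=%d", spec$ac_cap),
    sprintf("seed=%d", seed)
  ), meta_path)

  tr_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, tr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(vcf = vcf_path, truth = truth, samples = samples,
       genotypes = genotypes, metadata = meta_path)
}

#' Plant trio families with known transmission
#'
#' Builds `n_trios` father/mother/child families.  Parental haplotypes carry
#' planted heterozygous variant pairs in one of four configurations per
#' pair: transmission-forced cis, transmission-forced trans, both parents
#' heterozygous at both sites (trio phasing inherently uninformative), or a
#' de novo allele in the child (Mendelian violation).  Children inherit one
#' parental haplotype per parent with no recombination inside the pair
#' window, so the truth phase of every child het pair is exact and
#' recorded.
#'
#' @param ref `ReferenceBundle`.
#' @param n_trios number of families (>= 1).
#' @param seed RNG seed.
#' @param pairs_per_trio planted het variant pairs per family.
#' @param config_weights named weights over
#'   `cis` / `trans` / `uninformative` / `denovo`.
#' @param max_distance largest pair distance in bp (trio analyses use a
#'   wider window than cohort scanning).
#' @param ps_fragment_length phase-set block length for the read-based
#'   phase written to the VCF (`Inf` = one set per contig).
#' @param out_dir output directory.
#' @return list with `vcf`, `ped` (paths), `truth` (tibble: per pair the
#'   configuration, truth phase of the child pair, and the expected
#'   trio-phasing outcome), `samples`.
#' @export
plant_trios <- function(ref, n_trios, seed = 1L, pairs_per_trio = 6L,
                        config_weights = c(cis = 0.4, trans = 0.3,
                                           uninformative = 0.25,
                                           denovo = 0.05),
                        max_distance = 100L, ps_fragment_length = Inf,
                        out_dir = NULL) {
  stopifnot(inherits(ref, "ReferenceBundle"), n_trios >= 1L)
  set.seed(seed)
  if (is.null(out_dir)) out_dir <- file.path(tempfile("trios"), "")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  contig <- names(ref$contigs)[1]
  chars <- strsplit(ref$contigs[[contig]], "")[[1]]
  L <- length(chars)

  n_pairs <- n_trios * pairs_per_trio
  span <- max_distance + 20L
  if (n_pairs * span + 40L > L) {
    stop("capacity error: contig too short for ", n_pairs, " trio pairs")
  }
  starts <- 20L + span * (seq_len(n_pairs) - 1L)

  samples <- as.vector(vapply(seq_len(n_trios), function(i) {
    c(sprintf("F%03d", i), sprintf("M%03d", i), sprintf("C%03d", i))
  }, character(3)))
  n_ind <- length(samples)

  variants <- list()
  truth <- list()
  configs <- names(config_weights)

  add_var <- function(pos, alt, carriers) {
    variants[[length(variants) + 1L]] <<- list(
      pos = pos, ref = chars[pos], alt = alt, carriers = carriers)
  }

  pair_id <- 0L
  for (t in seq_len(n_trios)) {
    fa <- 3L * (t - 1L) + 1L; mo <- fa + 1L; ch <- fa + 2L
    # haplotype column indices (2*ind-1, 2*ind); child inherits the first
    # haplotype of each parent, so transmitted = hap1(father), hap1(mother)
    hF1 <- 2L * fa - 1L; hF2 <- 2L * fa
    hM1 <- 2L * mo - 1L; hM2 <- 2L * mo
    hC1 <- 2L * ch - 1L; hC2 <- 2L * ch   # paternal, maternal

    for (k in seq_len(pairs_per_trio)) {
      pair_id <- pair_id + 1L
      cfg <- sample(configs, 1L, prob = config_weights)
      d <- sample.int(max_distance, 1L)
      pA <- starts[pair_id]; pB <- pA + d
      altA <- sample(setdiff(.BASES, chars[pA]), 1L)
      altB <- sample(setdiff(.BASES, chars[pB]), 1L)

      if (cfg == "cis") {
        # mother hap1 carries both; father ref: forced maternal at both
        add_var(pA, altA, c(hM1, hC2))
        add_var(pB, altB, c(hM1, hC2))
        tp <- "cis"; exp_pbt <- "cis"
      } else if (cfg == "trans") {
        add_var(pA, altA, c(hF1, hC1))
        add_var(pB, altB, c(hM1, hC2))
        tp <- "trans"; exp_pbt <- "trans"
      } else if (cfg == "uninformative") {
        # both parents het at both sites; child receives father's cis pair
        add_var(pA, altA, c(hF1, hM1, hC1))
        add_var(pB, altB, c(hF1, hM1, hC1))
        tp <- "cis"; exp_pbt <- "uninformative"
      } else {
        # de novo at A on the paternal haplotype; B inherited maternally
        add_var(pA, altA, hC1)
        add_var(pB, altB, c(hM1, hC2))
        tp <- "trans"; exp_pbt <- "violation"
      }
      truth[[pair_id]] <- tibble(
        fam = sprintf("fam%03d", t), child = samples[3L * t],
        father = samples[3L * t - 2L], mother = samples[3L * t - 1L],
        contig = contig, pos1 = pA, pos2 = pB, d = d,
        ref1 = chars[pA], alt1 = altA, ref2 = chars[pB], alt2 = altB,
        config = cfg, truth_phase = tp, expected_pbt = exp_pbt
      )
    }
  }
  truth <- bind_rows(truth)

  nv <- length(variants)
  pos <- vapply(variants, `[[`, numeric(1), "pos")
  hap1 <- matrix(0L, nv, n_ind); hap2 <- matrix(0L, nv, n_ind)
  for (i in seq_len(nv)) {
    h <- variants[[i]]$carriers
    s <- .hap_sample(h); side <- .hap_side(h)
    hap1[i, s[side == 1L]] <- 1L
    hap2[i, s[side == 2L]] <- 1L
  }
  phased <- matrix(TRUE, nv, n_ind)
  het <- (hap1 + hap2) == 1L
  Lps <- ps_fragment_length
  ps_val <- if (is.infinite(Lps)) rep(1L, nv) else {
    as.integer((pos - 1L) %/% Lps * Lps + 1L)
  }
  ps <- matrix(rep(ps_val, n_ind), nv)
  ps[!het] <- NA_integer_
  gq <- matrix(99L, nv, n_ind); dp <- matrix(30L, nv, n_ind)

  sites <- tibble(
    contig = contig, pos = as.integer(pos),
    ref = vapply(variants, `[[`, character(1), "ref"),
    alt = vapply(variants, `[[`, character(1), "alt")
  )
  vcf_path <- file.path(out_dir, "trios.vcf")
  .write_vcf(vcf_path, ref$contigs, sites, samples, hap1, hap2, phased,
             ps, gq, dp)

  ped <- bind_rows(lapply(seq_len(n_trios), function(t) {
    f <- samples[3L * t - 2L]; m <- samples[3L * t - 1L]
    c_ <- samples[3L * t]
    tibble(fid = sprintf("fam%03d", t), iid = c(f, m, c_),
           pat = c("0", "0", f), mat = c("0", "0", m),
           sex = c(1L, 2L, 0L), phenotype = 0L)
  }))
  ped_path <- file.path(out_dir, "trios.ped")
  write_ped(ped, ped_path)

  list(vcf = vcf_path, ped = ped_path, truth = truth, samples = samples)
}
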