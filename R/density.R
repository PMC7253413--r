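#' Count reference dinucleotides of a canonical pattern class in intervals
#'
#' Counts positions `i` inside the interval set with
#' `ref[i] == W, ref[i + d] == X` for the pattern's reference pair and -
#' because patterns are collapsed over strands - also for its reverse
#' complement (self-complementary pairs are counted once).
#'
#' @param ref reference bundle or named contig sequences.
#' @param intervals tibble (`contig`, `start`, `end`, 1-based inclusive);
#'   `NULL` counts the whole genome.
#' @param wx reference pair of the canonical pattern (e.g. `"CA"`).
#' @param d distance (1 = adjacent).
#' @return integer count.
#' @export
count_ref_dinucs <- function(ref, intervals, wx, d = 1L) {
  contigs <- if (inherits(ref, "ReferenceBundle")) ref$contigs else ref
  pairs <- unique(c(wx, revcomp(wx)))
  total <- 0L
  for (ct in names(contigs)) {
    chars <- strsplit(contigs[[ct]], "")[[1]]
    L <- length(chars)
    iv <- if (is.null(intervals)) {
      tibble(contig = ct, start = 1L, end = L)
    } else {
      intervals[intervals$contig == ct, , drop = FALSE]
    }
    for (r in seq_len(nrow(iv))) {
      lo <- max(1L, iv$start[r]); hi <- min(L, iv$end[r])
      if (hi - lo < d) next
      # first base of the pair must lie inside the interval and the pair
      # inside the contig
      i <- lo:min(hi, L - d)
      for (p in pairs) {
        total <- total +
          sum(chars[i] == substr(p, 1, 1) &
                chars[i + d] == substr(p, 2, 2))
      }
    }
  }
  total
}

.count_mnvs_in <- function(records, intervals) {
  if (is.null(intervals)) return(nrow(records))
  if (!nrow(records)) return(0L)
  gr_rec <- GenomicRanges::GRanges(
    records$contig, IRanges::IRanges(records$pos1, records$pos1))
  gr_iv <- .intervals_to_granges(intervals)
  sum(IRanges::overlapsAny(gr_rec, gr_iv))
}

#' MNV density per substitution pattern and annotation category
#'
#' The density of pattern WX>YZ in interval set I is
#' `D = N(WX>YZ | I) / N(WX | I)`: observed MNVs per reference
#' dinucleotide opportunity.  `d_norm` divides by the genome-wide density,
#' so `d_norm = k` means the per-opportunity MNV probability in the
#' category is k times the genome average, and the whole genome has
#' `d_norm = 1` by construction.  Overlapping categories are scored
#' independently; a record may contribute to several.
#'
#' @param records adjacent MNV tibble (canonical `pattern` column).
#' @param annotations tibble (`contig`, `start`, `end`, `category`,
#'   optional `methylation`).
#' @param ref reference bundle or named contig sequences.
#' @param patterns canonical patterns to score (default: all with >= 1
#'   observed record).
#' @return tibble: `pattern`, `category`, `n_mnv`, `n_dinuc`, `density`,
#'   `d_norm` (plus `methylation` carried per category when present).
#'   Categories with zero dinucleotide opportunity are flagged with
#'   `NA` density.
#' @export
mnv_density <- function(records, annotations, ref, patterns = NULL) {
  recs <- filter(records, .data$d == 1L, !is.na(.data$pattern))
  if (is.null(patterns)) patterns <- sort(unique(recs$pattern))
  cats <- unique(annotations$category)
  meth_by_cat <- NULL
  if ("methylation" %in% names(annotations)) {
    meth_by_cat <- annotations %>%
      group_by(.data$category) %>%
      summarise(methylation = mean(.data$methylation), .groups = "drop")
  }
  out <- list()
  for (p in patterns) {
    wx <- pattern_components(p)$ref
    prec <- recs[recs$pattern == p, ]
    n_g <- nrow(prec)
    nd_g <- count_ref_dinucs(ref, NULL, wx, 1L)
    d_g <- if (nd_g > 0L) n_g / nd_g else NA_real_
    rows <- lapply(cats, function(cat) {
      iv <- annotations[annotations$category == cat, , drop = FALSE]
      n <- .count_mnvs_in(prec, iv)
      nd <- count_ref_dinucs(ref, iv, wx, 1L)
      dens <- if (nd > 0L) n / nd else NA_real_
      tibble(pattern = p, category = cat, n_mnv = n, n_dinuc = nd,
             density = dens,
             d_norm = if (!is.na(dens) && !is.na(d_g) && d_g > 0) {
               dens / d_g
             } else {
               NA_real_
             })
    })
    out[[length(out) + 1L]] <- bind_rows(rows) %>%
      bind_rows(tibble(pattern = p, category = "whole_genome",
                       n_mnv = n_g, n_dinuc = nd_g, density = d_g,
                       d_norm = ifelse(is.na(d_g), NA_real_, 1)))
  }
  res <- bind_rows(out)
  if (!is.null(meth_by_cat)) {
    res <- left_join(res, meth_by_cat, by = "category")
  }
  res
}

#' Correlation of normalized MNV density with methylation level
#'
#' Pearson correlation, per pattern, of `d_norm` against the per-category
#' methylation level across annotation categories (the whole-genome row is
#' excluded).  Requires at least three categories with methylation levels;
#' constant vectors yield an `NA` correlation with a flag.
#'
#' @param density tibble from [mnv_density()] with a `methylation` column.
#' @return tibble: `pattern`, `n_categories`, `r`, `p_value`, `degenerate`.
#' @export
correlate_density_methylation <- function(density) {
  dd <- filter(density, .data$category != "whole_genome",
               !is.na(.data$methylation), !is.na(.data$d_norm))
  if (!nrow(dd)) stop("no categories with methylation levels")
  out <- lapply(split(dd, dd$pattern), function(g) {
    degen <- nrow(g) < 3L || stats::sd(g$d_norm) == 0 ||
      stats::sd(g$methylation) == 0
    tibble(
      pattern = g$pattern[1], n_categories = nrow(g), degenerate = degen,
      r = if (degen) NA_real_ else stats::cor(g$d_norm, g$methylation),
      p_value = if (degen) NA_real_ else
        stats::cor.test(g$d_norm, g$methylation)$p.value
    )
  })
  bind_rows(out)
}

#' Origin-class fractions of MNVs per annotation category
#'
#' Partitions the adjacent MNVs falling in each category over the five
#' pattern classes of [pattern_origin_classes()] (CpG-transition,
#' pol-zeta, repeat, transversion, others); fractions sum to one per
#' category.
#'
#' @param records adjacent MNV tibble.
#' @param annotations annotation tibble; `NULL` scores the whole set as
#'   one category.
#' @return tibble: `category`, `n_total`, and one fraction column per
#'   origin class.  Empty categories are flagged with `NA` fractions.
#' @export
origin_fractions_by_region <- function(records, annotations = NULL) {
  recs <- filter(records, .data$d == 1L, !is.na(.data$pattern))
  classes <- pattern_origin_classes()
  class_of <- function(p) {
    for (nm in names(classes)) if (p %in% classes[[nm]]) return(nm)
    "others"
  }
  recs$class <- vapply(recs$pattern, class_of, character(1))
  cats <- if (is.null(annotations)) "all" else
    unique(annotations$category)
  rows <- lapply(cats, function(cat) {
    sel <- if (is.null(annotations)) recs else {
      iv <- annotations[annotations$category == cat, , drop = FALSE]
      if (nrow(recs)) {
        gr_rec <- GenomicRanges::GRanges(
          recs$contig, IRanges::IRanges(recs$pos1, recs$pos1))
        recs[IRanges::overlapsAny(gr_rec, .intervals_to_granges(iv)), ]
      } else {
        recs
      }
    }
    n <- nrow(sel)
    fr <- vapply(names(classes), function(nm) {
      if (n == 0L) NA_real_ else sum(sel$class == nm) / n
    }, numeric(1))
    out <- tibble(category = cat, n_total = n)
    for (nm in names(classes)) out[[paste0("frac_", nm)]] <- fr[[nm]]
    out
  })
  bind_rows(rows)
}
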