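#' One-step MNV classification
#'
#' An MNV is one-step when the cohort allele counts of its two constituent
#' SNVs are equal - the signature of both substitutions arising in a
#' single generation (assuming no recurrent mutation).  Strict mode
#' additionally requires `ac_mnv / ac1 >= 0.9`, guarding against pairs
#' whose allele counts match only by chance.
#'
#' @param ac1,ac2,ac_mnv integer vectors of constituent and MNV allele
#'   counts.
#' @param strict apply the `ac_mnv/ac1 >= 0.9` requirement.
#' @return logical vector.
#' @export
is_one_step <- function(ac1, ac2, ac_mnv, strict = FALSE) {
  if (any(ac1 <= 0L | ac2 <= 0L)) {
    stop("constituent allele counts must be positive")
  }
  base <- ac1 == ac2
  if (!strict) return(base)
  base & (ac_mnv / ac1 >= 0.9)
}

#' Count (possibly gapped) repeat units in a context string
#'
#' The repeat unit of an MNV is its reference or alternate allele pair
#' itself; for distance d the two bases of the unit are d apart, so
#' occurrences are positions `i` with `context[i] == unit[1]` and
#' `context[i + d] == unit[2]`, counting overlaps.
#'
#' @param context character scalar (the +/-4 bp window around the MNV, or
#'   any string).
#' @param unit 2-character unit.
#' @param d gap-inclusive distance between the unit's two bases
#'   (1 = adjacent).
#' @return integer count.
#' @examples
#' repeat_unit_count("TATATAT", "TT", 2)  # 3 (TATATAT -> TAAAAAT example)
#' @export
repeat_unit_count <- function(context, unit, d = 1L) {
  stopifnot(nchar(unit) == 2L, d >= 1L)
  ch <- strsplit(toupper(context), "")[[1]]
  n <- length(ch)
  if (n <= d) return(0L)
  b1 <- substr(unit, 1, 1); b2 <- substr(unit, 2, 2)
  sum(ch[seq_len(n - d)] == b1 & ch[seq_len(n - d) + d] == b2)
}

.is_mono_pair <- function(pair) {
  substr(pair, 1, 1) == substr(pair, 2, 2)
}

# core repetitive-context rule on a character vector; pos1 = first MNV base
.context_repetitive <- function(chars, pos1, d, ref2, alt2) {
  L <- length(chars)
  lo <- pos1 - 4L; hi <- pos1 + d + 4L
  # off-contig windows are truncated (padded-skip)
  win <- chars[max(1L, lo):min(L, hi)]
  ref_ctx <- paste(win, collapse = "")
  alt_win <- win
  off <- pos1 - max(1L, lo) + 1L
  alt_win[off] <- substr(alt2, 1, 1)
  alt_win[off + d] <- substr(alt2, 2, 2)
  alt_ctx <- paste(alt_win, collapse = "")

  n_ref <- repeat_unit_count(ref_ctx, ref2, d)
  n_alt <- repeat_unit_count(alt_ctx, alt2, d)

  # adjacent MNVs with mononucleotide-run alleles: raise that side's
  # thresholds by one unit (overlap-counting correction)
  bump_ref <- as.integer(d == 1L && .is_mono_pair(ref2))
  bump_alt <- as.integer(d == 1L && .is_mono_pair(alt2))
  (n_ref > 1L + bump_ref && n_alt > 1L + bump_alt) &&
    (n_ref > 2L + bump_ref || n_alt > 2L + bump_alt)
}

#' Repetitive-context classification of an MNV
#'
#' An MNV sits in a repetitive (slippage-prone) context when the repeat
#' unit counts of its +/-4 bp window satisfy: ref count > 1 AND alt
#' count > 1, AND (ref count > 2 OR alt count > 2), where the unit is the
#' reference (resp. alternate) allele pair.  For adjacent MNVs whose
#' reference and/or alternate pair is a mononucleotide run (e.g. `AA`),
#' the thresholds on that side are raised by one unit.
#'
#' @param rec one-row MNV tibble (needs `contig`, `pos1`, `d`, and the
#'   allele columns), or vectors via the `...` interface of
#'   [classify_repeat_context()].
#' @param ref reference bundle or named contig sequences.
#' @return logical scalar.
#' @export
in_repeat_context <- function(rec, ref) {
  seqs <- .contig_seq(ref, rec$contig)
  chars <- strsplit(substr(seqs, max(1L, rec$pos1 - 4L),
                           min(nchar(seqs), rec$pos1 + rec$d + 4L)),
                    "")[[1]]
  off <- rec$pos1 - max(1L, rec$pos1 - 4L) + 1L
  .context_repetitive(chars, off, rec$d,
                      paste0(rec$ref1, rec$ref2),
                      paste0(rec$alt1, rec$alt2))
}

#' @rdname in_repeat_context
#' @param records MNV tibble; returns the per-record logical vector.
#' @export
classify_repeat_context <- function(records, ref) {
  vapply(seq_len(nrow(records)), function(i) {
    in_repeat_context(records[i, ], ref)
  }, logical(1))
}

#' Predicted dominant mechanism per substitution pattern
#'
#' Ordered assignment: (1) pol-zeta for the polymerase signature patterns
#' GA>TT and GC>AA; (2) repeat when the pattern's fraction of MNVs in
#' repetitive contexts exceeds 10%; (3) otherwise one of `Ti at CpG`,
#' `Ti`, `Ti at CpG + Tv`, `Ti + Tv`, `Tv combination`, from the possible
#' single-step compositions of the pattern's two mutational paths (a CpG
#' transition is a C>T with a 3' G or G>A with a 5' C arising within the
#' dinucleotide during either path).
#'
#' @param pattern canonical pattern string(s) `"WX>YZ"`.
#' @param repeat_fraction per-pattern fraction of MNVs in repetitive
#'   contexts (same length as `pattern`).
#' @return character vector of mechanism labels.
#' @export
predicted_mechanism <- function(pattern, repeat_fraction = 0) {
  repeat_fraction <- rep_len(repeat_fraction, length(pattern))
  vapply(seq_along(pattern), function(i) {
    p <- pattern[i]
    if (p %in% c("GA>TT", "GC>AA")) return("pol_zeta")
    if (!is.na(repeat_fraction[i]) && repeat_fraction[i] > 0.10) {
      return("repeat")
    }
    .snv_composition_label(p)
  }, character(1))
}

# step classification helpers for path composition
.step_class <- function(from2, to2, position) {
  # substitution at `position` of the dinucleotide from2 -> to2
  ref_b <- substr(from2, position, position)
  alt_b <- substr(to2, position, position)
  transition <- paste0(ref_b, alt_b) %in% c("AG", "GA", "CT", "TC")
  if (!transition) return("Tv")
  cpg <- (position == 1L && ref_b == "C" && alt_b == "T" &&
            substr(from2, 2, 2) == "G") ||
    (position == 2L && ref_b == "G" && alt_b == "A" &&
       substr(from2, 1, 1) == "C")
  if (cpg) "TiCpG" else "Ti"
}

.snv_composition_label <- function(pattern) {
  pc <- pattern_components(pattern)
  W <- substr(pc$ref, 1, 1); X <- substr(pc$ref, 2, 2)
  Y <- substr(pc$alt, 1, 1); Z <- substr(pc$alt, 2, 2)
  mid1 <- paste0(Y, X)   # position 1 first
  mid2 <- paste0(W, Z)   # position 2 first
  paths <- list(
    c(.step_class(pc$ref, mid1, 1L), .step_class(mid1, pc$alt, 2L)),
    c(.step_class(pc$ref, mid2, 2L), .step_class(mid2, pc$alt, 1L))
  )
  has <- function(a, b) {
    any(vapply(paths, function(p) setequal(p, c(a, b)) ||
                 all(sort(p) == sort(c(a, b))), logical(1)))
  }
  if (has("TiCpG", "Ti") || has("TiCpG", "TiCpG")) return("Ti at CpG")
  if (has("Ti", "Ti")) return("Ti")
  if (has("TiCpG", "Tv")) return("Ti at CpG + Tv")
  if (has("Ti", "Tv")) return("Ti + Tv")
  "Tv combination"
}

#' Per-pattern statistics of an adjacent MNV set
#'
#' Aggregates a scanned MNV table (adjacent records only) into the
#' per-pattern quantities the mechanism analyses consume: observed counts,
#' one-step counts, repetitive-context counts, and the independent-SNV
#' null weight.
#'
#' @param records MNV tibble from [scan_mnvs()].
#' @param ref reference bundle.
#' @param rates SNV rate table.
#' @return tibble with one row per canonical pattern: `pattern`, `n_obs`,
#'   `n_one_step`, `n_repeat`, `p_null`, `n_dinuc`, `null_weight`.
#' @export
pattern_stats <- function(records, ref, rates = default_rate_table()) {
  adj <- filter(records, .data$d == 1L, !is.na(.data$pattern))
  if (nrow(adj)) {
    adj$one_step <- is_one_step(adj$ac1, adj$ac2, adj$ac_mnv)
    adj$in_rep <- classify_repeat_context(adj, ref)
  }
  agg <- if (nrow(adj)) {
    adj %>%
      group_by(.data$pattern) %>%
      summarise(n_obs = n(), n_one_step = sum(.data$one_step),
                n_repeat = sum(.data$in_rep), .groups = "drop")
  } else {
    tibble(pattern = character(), n_obs = integer(),
           n_one_step = integer(), n_repeat = integer())
  }
  null_pattern_weights(rates, ref) %>%
    left_join(agg, by = "pattern") %>%
    mutate(
      n_obs = ifelse(is.na(.data$n_obs), 0L, .data$n_obs),
      n_one_step = ifelse(is.na(.data$n_one_step), 0L, .data$n_one_step),
      n_repeat = ifelse(is.na(.data$n_repeat), 0L, .data$n_repeat)
    )
}

#' Estimate the non-SNV excess fraction q per pattern
#'
#' Under the independent-SNV null, the expected number of
#' non-repetitive-context MNVs of pattern p is `E_p = C x null_weight(p) x
#' n_individuals`, with one global scale C.  C is fitted by least squares
#' in log space over a calibration set of patterns with no known doublet
#' mechanism (everything except the pol-zeta signature and the
#' repeat-dominated patterns).  The excess fraction is
#' `q(p) = max(0, 1 - E_p / N_nonrepeat(p))`: the fraction of
#' non-repeat MNVs of that pattern not explained by two independent SNV
#' events.  Origin fractions per pattern partition observed MNVs into
#' `repeat` (`n_repeat / n_obs`), `snv_combination`
#' (`(1 - repeat) x (1 - q)`) and `other` (the remainder, dominated by
#' pol-zeta error for its signature patterns); the three sum to one.
#'
#' @param stats per-pattern tibble from [pattern_stats()].
#' @param n_individuals cohort size (scale only; absorbed by C but kept
#'   explicit so spectra from different cohort sizes are comparable).
#' @param calibration_exclude patterns excluded from the C fit (default:
#'   pol-zeta signature + repeat-class patterns).
#' @return `stats` with columns `expected_null`, `q_hat`,
#'   `frac_snv_combination`, `frac_repeat`, `frac_other`,
#'   `predicted_mechanism` added.
#' @export
estimate_q <- function(stats, n_individuals,
                       calibration_exclude = c(
                         pattern_origin_classes()$pol_zeta,
                         pattern_origin_classes()$repeat_class)) {
  if (all(stats$n_obs == 0L)) {
    stop("empty spectrum: cannot estimate the excess factor")
  }
  n_nonrep <- stats$n_obs - stats$n_repeat
  base <- stats$null_weight * n_individuals
  calib <- !(stats$pattern %in% calibration_exclude) & n_nonrep > 0L
  if (!any(calib)) stop("calibration pattern set is empty")
  logC <- mean(log(n_nonrep[calib]) - log(base[calib]))
  expected <- exp(logC) * base
  q_hat <- ifelse(n_nonrep > 0L, pmax(0, 1 - expected / n_nonrep),
                  NA_real_)
  frac_repeat <- ifelse(stats$n_obs > 0L, stats$n_repeat / stats$n_obs,
                        NA_real_)
  frac_snv <- (1 - frac_repeat) * (1 - q_hat)
  stats %>%
    mutate(
      expected_null = expected, q_hat = q_hat,
      frac_repeat = frac_repeat,
      frac_snv_combination = frac_snv,
      frac_other = 1 - frac_repeat - frac_snv,
      predicted_mechanism = predicted_mechanism(.data$pattern,
                                                frac_repeat)
    )
}

#' Global and per-pattern MNV mutation rates
#'
#' The global adjacent-MNV rate follows the Watterson-style site-count
#' argument: assuming no recurrent mutation, the one-step MNV site count
#' relative to the SNV site count scales the per-generation SNV rate,
#' `mu_MNV = (n_mnv_sites / n_snv_sites) x mu_SNV` (per 2 bp per
#' generation).  Each pattern's rate then redistributes the global rate by
#' its share of one-step MNV sites, normalised by the pattern's reference
#' dinucleotide availability:
#' `r_p = mu_MNV x share_p x (sum_W N_W / N_p) x coverage_factor`, so that
#' `sum_p r_p x N_p` conserves the coverage-scaled global expectation.
#' Expected events per generation per pattern are `r_p x N_p`.
#'
#' @param n_mnv_sites number of one-step adjacent MNV sites.
#' @param n_snv_sites number of SNV sites in the same callset.
#' @param spectrum tibble `pattern` / `n` of one-step adjacent MNV sites
#'   per pattern (e.g. [pattern_spectrum()] of the one-step subset).
#' @param dinuc_counts named numeric: reference dinucleotide count per
#'   canonical pattern (both strands), e.g. the `n_dinuc` column of
#'   [pattern_stats()].
#' @param mu_snv global SNV mutation rate per bp per generation
#'   (default 1.2e-8).
#' @param coverage_factor scalar (or per-pattern vector) coverage
#'   correction; default 1.
#' @return list with `mu_mnv_global` and a tibble `per_pattern`
#'   (`pattern`, `share`, `rate`, `n_dinuc`, `expected_per_generation`).
#' @export
estimate_rates <- function(n_mnv_sites, n_snv_sites, spectrum,
                           dinuc_counts, mu_snv = 1.2e-8,
                           coverage_factor = 1) {
  if (n_snv_sites <= 0L) stop("n_snv_sites must be positive")
  mu_global <- (n_mnv_sites / n_snv_sites) * mu_snv
  share <- if (sum(spectrum$n) > 0) spectrum$n / sum(spectrum$n) else
    rep(0, nrow(spectrum))
  nd <- dinuc_counts[spectrum$pattern]
  total_dinuc <- sum(dinuc_counts)
  rate <- mu_global * share * (total_dinuc / nd) * coverage_factor
  list(
    mu_snv = mu_snv, mu_mnv_global = mu_global,
    n_mnv_sites = n_mnv_sites, n_snv_sites = n_snv_sites,
    per_pattern = tibble(
      pattern = spectrum$pattern, share = share,
      n_dinuc = unname(nd), rate = unname(rate),
      expected_per_generation = unname(rate * nd)
    )
  )
}

#' Expected doublet mutations per generation
#'
#' Convenience product `rate x n_dinuc`: a per-2bp per-generation pattern
#' rate times the genome-wide count of its reference dinucleotide gives
#' the expected number of new MNVs of that pattern per generation.
#'
#' @param rate per-2bp per-generation mutation rate.
#' @param n_dinuc reference dinucleotide count.
#' @return numeric.
#' @export
expected_events_per_generation <- function(rate, n_dinuc) {
  stopifnot(rate >= 0, n_dinuc >= 0)
  rate * n_dinuc
}
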