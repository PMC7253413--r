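#' Build a trinucleotide-context SNV mutation-rate table
#'
#' Per-generation, per-site single-nucleotide mutation rates keyed by the
#' 3-mer context (5' base, reference base, 3' base) and the alternate base:
#' 64 contexts x 3 alternates = 192 rows.  The default table is synthetic but
#' reproduces the well-established rate hierarchy of the human germline:
#' transitions exceed transversions several-fold and C>T transitions at CpG
#' dinucleotides (spontaneous deamination of methylated cytosine) exceed
#' other transitions by roughly an order of magnitude.
#'
#' @param mu_tv per-alternate transversion rate (default 2.5e-9 /bp/gen).
#' @param mu_ti non-CpG transition rate (default 1.0e-8 /bp/gen).
#' @param mu_cpg_ti CpG transition rate: C>T with a 3' G, or equivalently G>A
#'   with a 5' C (default 1.2e-7 /bp/gen).
#' @return tibble with columns `context`, `ref`, `alt`, `mu`.
#' @export
default_rate_table <- function(mu_tv = 2.5e-9, mu_ti = 1.0e-8,
                               mu_cpg_ti = 1.2e-7) {
  stopifnot(mu_tv > 0, mu_ti > 0, mu_cpg_ti > 0)
  grid <- expand.grid(
    l = .BASES, ref = .BASES, r = .BASES, alt = .BASES,
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$ref != grid$alt, ]
  transition <- paste0(grid$ref, grid$alt) %in% c("AG", "GA", "CT", "TC")
  cpg <- (grid$ref == "C" & grid$alt == "T" & grid$r == "G") |
    (grid$ref == "G" & grid$alt == "A" & grid$l == "C")
  mu <- ifelse(!transition, mu_tv, ifelse(cpg, mu_cpg_ti, mu_ti))
  tibble(
    context = paste0(grid$l, grid$ref, grid$r),
    ref = grid$ref, alt = grid$alt, mu = mu
  ) %>% arrange(.data$context, .data$alt)
}

.rate_lookup <- function(rates) {
  stats::setNames(rates$mu, paste0(rates$context, ">", rates$alt))
}

#' Look up context-dependent SNV rates
#'
#' @param rates rate table from [default_rate_table()] or
#'   [read_rate_table()].
#' @param context character vector of 3-mers (5' base, ref, 3' base).
#' @param alt alternate base.
#' @return numeric vector of rates; errors if any context/alt pair is absent.
#' @export
mu_rate <- function(rates, context, alt) {
  lut <- .rate_lookup(rates)
  key <- paste0(toupper(context), ">", toupper(alt))
  out <- lut[key]
  if (anyNA(out)) {
    stop("rate table is missing context(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Null path probability of an adjacent MNV pattern under independent SNVs
#'
#' If an adjacent MNV WX->YZ arises as two independent single-nucleotide
#' events, it must pass through one of two intermediate states: first
#' position first (WX -> YX -> YZ) or second position first
#' (WX -> WZ -> YZ).  The probability is the sum over the two orders of the
#' product of the two context-dependent SNV rates, where the second step's
#' context contains the product of the first step.  Flanking bases outside
#' the dinucleotide enter the 3-mer contexts; they are either supplied
#' exactly or marginalised over a flank-base distribution.
#'
#' @param ref2,alt2 length-2 strings: the reference and alternate pairs.
#' @param rates SNV rate table.
#' @param flanks optional character vector `c(left, right)` of the bases
#'   immediately 5' of position 1 and 3' of position 2.
#' @param flank_freqs optional named numeric of base frequencies (A/C/G/T)
#'   used to marginalise unknown flanks; default uniform.
#' @return list with `p_null` (numeric) and `paths` (tibble decomposing the
#'   two orders; exact mode only carries the supplied flanks).
#' @export
null_path_probability <- function(ref2, alt2, rates, flanks = NULL,
                                  flank_freqs = NULL) {
  ref2 <- toupper(ref2); alt2 <- toupper(alt2)
  stopifnot(nchar(ref2) == 2L, nchar(alt2) == 2L)
  W <- substr(ref2, 1, 1); X <- substr(ref2, 2, 2)
  Y <- substr(alt2, 1, 1); Z <- substr(alt2, 2, 2)
  if (W == Y || X == Z) stop("both positions of the pattern must change")

  lut <- .rate_lookup(rates)
  mu1 <- function(context, alt) {
    out <- lut[paste0(context, ">", alt)]
    if (anyNA(out)) {
      stop("rate table is missing context ", context, ">", alt)
    }
    unname(out)
  }
  path_p <- function(L, R) {
    # order 1: position 1 first, the intermediate state is YX
    p1 <- mu1(paste0(L, W, X), Y) * mu1(paste0(Y, X, R), Z)
    # order 2: position 2 first, the intermediate state is WZ
    p2 <- mu1(paste0(W, X, R), Z) * mu1(paste0(L, W, Z), Y)
    c(p1, p2)
  }

  if (!is.null(flanks)) {
    stopifnot(length(flanks) == 2L)
    pp <- path_p(toupper(flanks[1]), toupper(flanks[2]))
  } else {
    if (is.null(flank_freqs)) {
      flank_freqs <- stats::setNames(rep(0.25, 4), .BASES)
    }
    flank_freqs <- flank_freqs[.BASES] / sum(flank_freqs[.BASES])
    pp <- c(0, 0)
    for (L in .BASES) {
      for (R in .BASES) {
        pp <- pp + flank_freqs[[L]] * flank_freqs[[R]] * path_p(L, R)
      }
    }
  }
  paths <- tibble(
    order = c("pos1_first", "pos2_first"),
    intermediate = c(paste0(Y, X), paste0(W, Z)),
    p = pp
  )
  list(p_null = sum(pp), paths = paths)
}

#' Null-model weight of every canonical adjacent pattern
#'
#' For each canonical pattern, sums `p_null` x (ordered reference dinucleotide
#' count) over the pattern's one or two strand orientations.  The result is
#' proportional to the expected number of MNV sites under the
#' independent-SNV null and is the per-pattern weight used by
#' [estimate_q()].
#'
#' @param rates SNV rate table.
#' @param ref a reference bundle (see [generate_reference()]) or named
#'   character vector of contig sequences, used for ordered dinucleotide
#'   counts and flank-base frequencies.
#' @return tibble with columns `pattern`, `p_null` (orientation-summed path
#'   probability), `n_dinuc` (orientation-summed ordered dinucleotide count)
#'   and `null_weight` (the orientation-sum of p_null x count).
#' @export
null_pattern_weights <- function(rates, ref) {
  contigs <- if (inherits(ref, "ReferenceBundle")) ref$contigs else ref
  seqs <- Biostrings::DNAStringSet(unlist(contigs))
  base_freq <- colSums(Biostrings::letterFrequency(seqs, .BASES))
  base_freq <- base_freq / sum(base_freq)
  dinuc <- colSums(Biostrings::dinucleotideFrequency(seqs))

  pats <- all_canonical_patterns()
  rows <- lapply(seq_len(nrow(pats)), function(i) {
    ref2 <- pats$ref[i]; alt2 <- pats$alt[i]
    orients <- unique(list(
      c(ref2, alt2),
      c(revcomp(ref2), revcomp(alt2))
    ))
    w <- 0; ptot <- 0; ntot <- 0
    for (o in orients) {
      p <- null_path_probability(o[1], o[2], rates,
                                 flank_freqs = base_freq)$p_null
      n <- unname(dinuc[o[1]])
      w <- w + p * n
      ptot <- ptot + p
      ntot <- ntot + n
    }
    tibble(pattern = pats$pattern[i], p_null = ptot, n_dinuc = ntot,
           null_weight = w)
  })
  bind_rows(rows)
}

#' Read / write a rate table TSV
#'
#' Plain TSV with columns `context`, `ref`, `alt`, `mu` (and optionally a
#' methylation stratum column, preserved verbatim).
#'
#' @param path file path.
#' @return [read_rate_table()] returns the rate tibble.
#' @export
read_rate_table <- function(path) {
  out <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("context", "ref", "alt", "mu")
  if (!all(need %in% names(out))) {
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(out$mu <= 0)) stop("all rates must be positive")
  out
}

#' @rdname read_rate_table
#' @param rates rate tibble to write.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
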