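#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows count n
#' @importFrom rlang .data
NULL

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of short DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] for plain
#' character input.
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fast path for the 2-mers used throughout pattern algebra
.rc2 <- function(x) {
  paste0(unname(.COMP[substr(x, 2, 2)]), unname(.COMP[substr(x, 1, 1)]))
}

#' Canonicalize an MNV substitution pattern
#'
#' An MNV that changes the reference pair `ref2` into `alt2` (the two changed
#' bases, read 5'->3' on the plus strand, `d` bp apart) is the same mutational
#' event as its reverse complement observed on the other strand.  Patterns are
#' therefore collapsed to a canonical representative: the lexicographically
#' smaller of the pattern and its reverse complement, comparing the reference
#' pair first and the alternate pair second.  Self-complementary patterns map
#' to themselves.
#'
#' @param ref2,alt2 character vectors of the two changed reference/alternate
#'   bases (length-2 strings).  Both positions must actually change.
#' @param d distance `pos2 - pos1` in bp (the intervening `d - 1` bases are
#'   untouched and not part of the pattern).  Not used in the collapsing rule
#'   itself but validated.
#' @return character vector of canonical patterns formatted `"WX>YZ"`.
#' @examples
#' canonical_pattern("TC", "AA")  # "GA>TT" (pol-zeta signature)
#' canonical_pattern("TA", "AT")  # self-complementary fixed point
#' @export
canonical_pattern <- function(ref2, alt2, d = 1L) {
  ref2 <- toupper(ref2)
  alt2 <- toupper(alt2)
  stopifnot(all(nchar(ref2) == 2L), all(nchar(alt2) == 2L), all(d >= 1L))
  if (!all(strsplit(paste0(ref2, alt2, collapse = ""), "")[[1]] %in% .BASES)) {
    stop("patterns must be composed of A/C/G/T only")
  }
  r1 <- substr(ref2, 1, 1); r2 <- substr(ref2, 2, 2)
  a1 <- substr(alt2, 1, 1); a2 <- substr(alt2, 2, 2)
  if (any(r1 == a1) || any(r2 == a2)) {
    stop("not an MNV pattern: reference and alternate agree at one position")
  }
  rc_ref <- .rc2(ref2)
  rc_alt <- .rc2(alt2)
  keep <- (ref2 < rc_ref) | (ref2 == rc_ref & alt2 <= rc_alt)
  paste0(ifelse(keep, ref2, rc_ref), ">", ifelse(keep, alt2, rc_alt))
}

#' Split a pattern string into its reference and alternate pairs
#' @param pattern character vector formatted `"WX>YZ"`.
#' @return tibble with columns `pattern`, `ref`, `alt`.
#' @export
pattern_components <- function(pattern) {
  parts <- strsplit(pattern, ">", fixed = TRUE)
  tibble(
    pattern = pattern,
    ref = vapply(parts, `[`, character(1), 1L),
    alt = vapply(parts, `[`, character(1), 2L)
  )
}

#' Enumerate all canonical adjacent substitution patterns
#'
#' All 16 reference dinucleotides times 3 x 3 alternate choices give 144
#' ordered patterns; collapsing reverse complements leaves 78 canonical
#' classes, 12 of which are self-complementary.
#'
#' @return tibble with columns `pattern`, `ref`, `alt`, `self_complementary`,
#'   sorted lexicographically.
#' @export
all_canonical_patterns <- function() {
  grid <- expand.grid(
    r1 = .BASES, r2 = .BASES, a1 = .BASES, a2 = .BASES,
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$r1 != grid$a1 & grid$r2 != grid$a2, ]
  ref <- paste0(grid$r1, grid$r2)
  alt <- paste0(grid$a1, grid$a2)
  canon <- canonical_pattern(ref, alt)
  out <- pattern_components(sort(unique(canon)))
  out$self_complementary <- out$ref == revcomp(out$ref) &
    out$alt == revcomp(out$alt)
  out
}

#' Pattern classes used for origin-fraction summaries
#'
#' Five-way classification of the 78 canonical adjacent patterns by the
#' mutational signal they predominantly carry: CpG-transition combinations,
#' the polymerase-zeta doublet signature, slippage-prone repeat patterns,
#' pure transversion combinations, and the remaining 63 patterns.
#'
#' @return named list of character vectors of canonical patterns.
#' @export
pattern_origin_classes <- function() {
  list(
    cpg          = c("CA>TG", "AC>GT", "CC>TT", "GA>AG"),
    pol_zeta     = c("GA>TT", "GC>AA"),
    repeat_class = c("AA>TT", "AT>TA", "TA>AT"),
    transversion = c("TA>GC", "CG>AT", "AT>CG", "CG>GC", "GC>CG", "CG>AC"),
    others       = setdiff(
      all_canonical_patterns()$pattern,
      c("CA>TG", "AC>GT", "CC>TT", "GA>AG", "GA>TT", "GC>AA",
        "AA>TT", "AT>TA", "TA>AT",
        "TA>GC", "CG>AT", "AT>CG", "CG>GC", "GC>CG", "CG>AC")
    )
  )
}

#' Tabulate canonical substitution patterns
#'
#' Counts MNV records per canonical pattern and distance.  For adjacent
#' records (`d == 1`) the table is completed with zero rows so all 78
#' canonical patterns are always present.
#'
#' @param records tibble of MNV records with columns `pattern` and `d`
#'   (see [scan_mnvs()]).
#' @return tibble with columns `pattern`, `d`, `n`.
#' @export
pattern_spectrum <- function(records) {
  base <- all_canonical_patterns() %>%
    select("pattern") %>%
    mutate(d = 1L)
  counted <- records %>%
    filter(!is.na(.data$pattern)) %>%
    count(.data$pattern, .data$d, name = "n")
  base %>%
    left_join(counted, by = c("pattern", "d")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    bind_rows(filter(counted, .data$d != 1L)) %>%
    arrange(.data$d, .data$pattern)
}
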