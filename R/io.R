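#' Read a phased multi-sample VCF into plain matrices
#'
#' Wraps [VariantAnnotation::readVcf()] and flattens the fields this package
#' works with: fixed site columns plus per-sample GT / PS / GQ / DP and the
#' allele balance derived from AD.  Input must be decomposed and normalized
#' (biallelic records, minimal allele representation); violations are
#' reported with the offending site.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return list with elements
#'   `sites` (tibble: contig, pos, ref, alt, type, filter, ac, an),
#'   `samples` (character), and matrices `gt` (character, `a|b` or `a/b`),
#'   `phased` (logical), `hap1`/`hap2` (integer allele indices, NA when
#'   missing), `ps` (integer), `gq`, `dp` (integer), `ab` (numeric alt-read
#'   fraction, NA for non-het or missing AD).
#' @export
read_phased_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  altl <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altl)
  if (any(nalt != 1L)) {
    bad <- which(nalt != 1L)[1]
    stop("multiallelic record at ", as.character(GenomicRanges::seqnames(rr))[bad],
         ":", GenomicRanges::start(rr)[bad],
         "; decompose the VCF before scanning")
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(altl))
  pos <- GenomicRanges::start(rr)
  contig <- as.character(GenomicRanges::seqnames(rr))
  if (any(ref == alt)) {
    bad <- which(ref == alt)[1]
    stop("non-variant record at ", contig[bad], ":", pos[bad])
  }
  non_minimal <- nchar(ref) > 1L & nchar(alt) > 1L &
    substr(ref, 1, 1) == substr(alt, 1, 1) &
    substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))
  if (any(non_minimal)) {
    bad <- which(non_minimal)[1]
    stop("non-minimal allele representation at ", contig[bad], ":", pos[bad],
         " (", ref[bad], ">", alt[bad], "); normalize the VCF first")
  }
  type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                 ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))

  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT
  redim <- function(x) matrix(x, nrow(gt), ncol(gt),
                              dimnames = dimnames(gt))
  phased <- redim(substr(gt, 2, 2) == "|")
  a1 <- redim(suppressWarnings(as.integer(substr(gt, 1, 1))))
  a2 <- redim(suppressWarnings(as.integer(substr(gt, 3, 3))))

  ps <- if ("PS" %in% names(g)) {
    m <- g$PS; storage.mode(m) <- "integer"; m
  } else {
    matrix(NA_integer_, nrow(gt), ncol(gt))
  }
  gq <- if ("GQ" %in% names(g)) {
    m <- g$GQ; storage.mode(m) <- "integer"; m
  } else {
    matrix(NA_integer_, nrow(gt), ncol(gt))
  }
  dp <- if ("DP" %in% names(g)) {
    m <- g$DP; storage.mode(m) <- "integer"; m
  } else {
    matrix(NA_integer_, nrow(gt), ncol(gt))
  }
  ab <- matrix(NA_real_, nrow(gt), ncol(gt))
  if ("AD" %in% names(g)) {
    ad <- g$AD
    flat <- unlist(ad, use.names = FALSE)
    if (length(flat) == 2L * length(gt)) {
      refd <- flat[seq(1L, length(flat), by = 2L)]
      altd <- flat[seq(2L, length(flat), by = 2L)]
      tot <- refd + altd
      abv <- ifelse(is.na(tot) | tot == 0, NA_real_, altd / tot)
      ab <- matrix(abv, nrow(gt), ncol(gt))
    }
  }
  het <- !is.na(a1) & !is.na(a2) & (a1 + a2 == 1L)
  ab[!het] <- NA_real_

  an <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  ac <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)

  list(
    sites = tibble(
      contig = contig, pos = pos, ref = ref, alt = alt, type = type,
      filter = as.character(VariantAnnotation::filt(vcf)),
      ac = as.integer(ac), an = as.integer(an)
    ),
    samples = colnames(gt),
    gt = gt, phased = phased, hap1 = a1, hap2 = a2,
    ps = ps, gq = gq, dp = dp, ab = ab
  )
}

# Emit a phased multi-sample VCF 4.2.  `sites` is a tibble
# (contig, pos, ref, alt); genotype matrices are records x samples.
.write_vcf <- function(path, contigs, sites, samples, hap1, hap2, phased,
                       ps, gq, dp) {
  stopifnot(nrow(sites) == nrow(hap1))
  o <- order(match(sites$contig, names(contigs)), sites$pos)
  sites <- sites[o, , drop = FALSE]
  hap1 <- hap1[o, , drop = FALSE]; hap2 <- hap2[o, , drop = FALSE]
  phased <- phased[o, , drop = FALSE]; ps <- ps[o, , drop = FALSE]
  gq <- gq[o, , drop = FALSE]; dp <- dp[o, , drop = FALSE]

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), nchar(contigs)),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", paste(samples, collapse = "\t"), sep = "\t")
  )

  sep <- matrix("/", nrow(hap1), ncol(hap1)); sep[phased] <- "|"
  miss <- is.na(hap1) | is.na(hap2)
  gt_chr <- paste0(hap1, sep, hap2)
  gt_chr[miss] <- "./."
  ps_chr <- matrix(".", nrow(hap1), ncol(hap1))
  ps_chr[!is.na(ps)] <- as.character(ps[!is.na(ps)])
  het <- !miss & (hap1 + hap2 == 1L)
  hom_alt <- !miss & hap1 == 1L & hap2 == 1L
  ad_chr <- matrix(paste0(dp, ",0"), nrow(hap1))
  ad_chr[het] <- paste0(dp[het] %/% 2L, ",", dp[het] - dp[het] %/% 2L)
  ad_chr[hom_alt] <- paste0("0,", dp[hom_alt])
  ad_chr[miss] <- ".,."
  fld <- matrix(
    paste0(gt_chr, ":", ps_chr, ":", gq, ":", dp, ":", ad_chr),
    nrow = nrow(hap1)
  )
  fld[miss] <- "./.:.:.:.:.,."
  sample_block <- do.call(paste, c(as.data.frame(fld), list(sep = "\t")))

  body <- paste(sites$contig, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT:PS:GQ:DP:AD", sample_block, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sequences of a reference bundle as FASTA
#'
#' @param ref a `ReferenceBundle` (see [generate_reference()]).
#' @param path output FASTA path (60-column wrapped).
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read / write transcript models as TSV
#'
#' Six-column dialect: `gene`, `tx`, `contig`, `strand`, `cds_starts`,
#' `cds_ends` (comma-separated 1-based inclusive coordinates, ordered by
#' genomic position), plus an optional `loeuf_decile` column.
#'
#' @param path file path.
#' @return tibble of transcript models with list-columns `cds_starts`,
#'   `cds_ends`.
#' @export
read_transcripts_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble(
    gene = raw$gene, tx = raw$tx, contig = raw$contig, strand = raw$strand,
    cds_starts = lapply(strsplit(as.character(raw$cds_starts), ","),
                        as.integer),
    cds_ends = lapply(strsplit(as.character(raw$cds_ends), ","), as.integer),
    loeuf_decile = if ("loeuf_decile" %in% names(raw)) {
      as.integer(raw$loeuf_decile)
    } else {
      NA_integer_
    }
  )
}

#' @rdname read_transcripts_tsv
#' @param transcripts transcript tibble to write.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  flat <- transcripts
  flat$cds_starts <- vapply(transcripts$cds_starts, paste, character(1),
                            collapse = ",")
  flat$cds_ends <- vapply(transcripts$cds_ends, paste, character(1),
                          collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GFF3 file
#'
#' Collects `CDS` features grouped by their `Parent` (transcript) attribute.
#' The `gene_id` attribute, when present, supplies the gene id; otherwise
#' the transcript id is reused.
#'
#' @param path GFF3 path.
#' @return transcript tibble as in [read_transcripts_tsv()].
#' @export
read_transcripts_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3")
  }
  gr <- rtracklayer::import(path)
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(cds$Parent, ","))
  gene <- if (!is.null(cds$gene_id)) as.character(cds$gene_id) else parent
  df <- tibble(
    tx = parent, gene = gene,
    contig = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds), end = GenomicRanges::end(cds)
  )
  df %>%
    arrange(.data$tx, .data$start) %>%
    group_by(.data$gene, .data$tx, .data$contig, .data$strand) %>%
    summarise(cds_starts = list(.data$start), cds_ends = list(.data$end),
              .groups = "drop") %>%
    mutate(loeuf_decile = NA_integer_)
}

#' Read / write interval sets as BED
#'
#' BED interface is 0-based half-open; columns 4 and 5 carry the category
#' label and (for annotation sets) the methylation level.  Internally
#' intervals are 1-based inclusive tibbles.
#'
#' @param path BED path.
#' @return tibble with columns `contig`, `start`, `end` (1-based inclusive),
#'   plus `category` and `methylation` when present.
#' @export
read_bed <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- tibble(
    contig = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4) out$category <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$methylation <- as.numeric(raw[[5]])
  out
}

#' @rdname read_bed
#' @param intervals tibble with `contig`, `start`, `end` (1-based inclusive)
#'   and optional `category` / `methylation` columns.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$contig, intervals$start - 1L, intervals$end)
  if (!is.null(intervals$category)) cols <- c(cols, list(intervals$category))
  if (!is.null(intervals$methylation)) {
    cols <- c(cols, list(intervals$methylation))
  }
  utils::write.table(do.call(data.frame, cols), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$contig,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
  )
}

#' Write a pedigree file
#'
#' Standard 6-column PED: family, individual, father, mother, sex,
#' phenotype.
#'
#' @param ped tibble with columns `fid`, `iid`, `pat`, `mat`, `sex`,
#'   `phenotype`.
#' @param path output path.
#' @export
write_ped <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @return [read_ped()] returns the pedigree tibble.
#' @export
read_ped <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tibble(fid = as.character(raw[[1]]), iid = as.character(raw[[2]]),
         pat = as.character(raw[[3]]), mat = as.character(raw[[4]]),
         sex = raw[[5]], phenotype = raw[[6]])
}
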