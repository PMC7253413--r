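# Shared fixture builders.  Everything is generated in code at test time;
# no binary fixtures are stored.

# tiny deterministic reference with a couple of genes and repeat tracts
tiny_reference <- function(seed = 101L, length = 20000L,
                           repeats = default_repeat_spec(6L),
                           genes = list(
                             list(gene = "GPLUS", cds_len = 150L,
                                  strand = "+", loeuf_decile = 1L),
                             list(gene = "GMINUS", cds_len = 150L,
                                  strand = "-", loeuf_decile = 9L)
                           )) {
  generate_reference(length = length, repeat_spec = repeats,
                     gene_spec = genes, seed = seed)
}

# hand-written phased VCF from a compact genotype table.
# gts: list of character vectors (one per site) of per-sample GT strings,
# each optionally suffixed with ":PS"; e.g. "0|1:7".  GQ/DP/AD are filled
# with passing values unless overridden.
write_mini_vcf <- function(path, contig_len, sites, gts,
                           samples = sprintf("S%02d", seq_along(gts[[1]])),
                           gq = 99L, dp = 30L, filter = "PASS") {
  n <- length(gts[[1]])
  gq <- rep_len(gq, length(gts)); dp <- rep_len(dp, length(gts))
  filter <- rep_len(filter, length(gts))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", contig_len),
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=RF,Description=\"failed site QC\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"ps\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(gts), function(i) {
    flds <- vapply(gts[[i]], function(g) {
      parts <- strsplit(g, ":", fixed = TRUE)[[1]]
      gt <- parts[1]
      ps <- if (length(parts) > 1L) parts[2] else "."
      a <- suppressWarnings(as.integer(strsplit(gt, "[|/]")[[1]]))
      ad <- if (anyNA(a)) ".,." else if (sum(a) == 1L) {
        paste0(dp[i] %/% 2L, ",", dp[i] - dp[i] %/% 2L)
      } else if (sum(a) == 2L) paste0("0,", dp[i]) else paste0(dp[i], ",0")
      paste(gt, ps, gq[i], dp[i], ad, sep = ":")
    }, character(1))
    paste(c("chr1", sites$pos[i], ".", sites$ref[i], sites$alt[i], ".",
            filter[i], ".", "GT:PS:GQ:DP:AD", flds), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# independent brute-force MNV discovery: all site pairs x all samples,
# haplotypes reconstructed directly from GT strings.  Written without
# reference to the scanner's internals.
brute_force_mnvs <- function(vcf, max_dist, lcr = NULL) {
  v <- if (is.list(vcf)) vcf else read_phased_vcf(vcf)
  s <- v$sites
  in_lcr <- rep(FALSE, nrow(s))
  if (!is.null(lcr) && nrow(lcr)) {
    for (i in seq_len(nrow(s))) {
      in_lcr[i] <- any(lcr$contig == s$contig[i] &
                         lcr$start <= s$pos[i] &
                         lcr$end >= s$pos[i] + nchar(s$ref[i]) - 1L)
    }
  }
  ok_site <- s$filter == "PASS" & !in_lcr & s$type == "SNV"
  out <- list()
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(s))) {
      if (j <= i) next
      if (!ok_site[i] || !ok_site[j]) next
      if (s$contig[i] != s$contig[j]) next
      dd <- s$pos[j] - s$pos[i]
      if (dd < 1L || dd > max_dist) next
      cis_count <- 0L; hom_count <- 0L; ind <- character(0)
      for (k in seq_along(v$samples)) {
        pass <- function(ii) {
          het <- !is.na(v$hap1[ii, k]) &&
            (v$hap1[ii, k] + v$hap2[ii, k] == 1L)
          !is.na(v$gq[ii, k]) && v$gq[ii, k] >= 20L &&
            !is.na(v$dp[ii, k]) && v$dp[ii, k] >= 10L &&
            (!het || (!is.na(v$ab[ii, k]) && v$ab[ii, k] > 0.2))
        }
        if (!pass(i) || !pass(j)) next
        # state per site: "both", "none", "hap1", "hap2", "unknown"
        state <- function(ii) {
          h1 <- v$hap1[ii, k]; h2 <- v$hap2[ii, k]
          if (is.na(h1) || is.na(h2)) return("unknown")
          if (h1 == 1L && h2 == 1L) return("both")
          if (h1 + h2 == 0L) return("none")
          if (!v$phased[ii, k]) return("unknown")
          if (h1 == 1L) "hap1" else "hap2"
        }
        st1 <- state(i); st2 <- state(j)
        shared <- 0L
        if (st1 == "none" || st2 == "none") {
          shared <- 0L
        } else if (st1 == "both" && st2 == "both") {
          shared <- 2L
        } else if (st1 == "both" || st2 == "both") {
          shared <- 1L           # one hap of the het side matches
        } else if (st1 == "unknown" || st2 == "unknown") {
          shared <- 0L
        } else {
          # two phased hets: comparable only within one phase set
          same_ps <- !is.na(v$ps[i, k]) && !is.na(v$ps[j, k]) &&
            v$ps[i, k] == v$ps[j, k]
          shared <- if (same_ps && st1 == st2) 1L else 0L
        }
        if (shared > 0L) {
          cis_count <- cis_count + shared
          if (shared == 2L) hom_count <- hom_count + 1L
          ind <- c(ind, v$samples[k])
        }
      }
      if (cis_count > 0L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          pos1 = s$pos[i], pos2 = s$pos[j], d = dd,
          ac_mnv = cis_count, n_hom = hom_count,
          n_indiv = length(ind)
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(pos1 = integer(), pos2 = integer(),
                          d = integer(), ac_mnv = integer(),
                          n_hom = integer(), n_indiv = integer()))
  }
  dplyr::bind_rows(out)
}

# brute-force consequence classifier, written independently of
# classify_codon_change: mutates the full CDS, translates whole proteins
# and compares them.
brute_force_consequence <- function(cds, codon_idx, off1, off2, alt1,
                                    alt2) {
  mutate_at <- function(s, i, b) {
    substr(s, i, i) <- b
    s
  }
  p1 <- codon_idx * 3L + off1 + 1L
  p2 <- codon_idx * 3L + off2 + 1L
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  aa_ref <- substr(tr(cds), codon_idx + 1L, codon_idx + 1L)
  aa1 <- substr(tr(mutate_at(cds, p1, alt1)), codon_idx + 1L,
                codon_idx + 1L)
  aa2 <- substr(tr(mutate_at(cds, p2, alt2)), codon_idx + 1L,
                codon_idx + 1L)
  aam <- substr(tr(mutate_at(mutate_at(cds, p1, alt1), p2, alt2)),
                codon_idx + 1L, codon_idx + 1L)
  is_stop <- function(a) a == "*"
  cat_ <- if (is_stop(aam) && !is_stop(aa1) && !is_stop(aa2)) {
    "gained_nonsense"
  } else if (!is_stop(aam) && (is_stop(aa1) || is_stop(aa2))) {
    "rescued_nonsense"
  } else if (aa1 == aa_ref && aa2 == aa_ref && aam != aa_ref) {
    "gained_missense"
  } else if (aam == aa1 || aam == aa2) {
    "unchanged"
  } else if (aam != aa_ref && !is_stop(aam) &&
             ((aa1 != aa_ref && !is_stop(aa1)) ||
                (aa2 != aa_ref && !is_stop(aa2)))) {
    "changed_missense"
  } else {
    "other_changed"
  }
  list(aa_ref = aa_ref, aa1 = aa1, aa2 = aa2, aa_mnv = aam,
       category = cat_)
}

# naive repeat-unit counter for oracle comparisons
naive_repeat_count <- function(context, unit, d) {
  n <- 0L
  for (i in seq_len(nchar(context))) {
    if (i + d > nchar(context)) break
    if (substr(context, i, i) == substr(unit, 1, 1) &&
        substr(context, i + d, i + d) == substr(unit, 2, 2)) {
      n <- n + 1L
    }
  }
  n
}
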