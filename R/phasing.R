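# Read-backed cis/trans phasing of two coding variants on one transcript.
#
# When paired-end reads are aligned directly to a transcript, a pair whose
# mates cover both variant positions observes one molecule of mRNA and so one
# haplotype. Pairs carrying both alternate alleles support cis; pairs carrying
# exactly one support trans (as for the Y220C/R273C compound-heterozygous
# pattern in MFE319 cells, where alt-alt pairs are absent).

#' Describe a variant site on a transcript
#'
#' @param position 1-based transcript coordinate (cDNA convention).
#' @param ref_base,alt_base Single nucleotides in `A`, `C`, `G`, `T`;
#'   must differ.
#' @return A `variant_site` list.
#' @export
#' @examples
#' variant_site(659, "A", "G") # TP53 c.659A>G (Y220C)
variant_site <- function(position, ref_base, alt_base) {
  stopifnot(is.numeric(position), length(position) == 1L, position >= 1,
            position == trunc(position))
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  stopifnot(ref_base %in% c("A", "C", "G", "T"),
            alt_base %in% c("A", "C", "G", "T"),
            ref_base != alt_base)
  structure(list(position = as.integer(position),
                 ref_base = ref_base, alt_base = alt_base),
            class = "variant_site")
}

#' Parse a `"659:A>G"` style site string
#'
#' @param x String of the form `"<position>:<ref>><alt>"`.
#' @return A [variant_site()].
#' @export
parse_site <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([ACGTacgt])>([ACGTacgt])$", x))[[1L]]
  if (length(m) != 4L) {
    stop("cannot parse site string '", x, "'; expected e.g. \"659:A>G\"",
         call. = FALSE)
  }
  variant_site(as.integer(m[2L]), m[3L], m[4L])
}

#' Read single-transcript SAM alignments into a record table
#'
#' Uses Rsamtools to convert and read the SAM, so coordinates, flags and
#' CIGAR semantics follow the standard. Unmapped records are dropped.
#'
#' @param path Path to a SAM file whose reads are aligned to one transcript.
#' @return Data frame with columns `qname`, `flag`, `pos`, `cigar`, `seq`,
#'   `qual` (one row per alignment record).
#' @export
read_sam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM requires the Rsamtools package", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(qname = rec$qname, flag = rec$flag, pos = rec$pos,
             cigar = rec$cigar, seq = as.character(rec$seq),
             qual = as.character(rec$qual),
             stringsAsFactors = FALSE)
}

#' Read per-site allele calls from a simplified TSV
#'
#' Columns: `pair_id`, `site` (transcript position of the observed base),
#' `base`, `qual` (numeric Phred). One row per observed base per mate.
#'
#' @param path TSV path.
#' @return Data frame with those four columns.
#' @export
read_allele_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "site", "base", "qual") %in% names(df)))
  df
}

# Base and Phred quality observed by one alignment record at a 1-based
# reference position, walking the CIGAR (M/=/X consume both, I/S consume the
# query, D/N consume the reference, H/P neither). NULL when not covered.
.base_at <- function(pos, cigar, seq, qual, ref_pos) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  if (requireNamespace("GenomicAlignments", quietly = TRUE)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  } else {
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  }
  rpos <- pos; qpos <- 1L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      if (ref_pos >= rpos && ref_pos < rpos + len) {
        off <- qpos + (ref_pos - rpos)
        return(list(base = substr(seq, off, off),
                    qual = utf8ToInt(substr(qual, off, off)) - 33L))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (ref_pos >= rpos && ref_pos < rpos + len) return(NULL) # deleted
      rpos <- rpos + len
    } # H, P: no-op
  }
  NULL
}

# Collapse per-record base observations at one site to a per-pair allele
# category. Quality-filtered first; mates disagreeing -> "other"
# (conservative). `pair_ids` fixes the output order.
.site_alleles_by_pair <- function(pair, bases, quals, site, min_qual,
                                  pair_ids) {
  keep <- !is.na(bases) & !is.na(quals) & quals >= min_qual
  fac <- factor(pair[keep], levels = pair_ids)
  bl <- split(bases[keep], fac)
  ql <- split(quals[keep], fac)
  allele <- vapply(bl, function(b) {
    if (!length(b)) return("uncovered")
    if (length(unique(b)) > 1L) return("other")
    if (b[1L] == site$ref_base) "ref"
    else if (b[1L] == site$alt_base) "alt"
    else "other"
  }, "")
  qual <- vapply(ql, function(q) if (length(q)) min(q) else NA_real_, 0)
  list(allele = unname(allele), qual = unname(qual))
}

#' Extract per-pair alleles at two variant sites
#'
#' For every read pair, determines the allele observed at each site:
#' `"ref"`/`"alt"` for a confident match, `"other"` for a third base or
#' mate-disagreement, `"uncovered"` when no mate overlaps the site with
#' sufficient base quality. A pair is informative when both sites are
#' `ref` or `alt`.
#'
#' @param alignments Either a record table from [read_sam_alignments()]
#'   (columns `qname`, `pos`, `cigar`, `seq`, `qual`) or a per-site call
#'   table from [read_allele_tsv()] (columns `pair_id`, `site`, `base`,
#'   `qual`).
#' @param site1,site2 Two distinct [variant_site()] objects (or site strings
#'   accepted by [parse_site()]).
#' @param min_qual Minimum Phred base quality; default 20.
#' @return Data frame with columns `pair_id`, `allele_site1`, `allele_site2`,
#'   `min_base_quality`, `informative`.
#' @export
extract_pair_alleles <- function(alignments, site1, site2, min_qual = 20) {
  if (is.character(site1)) site1 <- parse_site(site1)
  if (is.character(site2)) site2 <- parse_site(site2)
  stopifnot(inherits(site1, "variant_site"), inherits(site2, "variant_site"))
  if (site1$position == site2$position) {
    stop("the two variant sites must be distinct positions", call. = FALSE)
  }
  if (all(c("pair_id", "site", "base") %in% names(alignments))) {
    obs <- .pair_alleles_tsv(alignments, site1, site2, min_qual)
  } else if (all(c("qname", "pos", "cigar", "seq", "qual") %in%
                 names(alignments))) {
    obs <- .pair_alleles_sam(alignments, site1, site2, min_qual)
  } else {
    stop("unrecognized alignment table layout", call. = FALSE)
  }
  obs$informative <- obs$allele_site1 %in% c("ref", "alt") &
    obs$allele_site2 %in% c("ref", "alt")
  obs
}

# Per-record base and quality at a reference position, vectorized with a
# fast path for fully matched alignments ("<n>M"); gapped/clipped CIGARs fall
# back to the per-record walker.
.records_base_at <- function(rec, ref_pos) {
  n <- nrow(rec)
  base <- rep(NA_character_, n)
  qual <- rep(NA_real_, n)
  simple <- grepl("^[0-9]+M$", rec$cigar)
  off <- ref_pos - rec$pos + 1L
  hit <- simple & off >= 1L & off <= nchar(rec$seq)
  if (any(hit)) {
    base[hit] <- substring(rec$seq[hit], off[hit], off[hit])
    qchars <- substring(rec$qual[hit], off[hit], off[hit])
    qual[hit] <- as.integer(charToRaw(paste(qchars, collapse = ""))) - 33L
  }
  for (i in which(!simple)) {
    h <- .base_at(rec$pos[i], rec$cigar[i], rec$seq[i], rec$qual[i], ref_pos)
    if (!is.null(h)) {
      base[i] <- h$base
      qual[i] <- h$qual
    }
  }
  list(base = base, qual = qual)
}

.pair_alleles_sam <- function(rec, site1, site2, min_qual) {
  bad <- is.na(rec$pos) | is.na(rec$cigar) | rec$cigar == "*" |
    is.na(rec$seq) | nchar(rec$seq) == 0L |
    nchar(rec$seq) != nchar(rec$qual)
  if (any(bad)) {
    message("skipping ", sum(bad), " malformed alignment record(s)")
    rec <- rec[!bad, , drop = FALSE]
  }
  pair_ids <- unique(rec$qname)
  b1 <- .records_base_at(rec, site1$position)
  b2 <- .records_base_at(rec, site2$position)
  a1 <- .site_alleles_by_pair(rec$qname, b1$base, b1$qual, site1, min_qual,
                              pair_ids)
  a2 <- .site_alleles_by_pair(rec$qname, b2$base, b2$qual, site2, min_qual,
                              pair_ids)
  data.frame(pair_id = pair_ids,
             allele_site1 = a1$allele, allele_site2 = a2$allele,
             min_base_quality = pmin(a1$qual, a2$qual, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

.pair_alleles_tsv <- function(df, site1, site2, min_qual) {
  pair_ids <- unique(as.character(df$pair_id))
  call_site <- function(site) {
    sel <- df$site == site$position
    .site_alleles_by_pair(as.character(df$pair_id[sel]), df$base[sel],
                          df$qual[sel], site, min_qual, pair_ids)
  }
  a1 <- call_site(site1)
  a2 <- call_site(site2)
  data.frame(pair_id = pair_ids,
             allele_site1 = a1$allele, allele_site2 = a2$allele,
             min_base_quality = pmin(a1$qual, a2$qual, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Call cis or trans from per-pair allele observations
#'
#' Only alt-containing informative pairs discriminate the configurations:
#' alt-alt pairs arise from a cis haplotype, alt-ref and ref-alt pairs from
#' the two trans haplotypes. Ref-ref pairs occur under either configuration
#' of a heterozygous pair of variants, so they count toward coverage
#' (`min_informative`) but are neutral in the decision.
#'
#' @param observations Data frame from [extract_pair_alleles()].
#' @param min_informative Minimum informative pairs (both sites ref/alt)
#'   for any call; default 5.
#' @param max_conflict Maximum tolerated share of alt-containing pairs
#'   contradicting the winning configuration; default 0.1 (robust to ~1%
#'   per-base sequencing error).
#' @return A `phasing_call`: list with `call` (`"cis"`, `"trans"`,
#'   `"ambiguous"` or `"insufficient"`), `counts` (2x2 table, site1 allele x
#'   site2 allele over informative pairs), `n_informative`, `n_cis_support`
#'   (alt-alt pairs), `n_trans_support` (alt-ref + ref-alt) and
#'   `conflict_fraction` (share of alt-containing pairs on the minority
#'   side; `NA` when there are none).
#' @export
phase <- function(observations, min_informative = 5, max_conflict = 0.1) {
  stopifnot(all(c("allele_site1", "allele_site2") %in% names(observations)))
  inf <- observations$allele_site1 %in% c("ref", "alt") &
    observations$allele_site2 %in% c("ref", "alt")
  a1 <- factor(observations$allele_site1[inf], levels = c("ref", "alt"))
  a2 <- factor(observations$allele_site2[inf], levels = c("ref", "alt"))
  counts <- table(site1 = a1, site2 = a2)
  n_inf <- sum(counts)
  aa <- counts["alt", "alt"]
  disc <- counts["alt", "ref"] + counts["ref", "alt"]
  n_alt <- aa + disc
  conflict <- if (n_alt > 0) min(aa, disc) / n_alt else NA_real_
  call <- if (n_inf < min_informative) {
    "insufficient"
  } else if (n_alt > 0 && aa / n_alt >= 1 - max_conflict) {
    "cis"
  } else if (n_alt > 0 && disc / n_alt >= 1 - max_conflict) {
    "trans"
  } else {
    "ambiguous"
  }
  structure(list(call = call, counts = counts, n_informative = n_inf,
                 n_cis_support = as.integer(aa),
                 n_trans_support = as.integer(disc),
                 conflict_fraction = conflict),
            class = "phasing_call")
}

#' @export
print.phasing_call <- function(x, ...) {
  cat("Phasing call:", x$call, "\n")
  cat("  informative pairs:", x$n_informative,
      "(cis support", x$n_cis_support,
      "/ trans support", x$n_trans_support, ")\n")
  cat("  conflict fraction:",
      if (is.na(x$conflict_fraction)) "NA"
      else format(x$conflict_fraction, digits = 3), "\n")
  print(x$counts)
  invisible(x)
}
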