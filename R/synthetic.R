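# Seeded generators emulating the statistical shape of each pipeline input:
# cell-line panels (hundreds of samples, thousands of features, mutant/WT
# imbalance), gene-level essentiality/abundance tables, paired reads over two
# variant sites and dose-response plates. All generators are deterministic
# under a fixed seed.

# default panel composition: large WT majority, missense-dominated mutants,
# resembling a cell-line panel's TP53 composition
.default_panel <- function(n_wt = 200L, n_missense = 50L,
                           n_truncating = 20L) {
  sample_annotation(
    sample_id = sprintf("S%03d", seq_len(n_wt + n_missense + n_truncating)),
    tp53_status = c(rep("WT", n_wt), rep("missense", n_missense),
                    rep("truncating", n_truncating)))
}

#' Generate a synthetic CRISPR-dependency score matrix
#'
#' Per-gene baseline essentiality drawn from Normal(-0.3, 0.3) (most genes
#' mildly non-essential, a tail of essentials), per-sample noise
#' Normal(0, `noise_sd`). By default no mutant-selective effect is planted
#' (the null that matches the observed absence of TP53 synthetic-lethal
#' dependencies); optionally one gene receives a fixed baseline and an extra
#' mutant-group shift.
#'
#' @param seed Integer seed; identical seed and arguments give identical
#'   output.
#' @param n_genes Number of genes; default 2000.
#' @param n_wt,n_missense,n_truncating Panel composition; defaults 200/50/20.
#' @param noise_sd Per-sample score noise; default 0.2.
#' @param planted Optional list `list(gene =, baseline =, shift =)` planting a
#'   synthetic-lethal gene: its baseline mean replaces the drawn one and
#'   `shift` is added in all non-WT samples. E.g. `baseline = -0.4, shift =
#'   -0.6` gives mutant mean -1.0 and delta -0.6.
#' @return List with `matrix` (genes x samples) and `annotation`.
#' @export
gen_dependency_matrix <- function(seed, n_genes = 2000L,
                                  n_wt = 200L, n_missense = 50L,
                                  n_truncating = 20L,
                                  noise_sd = 0.2, planted = NULL) {
  set.seed(seed)
  ann <- .default_panel(n_wt, n_missense, n_truncating)
  n_s <- nrow(ann)
  base <- stats::rnorm(n_genes, mean = -0.3, sd = 0.3)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  mat <- base + matrix(stats::rnorm(n_genes * n_s, sd = noise_sd),
                       n_genes, n_s)
  dimnames(mat) <- list(genes, ann$sample_id)
  if (!is.null(planted)) {
    stopifnot(planted$gene %in% genes)
    mut_cols <- ann$tp53_status != "WT"
    mat[planted$gene, ] <- planted$baseline +
      stats::rnorm(n_s, sd = noise_sd)
    mat[planted$gene, mut_cols] <- mat[planted$gene, mut_cols] +
      planted$shift
  }
  list(matrix = mat, annotation = ann)
}

#' Generate a synthetic z-scored proteomics matrix
#'
#' Raw abundances are Normal(0, 1) per feature; a planted feature receives a
#' group shift, then every feature is z-scored across all samples (the form
#' in which panel proteomics is distributed). Because planting inflates the
#' marginal SD before z-scoring, effect sizes are specified on the
#' post-z-score scale: the generator solves for the raw shift `s` satisfying
#' `s / sqrt(1 + s^2 f (1 - f)) = shift_z` (with `f` the planted-group
#' fraction) so that the realized between-group z-score difference matches
#' the request. Shifts at or above `1/sqrt(f(1-f))` are unattainable after
#' z-scoring and raise an error.
#'
#' @inheritParams gen_dependency_matrix
#' @param n_proteins Number of protein features; default 2000.
#' @param planted Optional list `list(feature =, group =, shift_z =)`;
#'   `group` is the TP53 status receiving the shift. Default `NULL` (null
#'   matrix). The conventional p53-like plant is
#'   `list(feature = "P53_LIKE", group = "missense", shift_z = 2.5)`.
#' @return List with `matrix` (proteins x samples, z-scored per feature) and
#'   `annotation`.
#' @export
gen_proteomics_matrix <- function(seed, n_proteins = 2000L,
                                  n_wt = 200L, n_missense = 50L,
                                  n_truncating = 20L, planted = NULL) {
  set.seed(seed)
  ann <- .default_panel(n_wt, n_missense, n_truncating)
  n_s <- nrow(ann)
  feats <- sprintf("PROT%04d", seq_len(n_proteins))
  mat <- matrix(stats::rnorm(n_proteins * n_s), n_proteins, n_s)
  if (!is.null(planted)) {
    feats[1L] <- planted$feature
    f <- sum(ann$tp53_status == planted$group) / n_s
    zmax <- 1 / sqrt(f * (1 - f))
    if (planted$shift_z >= zmax) {
      stop("requested post-z shift ", planted$shift_z,
           " unattainable for group fraction ", signif(f, 3),
           " (max ", signif(zmax, 4), ")", call. = FALSE)
    }
    s <- planted$shift_z / sqrt(1 - planted$shift_z^2 * f * (1 - f))
    mat[1L, ann$tp53_status == planted$group] <-
      mat[1L, ann$tp53_status == planted$group] + s
  }
  zm <- t(scale(t(mat))) # z-score per feature after planting
  mat <- matrix(as.numeric(zm), n_proteins, n_s,
                dimnames = list(feats, ann$sample_id))
  list(matrix = mat, annotation = ann)
}

#' Generate synthetic essentiality and abundance tables for nomination
#'
#' Decoy genes have mildly negative Chronos scores (truncated above -1.8 so
#' that no decoy can pass the essentiality filter) and log-normal protein
#' abundances centered near 100 nM. Planted payload-like targets combine
#' strong essentiality (Chronos in [-3, -2.5]) with low abundance
#' (1-100 nM), so they pass the filter and take the best composite scores.
#'
#' @param seed Integer seed.
#' @param n_decoys Number of decoy genes; default 2000.
#' @param n_planted Number of planted targets; default 5.
#' @return List with `essentiality` (`gene`, `mean_chronos`), `abundance`
#'   (`gene`, `abundance_nM`) and `planted` (character vector of planted
#'   gene ids).
#' @export
gen_nomination_tables <- function(seed, n_decoys = 2000L, n_planted = 5L) {
  set.seed(seed)
  genes <- sprintf("DECOY%04d", seq_len(n_decoys))
  chronos <- pmax(stats::rnorm(n_decoys, -0.3, 0.4), -1.8)
  abund <- 10^stats::rnorm(n_decoys, mean = 2, sd = 1)
  planted <- character(0)
  if (n_planted > 0L) {
    planted <- sprintf("TARGET%02d", seq_len(n_planted))
    genes <- c(planted, genes)
    chronos <- c(stats::runif(n_planted, -3, -2.5), chronos)
    abund <- c(10^stats::runif(n_planted, 0, 2), abund)
  }
  list(essentiality = data.frame(gene = genes, mean_chronos = chronos,
                                 stringsAsFactors = FALSE),
       abundance = data.frame(gene = genes, abundance_nM = abund,
                              stringsAsFactors = FALSE),
       planted = planted)
}

# write SAM records for read pairs aligned to one transcript
.write_sam <- function(path, transcript, tlen, recs) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", transcript, "\tLN:", tlen))
  if (nrow(recs)) {
    lines <- c(lines,
               paste(recs$qname, recs$flag, transcript, recs$pos, "60",
                     recs$cigar, "=", recs$mpos, recs$tlen, recs$seq,
                     recs$qual, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate paired reads over two heterozygous variant sites
#'
#' A two-haplotype model of a compound-heterozygous transcript: in `cis` one
#' haplotype carries both alternate alleles and the other neither; in `trans`
#' each haplotype carries exactly one. Every pair is drawn from one haplotype
#' (one mRNA molecule); mate 1 covers site 1 and mate 2 covers site 2, and
#' each base is miscalled to a uniformly random other base with probability
#' `error_rate`.
#'
#' @param phase `"cis"` or `"trans"` — the ground truth.
#' @param n_pairs Number of read pairs; default 100.
#' @param error_rate Per-base miscall probability; default 0.01.
#' @param seed Integer seed.
#' @param read_len Read length (nt); default 100.
#' @param sam_path Optional path; when given, the alignments are also written
#'   as SAM against the synthetic transcript.
#' @return List with `alignments` (record table in the
#'   [read_sam_alignments()] layout), `sites` (list of the two
#'   [variant_site()]s: 659 A>G and 817 C>T, the Y220C/R273C cDNA
#'   convention), `truth` (data frame `pair_id`, `haplotype`,
#'   `allele_site1`, `allele_site2` before sequencing error), `phase`,
#'   `transcript_seq` and, if written, `sam_path`.
#' @export
gen_read_pairs <- function(phase = c("trans", "cis"), n_pairs = 100L,
                           error_rate = 0.01, seed = 1L, read_len = 100L,
                           sam_path = NULL) {
  phase <- match.arg(phase)
  stopifnot(error_rate >= 0, error_rate <= 1, n_pairs >= 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  tlen <- 1200L
  site1 <- variant_site(659, "A", "G")
  site2 <- variant_site(817, "C", "T")
  ref <- sample(bases, tlen, replace = TRUE)
  ref[site1$position] <- site1$ref_base
  ref[site2$position] <- site2$ref_base
  hap <- list(ref, ref)
  if (phase == "cis") {
    hap[[1L]][site1$position] <- site1$alt_base
    hap[[1L]][site2$position] <- site2$alt_base
  } else {
    hap[[1L]][site1$position] <- site1$alt_base
    hap[[2L]][site2$position] <- site2$alt_base
  }
  qual_str <- strrep(rawToChar(as.raw(30L + 33L)), read_len) # Phred 30
  recs <- NULL
  truth <- NULL
  if (n_pairs > 0L) {
    hap_idx <- sample(1:2, n_pairs, replace = TRUE)
    # mate 1 spans site 1, mate 2 ends at/after site 2 and fits the transcript
    s1 <- sample(max(1L, site1$position - read_len + 1L):site1$position,
                 n_pairs, replace = TRUE)
    s2lo <- max(site2$position - read_len + 1L, 1L)
    s2hi <- min(site2$position, tlen - read_len + 1L)
    s2 <- sample(s2lo:s2hi, n_pairs, replace = TRUE)
    mk_read <- function(start, h) {
      seq <- hap[[h]][start:(start + read_len - 1L)]
      err <- stats::runif(read_len) < error_rate
      if (any(err)) {
        seq[err] <- vapply(seq[err],
                           function(b) sample(setdiff(bases, b), 1L), "")
      }
      paste(seq, collapse = "")
    }
    pid <- sprintf("pair%04d", seq_len(n_pairs))
    r1 <- vapply(seq_len(n_pairs), function(i) mk_read(s1[i], hap_idx[i]), "")
    r2 <- vapply(seq_len(n_pairs), function(i) mk_read(s2[i], hap_idx[i]), "")
    isize <- s2 + read_len - s1
    recs <- data.frame(
      qname = rep(pid, 2L),
      flag = c(rep(99L, n_pairs), rep(147L, n_pairs)),
      pos = c(s1, s2),
      mpos = c(s2, s1),
      tlen = c(isize, -isize),
      cigar = paste0(read_len, "M"),
      seq = c(r1, r2),
      qual = qual_str,
      stringsAsFactors = FALSE)
    hap_allele <- function(h, site) {
      b <- hap[[h]][site$position]
      if (b == site$alt_base) "alt" else "ref"
    }
    truth <- data.frame(
      pair_id = pid, haplotype = hap_idx,
      allele_site1 = vapply(hap_idx, hap_allele, "", site = site1),
      allele_site2 = vapply(hap_idx, hap_allele, "", site = site2),
      stringsAsFactors = FALSE)
  } else {
    recs <- data.frame(qname = character(), flag = integer(),
                       pos = integer(), mpos = integer(), tlen = integer(),
                       cigar = character(), seq = character(),
                       qual = character(), stringsAsFactors = FALSE)
    truth <- data.frame(pair_id = character(), haplotype = integer(),
                        allele_site1 = character(),
                        allele_site2 = character(), stringsAsFactors = FALSE)
  }
  out <- list(alignments = recs, sites = list(site1 = site1, site2 = site2),
              truth = truth, phase = phase,
              transcript_seq = paste(ref, collapse = ""))
  if (!is.null(sam_path) && n_pairs >= 0L) {
    .write_sam(sam_path, "TRANSCRIPT1", tlen, recs)
    out$sam_path <- sam_path
  }
  out
}

#' Generate a synthetic dose-response table from 4PL truth
#'
#' Samples the four-parameter logistic at a log-spaced dose grid with
#' replicate Gaussian noise scaled to the curve's dynamic range, plus vehicle
#' (dose 0) rows at the `top` level.
#'
#' @param ec50 True EC50 (M); default 25e-9 (25 nM).
#' @param hill True hill slope; default 1.
#' @param top,bottom True asymptotes; defaults 100 and 0 (percent scale).
#' @param noise_sd Noise SD as a fraction of `|top - bottom|` (absolute when
#'   the truth is flat); default 0.05.
#' @param dose_grid Doses (M); default 8 half-log steps around the EC50.
#' @param n_rep Replicates per dose; default 3.
#' @param n_vehicle Vehicle rows; default `n_rep`.
#' @param seed Integer seed.
#' @return List with `table` (`dose`, `response`, `replicate`) and `truth`
#'   (the input parameters).
#' @export
gen_dose_response <- function(ec50 = 25e-9, hill = 1, top = 100, bottom = 0,
                              noise_sd = 0.05,
                              dose_grid = ec50 * 10^seq(-2, 1.5, by = 0.5),
                              n_rep = 3L, n_vehicle = n_rep, seed = 1L) {
  stopifnot(ec50 > 0, all(dose_grid > 0), n_rep >= 1L)
  set.seed(seed)
  span <- abs(top - bottom)
  sd_abs <- noise_sd * if (span > 0) span else 1
  dose <- c(rep(0, n_vehicle), rep(dose_grid, each = n_rep))
  mu <- ifelse(dose == 0, top,
               bottom + (top - bottom) / (1 + (dose / ec50)^hill))
  resp <- mu + stats::rnorm(length(dose), sd = sd_abs)
  tab <- data.frame(dose = dose, response = resp,
                    replicate = c(seq_len(n_vehicle),
                                  rep(seq_len(n_rep), times =
                                        length(dose_grid))))
  list(table = tab,
       truth = list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
                    noise_sd = noise_sd))
}
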