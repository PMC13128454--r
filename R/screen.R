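# Differential screening of sample x feature score matrices (CRISPR
# dependency, drug sensitivity, quantitative proteomics) between TP53-mutant
# and wild-type cell lines.

TP53_STATUSES <- c("WT", "missense", "truncating", "other")

#' Construct a sample annotation table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param tp53_status Character vector, one of `"WT"`, `"missense"`,
#'   `"truncating"`, `"other"` per sample.
#' @return Data frame with columns `sample_id`, `tp53_status`.
#' @export
sample_annotation <- function(sample_id, tp53_status) {
  sample_id <- as.character(sample_id)
  tp53_status <- as.character(tp53_status)
  stopifnot(length(sample_id) == length(tp53_status),
            !anyDuplicated(sample_id))
  bad <- setdiff(unique(tp53_status), TP53_STATUSES)
  if (length(bad)) {
    stop("unknown tp53_status value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(TP53_STATUSES, collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = sample_id, tp53_status = tp53_status,
             stringsAsFactors = FALSE)
}

# Resolve annotation to mutant/WT column index sets for a features x samples
# matrix. Every matrix column must be annotated; WT group must be non-empty.
.screen_groups <- function(mat, annotation, mutant_def) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  stopifnot(all(c("sample_id", "tp53_status") %in% names(annotation)))
  mutant_def <- match.arg(mutant_def, TP53_STATUSES[-1L], several.ok = TRUE)
  status <- annotation$tp53_status[match(colnames(mat),
                                         annotation$sample_id)]
  if (anyNA(status)) {
    stop("matrix samples missing from annotation: ",
         paste(head(colnames(mat)[is.na(status)], 5L), collapse = ", "),
         call. = FALSE)
  }
  mut <- which(status %in% mutant_def)
  wt <- which(status == "WT")
  if (!length(wt)) stop("no WT samples in annotation", call. = FALSE)
  if (!length(mut)) stop("no samples match mutant_def", call. = FALSE)
  list(mut = mut, wt = wt)
}

#' Per-feature group means between mutant and wild-type samples
#'
#' Means are taken over non-missing values within each group; a feature with
#' no observation in a group gets `NA` (missing, never zero) for that group
#' and for the difference.
#'
#' @param mat Numeric matrix, features in rows, samples in columns (column
#'   names are sample ids); `NA` allowed.
#' @param annotation A [sample_annotation()] data frame covering every column.
#' @param mutant_def Which TP53 statuses count as mutant; default all
#'   non-WT (`missense`, `truncating`, `other`).
#' @return Data frame with columns `feature`, `mean_mut`, `mean_wt`, `delta`
#'   (`mean_mut - mean_wt`), `n_mut`, `n_wt` (non-missing counts).
#' @export
group_means <- function(mat, annotation,
                        mutant_def = c("missense", "truncating", "other")) {
  g <- .screen_groups(mat, annotation, mutant_def)
  n_mut <- rowSums(!is.na(mat[, g$mut, drop = FALSE]))
  n_wt <- rowSums(!is.na(mat[, g$wt, drop = FALSE]))
  mean_mut <- rowMeans(mat[, g$mut, drop = FALSE], na.rm = TRUE)
  mean_wt <- rowMeans(mat[, g$wt, drop = FALSE], na.rm = TRUE)
  mean_mut[n_mut == 0L] <- NA_real_
  mean_wt[n_wt == 0L] <- NA_real_
  data.frame(feature = rownames(mat),
             mean_mut = mean_mut, mean_wt = mean_wt,
             delta = mean_mut - mean_wt,
             n_mut = n_mut, n_wt = n_wt,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Synthetic-lethal candidate filter on dependency group means
#'
#' Flags genes that are both strongly essential in the mutant group and
#' selectively more essential there than in wild type. An empty result is a
#' valid (and, for TP53, the observed) outcome.
#'
#' @param rows Output of [group_means()] on a dependency-score matrix (more
#'   negative = more essential).
#' @param mut_thresh Mutant-group mean must be below this; default -0.5.
#' @param delta_thresh Mutant-minus-WT difference must be below this;
#'   default -0.2.
#' @return Character vector of features passing both thresholds, sorted by
#'   `delta` ascending (most selective first).
#' @export
dependency_hits <- function(rows, mut_thresh = -0.5, delta_thresh = -0.2) {
  stopifnot(all(c("feature", "mean_mut", "delta") %in% names(rows)))
  keep <- !is.na(rows$mean_mut) & !is.na(rows$delta) &
    rows$mean_mut < mut_thresh & rows$delta < delta_thresh
  hits <- rows[keep, , drop = FALSE]
  hits$feature[order(hits$delta)]
}

# Vectorized two-sided two-sample t statistics per matrix row.
# Welch (default) or pooled-variance Student. Rows with < 2 observations in a
# group, or zero variance in both groups, get NA.
.row_ttest <- function(mat, idx1, idx2, var_equal = FALSE) {
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1L, 1L)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1L, 1L)
  ok <- n1 >= 2L & n2 >= 2L
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2L
  } else {
    a1 <- v1 / n1; a2 <- v2 / n2
    se2 <- a1 + a2
    df <- se2^2 / (a1^2 / (n1 - 1L) + a2^2 / (n2 - 1L))
  }
  ok <- ok & se2 > 0 & is.finite(se2)
  tstat <- ifelse(ok, (m1 - m2) / sqrt(se2), NA_real_)
  p <- ifelse(ok, 2 * stats::pt(-abs(tstat), df), NA_real_)
  list(p = p, t = tstat, df = ifelse(ok, df, NA_real_))
}

#' Proteome-wide differential abundance screen
#'
#' Per-feature two-sided t-test (Welch by default, matching the
#' heteroscedastic convention for pairwise comparisons) of mutant versus
#' wild-type z-scored abundance, with Benjamini-Hochberg adjustment across all
#' tested features. Hits must both clear the mean-difference threshold and be
#' significant after adjustment — the rule under which p53 itself is the lone
#' protein elevated in TP53-mutant lines.
#'
#' @inheritParams group_means
#' @param delta_thresh Minimum mutant-minus-WT mean difference for a hit;
#'   default 2 (z-score units).
#' @param q_thresh Maximum BH-adjusted q-value for a hit; default 0.05.
#' @param var_equal Use pooled-variance Student's t instead of Welch.
#' @return List with `table` (a data frame: `feature`, `mean_mut`, `mean_wt`,
#'   `delta`, `n_mut`, `n_wt`, `p_value`, `q_value`) and `hits` (character
#'   vector sorted by `delta` descending). Features with fewer than two
#'   observations in either group, or no variance, get `NA` p/q and are never
#'   hits.
#' @export
proteomic_screen <- function(mat, annotation,
                             mutant_def = c("missense", "truncating", "other"),
                             delta_thresh = 2, q_thresh = 0.05,
                             var_equal = FALSE) {
  g <- .screen_groups(mat, annotation, mutant_def)
  tab <- group_means(mat, annotation, mutant_def)
  tt <- .row_ttest(mat, g$mut, g$wt, var_equal = var_equal)
  tab$p_value <- tt$p
  tab$q_value <- stats::p.adjust(tt$p, method = "BH")
  keep <- !is.na(tab$q_value) & !is.na(tab$delta) &
    tab$delta > delta_thresh & tab$q_value < q_thresh
  hits <- tab[keep, , drop = FALSE]
  list(table = tab, hits = hits$feature[order(-hits$delta)])
}

#' Read a score matrix from CSV/TSV
#'
#' @param path File path; delimiter inferred from the extension (`.tsv`
#'   tab, otherwise comma).
#' @param features_in_rows If `FALSE`, the file is samples x features and is
#'   transposed on read.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_score_matrix <- function(path, features_in_rows = TRUE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!features_in_rows) m <- t(m)
  m
}

#' Read a sample annotation CSV (columns `sample_id`, `tp53_status`)
#'
#' @param path File path.
#' @return Validated annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_annotation(df$sample_id, df$tp53_status)
}
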