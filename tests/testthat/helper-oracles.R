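# Independent oracles kept deliberately naive: they re-derive expected values
# by direct transcription of the model definitions, not by calling the
# package's own code paths.

# Hand-coded transcription of the four rate equations.
oracle_derivatives <- function(M_A, M_B, P, MP, k_diff, k_bind, k_unbind,
                               t_half, r_prod) {
  c(dM_A = 0,
    dM_B = -k_diff * M_B + k_diff * M_A - k_bind * M_B * P + k_unbind * MP,
    dP = -k_bind * M_B * P + k_unbind * MP - P * log(2) / t_half + r_prod,
    dMP = k_bind * M_B * P - k_unbind * MP - MP * log(2) / t_half)
}

# Brute-force group means/delta by explicit loops over samples.
oracle_group_means <- function(mat, annotation, mutant_def) {
  status <- annotation$tp53_status[match(colnames(mat),
                                         annotation$sample_id)]
  t(apply(mat, 1L, function(row) {
    mv <- row[status %in% mutant_def]
    wv <- row[status == "WT"]
    mm <- if (sum(!is.na(mv))) mean(mv, na.rm = TRUE) else NA_real_
    mw <- if (sum(!is.na(wv))) mean(wv, na.rm = TRUE) else NA_real_
    c(mean_mut = mm, mean_wt = mw, delta = mm - mw)
  }))
}

# Welch p-values one feature at a time through stats::t.test.
oracle_welch_p <- function(mat, annotation, mutant_def) {
  status <- annotation$tp53_status[match(colnames(mat),
                                         annotation$sample_id)]
  apply(mat, 1L, function(row) {
    mv <- row[status %in% mutant_def]
    wv <- row[status == "WT"]
    mv <- mv[!is.na(mv)]; wv <- wv[!is.na(wv)]
    if (length(mv) < 2L || length(wv) < 2L) return(NA_real_)
    out <- tryCatch(stats::t.test(mv, wv, var.equal = FALSE)$p.value,
                    error = function(e) NA_real_)
    out
  })
}

# Filter-then-sort nomination by explicit enumeration.
oracle_nominate <- function(ess, ab, chronos_max, abundance_max) {
  tab <- merge(ess, ab, by = "gene")
  keep <- tab$mean_chronos <= chronos_max & tab$abundance_nM <= abundance_max
  tab <- tab[keep, , drop = FALSE]
  score <- log10(tab$abundance_nM) + tab$mean_chronos
  tab$gene[order(score, tab$gene)]
}

# Build an allele-observation table straight from counts.
obs_from_counts <- function(n_aa = 0, n_ar = 0, n_ra = 0, n_rr = 0,
                            extra = NULL) {
  n <- n_aa + n_ar + n_ra + n_rr
  df <- data.frame(
    pair_id = sprintf("p%03d", seq_len(n)),
    allele_site1 = c(rep("alt", n_aa + n_ar), rep("ref", n_ra + n_rr)),
    allele_site2 = c(rep("alt", n_aa), rep("ref", n_ar),
                     rep("alt", n_ra), rep("ref", n_rr)),
    min_base_quality = rep(30, n),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  df$informative <- df$allele_site1 %in% c("ref", "alt") &
    df$allele_site2 %in% c("ref", "alt")
  df
}
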