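# Nomination of cytotoxic-payload targets: genes whose knockout is strongly
# essential and whose protein is scarce, so that a bifunctional molecule's
# cytotoxic warhead acts on a target far less abundant than trapped mutant
# p53.

#' Rank candidate payload targets by essentiality and protein abundance
#'
#' Inner-joins a gene-level essentiality table to a protein-concentration
#' table, filters to genes with mean Chronos score at or below `chronos_max`
#' (more negative = more essential) and abundance at or below
#' `abundance_max_nM` (the p53 concentration measured in 293T cells is the
#' reference ceiling, 920 nM), then ranks by the composite score
#' `log10(abundance_nM) + mean_chronos`, lowest first. Because the abundance
#' enters through its logarithm, rescaling the abundance unit shifts every
#' score by a constant and leaves the ordering unchanged.
#'
#' @param essentiality Data frame with columns `gene`, `mean_chronos`.
#' @param abundance Data frame with columns `gene`, `abundance_nM` (> 0).
#' @param chronos_max Essentiality ceiling; default -2.
#' @param abundance_max_nM Abundance ceiling in nM; default 920.
#' @param top_k Optional truncation to the best `top_k` genes.
#' @return Data frame with columns `gene`, `mean_chronos`, `abundance_nM`,
#'   `score`, `passes_filter`, `rank` — filtered rows only, sorted by `score`
#'   ascending with lexicographic tie-break on `gene`. Empty (with a warning)
#'   when the join or the filter leaves nothing.
#' @export
#' @examples
#' ess <- data.frame(gene = c("A", "B", "C"), mean_chronos = c(-3, -3, -1))
#' ab <- data.frame(gene = c("A", "B", "C"), abundance_nM = c(10, 100, 1))
#' nominate_targets(ess, ab) # A (score -2) ranks before B (score -1)
nominate_targets <- function(essentiality, abundance,
                             chronos_max = -2, abundance_max_nM = 920,
                             top_k = NULL) {
  stopifnot(all(c("gene", "mean_chronos") %in% names(essentiality)),
            all(c("gene", "abundance_nM") %in% names(abundance)))
  tab <- merge(essentiality[, c("gene", "mean_chronos")],
               abundance[, c("gene", "abundance_nM")],
               by = "gene")
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (!nrow(tab)) {
    warning("no genes shared between essentiality and abundance tables")
    return(.empty_nomination())
  }
  if (any(tab$abundance_nM <= 0)) {
    stop("abundance_nM must be positive for all scored genes", call. = FALSE)
  }
  tab$score <- log10(tab$abundance_nM) + tab$mean_chronos
  tab$passes_filter <- tab$mean_chronos <= chronos_max &
    tab$abundance_nM <= abundance_max_nM
  tab <- tab[tab$passes_filter, , drop = FALSE]
  if (!nrow(tab)) return(.empty_nomination())
  tab <- tab[order(tab$score, tab$gene), , drop = FALSE]
  if (!is.null(top_k)) tab <- utils::head(tab, top_k)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

.empty_nomination <- function() {
  data.frame(gene = character(), mean_chronos = numeric(),
             abundance_nM = numeric(), score = numeric(),
             passes_filter = logical(), rank = integer(),
             stringsAsFactors = FALSE)
}
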