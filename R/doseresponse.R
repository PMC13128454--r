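# Quantification of dose-response readouts: vehicle normalization,
# four-parameter logistic (4PL) fits, competition / NanoBiT Emax conventions
# and qPCR 2^-ddCt relative expression.

#' Normalize responses to the vehicle (dose 0) mean
#'
#' Each response is divided by the mean of the vehicle observations, so
#' vehicle rows come out at ~1 and treated rows are fractions (competition,
#' viability) or fold-signals (NanoBiT) of the untreated baseline.
#'
#' @param table Data frame with columns `dose` (M, 0 = vehicle) and
#'   `response`; other columns are kept.
#' @return The table with `response` replaced by the vehicle-normalized value.
#' @export
normalize_to_vehicle <- function(table) {
  stopifnot(all(c("dose", "response") %in% names(table)))
  veh <- table$response[table$dose == 0]
  if (!length(veh)) {
    stop("no vehicle (dose 0) observations to normalize against",
         call. = FALSE)
  }
  m <- mean(veh, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    stop("vehicle mean is zero or non-finite; cannot normalize",
         call. = FALSE)
  }
  table$response <- table$response / m
  table
}

# Per-dose aggregation of replicates (vehicle excluded).
.dose_means <- function(table, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  tab <- table[table$dose > 0 & is.finite(table$response), , drop = FALSE]
  if (!nrow(tab)) stop("no nonzero-dose observations", call. = FALSE)
  fn <- if (aggregate == "mean") mean else stats::median
  agg <- tapply(tab$response, tab$dose, fn)
  data.frame(dose = as.numeric(names(agg)), response = as.numeric(agg))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit on log dose of
#' `response = bottom + (top - bottom) / (1 + (dose/ec50)^hill)`,
#' so a positive hill slope describes a falling curve (top at low dose) and a
#' negative one a rising curve; the orientation is picked up automatically
#' from the dose-extreme means at initialization. EC50 is fitted on the log
#' scale and bounded within `[min_dose/100, max_dose*100]`. The fit refuses to
#' fabricate an EC50 from a flat curve: when the fitted dynamic range does not
#' clearly exceed the residual noise, `converged` is `FALSE` and `ec50` is
#' `NA`.
#'
#' @param table Data frame with columns `dose` (M; vehicle rows ignored for
#'   fitting) and `response`; replicates allowed.
#' @return A `fit_4pl` object: list with `ec50` (M), `hill`, `top`, `bottom`
#'   (asymptotes, `bottom <= top` after orientation normalization), `emax`
#'   (fitted high-dose asymptote), `converged`, `residual_sd`, `n`.
#' @export
#' @examples
#' d <- gen_dose_response(ec50 = 25e-9, seed = 1)
#' fit_4pl(d$table)$ec50
fit_4pl <- function(table) {
  stopifnot(all(c("dose", "response") %in% names(table)))
  tab <- table[table$dose > 0 & is.finite(table$response), , drop = FALSE]
  if (length(unique(tab$dose)) < 2L) {
    stop("need >= 2 distinct nonzero doses to fit", call. = FALSE)
  }
  dm <- .dose_means(tab)
  dm <- dm[order(dm$dose), ]
  top0 <- dm$response[1L]
  bot0 <- dm$response[nrow(dm)]
  hill0 <- if (top0 >= bot0) 1 else -1
  mid <- (top0 + bot0) / 2
  ec50_0 <- dm$dose[which.min(abs(dm$response - mid))]
  lo <- log(min(tab$dose) / 100)
  hi <- log(max(tab$dose) * 100)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) /
        (1 + exp(hill * (log(dose) - lec50))),
      data = tab,
      start = list(top = max(top0, bot0), bottom = min(top0, bot0),
                   hill = hill0, lec50 = log(ec50_0)),
      lower = c(top = -Inf, bottom = -Inf, hill = -20, lec50 = lo),
      upper = c(top = Inf, bottom = Inf, hill = 20, lec50 = hi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  n <- nrow(tab)
  if (is.null(fit)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          emax = NA_real_, converged = FALSE,
                          residual_sd = stats::sd(tab$response), n = n),
                     class = "fit_4pl"))
  }
  cf <- stats::coef(fit)
  res_sd <- sqrt(sum(stats::residuals(fit)^2) / max(n - 4L, 1L))
  top <- max(cf[["top"]], cf[["bottom"]])
  bottom <- min(cf[["top"]], cf[["bottom"]])
  span <- top - bottom
  # the high-dose asymptote: bottom for falling curves, top for rising
  falling <- (cf[["hill"]] >= 0) == (cf[["top"]] >= cf[["bottom"]])
  emax <- if (falling) bottom else top
  ec50 <- exp(cf[["lec50"]])
  flat <- span <= 3 * res_sd ||
    ec50 <= exp(lo) * 1.0001 || ec50 >= exp(hi) * 0.9999
  structure(list(ec50 = if (flat) NA_real_ else ec50,
                 hill = abs(cf[["hill"]]),
                 top = top, bottom = bottom, emax = emax,
                 converged = !flat, residual_sd = res_sd, n = n),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "4PL fit (n = %d): EC50 = %.4g M (%.4g nM), hill = %.3g\n",
      x$n, x$ec50, x$ec50 * 1e9, x$hill))
    cat(sprintf("  top = %.4g, bottom = %.4g, residual sd = %.3g\n",
                x$top, x$bottom, x$residual_sd))
  } else {
    cat("4PL fit did not converge (flat or ill-determined curve); ",
        "no EC50 reported\n", sep = "")
  }
  invisible(x)
}

#' Competition-assay Emax: lowest marker-positive percentage reached
#'
#' The most complete depletion of the marker-positive population observed at
#' any tested dose — the minimum of the per-dose replicate means, vehicle
#' excluded.
#'
#' @param table Data frame with `dose` and `response` (percent positive).
#' @param aggregate Replicate aggregation, `"mean"` (default) or `"median"`.
#' @return The minimum per-dose aggregated response.
#' @export
emax_competition <- function(table, aggregate = c("mean", "median")) {
  dm <- .dose_means(table, aggregate)
  min(dm$response)
}

#' NanoBiT Emax: maximal vehicle-normalized luminescence fold
#'
#' The largest normalized split-luciferase signal observed at any tested dose
#' — the maximum of the per-dose replicate means, vehicle excluded. The input
#' should already be vehicle-normalized (see [normalize_to_vehicle()]).
#'
#' @inheritParams emax_competition
#' @return The maximum per-dose aggregated response.
#' @export
emax_nanobit <- function(table, aggregate = c("mean", "median")) {
  dm <- .dose_means(table, aggregate)
  max(dm$response)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `relative expression = 2^-(dCt_sample - dCt_calibrator)`, i.e. each qPCR
#' cycle saved corresponds to a doubling of template.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in the
#'   sample of interest.
#' @param ct_target_cal,ct_ref_cal The same in the calibrator condition.
#' @return List with `relative_expression`, `dct_sample`, `dct_calibrator`.
#' @export
#' @examples
#' relative_expression_ddct(20, 15, 21, 15)$relative_expression # 2
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_cal, ct_ref_cal) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_cal), is.finite(ct_ref_cal))
  dct_sample <- ct_target_sample - ct_ref_sample
  dct_cal <- ct_target_cal - ct_ref_cal
  list(relative_expression = 2^-(dct_sample - dct_cal),
       dct_sample = dct_sample, dct_calibrator = dct_cal)
}
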