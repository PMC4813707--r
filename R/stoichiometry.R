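# Bait-normalized iBAQ ratio series and windowed linear regression.
#
# For each protein, the iBAQ value in every fraction of the peak window is
# divided by the bait's iBAQ value in the same fraction. A horizontal trend
# of that ratio across the window means the protein keeps a constant molar
# ratio to the bait through both assemblies; an ascending trend means
# over-representation in the high-mass assembly (higher fractions).

#' Bait-normalized iBAQ ratio series
#'
#' For each fraction in `window` where the bait iBAQ is positive, computes
#' `ratio = iBAQ(protein) / iBAQ(bait)`. Fractions with bait iBAQ = 0 are
#' skipped (the ratio is undefined there) and counted in `n_skipped`.
#'
#' @param tab A [quant_table()].
#' @param protein_id Protein to normalize.
#' @param bait_id Bait protein identifier.
#' @param window Integer vector `c(first, last)` of fraction indices;
#'   defaults to the 26--36 peak window.
#' @return A `ratio_series`: protein_id, fractions used, ratios, n_skipped.
#' @export
ratio_series <- function(tab, protein_id, bait_id, window = c(26L, 36L)) {
  validate_quant_table(tab)
  if (window[1] < 1L || window[2] > tab$n_fractions || window[1] > window[2]) {
    abort_input("window outside [1, n_fractions]")
  }
  bi <- match(bait_id, tab$proteins$protein_id)
  if (is.na(bi)) abort_value(sprintf("bait %s absent from table", bait_id))
  pi <- match(protein_id, tab$proteins$protein_id)
  if (is.na(pi)) abort_value(sprintf("protein %s absent from table", protein_id))
  fr <- seq.int(window[1], window[2])
  bait_ibaq <- tab$ibaq[bi, fr]
  usable <- bait_ibaq > 0
  if (!any(usable)) abort_value("no usable fractions: bait iBAQ is 0 across the window")
  structure(
    list(
      protein_id = protein_id,
      fractions = fr[usable],
      ratios = unname(tab$ibaq[pi, fr][usable] / bait_ibaq[usable]),
      n_skipped = sum(!usable)
    ),
    class = "ratio_series"
  )
}

#' Pool ratio series from several replicates
#'
#' Concatenates series point-wise; fraction indices must already be in a
#' common (aligned) coordinate system, e.g. shifted by the replicate
#' alignment offset.
#'
#' @param series_list List of `ratio_series` for the same protein.
#' @return A pooled `ratio_series`.
#' @export
pool_series <- function(series_list) {
  structure(
    list(
      protein_id = series_list[[1]]$protein_id,
      fractions = unlist(lapply(series_list, `[[`, "fractions")),
      ratios = unlist(lapply(series_list, `[[`, "ratios")),
      n_skipped = sum(vapply(series_list, `[[`, numeric(1), "n_skipped"))
    ),
    class = "ratio_series"
  )
}

#' Ordinary least squares fit of a ratio series
#'
#' Regresses ratio on fraction index. The standard error and two-sided
#' p-value for H0: slope = 0 come from the t distribution with
#' `n_used - 2` degrees of freedom. The trend is classified at `alpha`
#' via [classify_trend()].
#'
#' @param series A `ratio_series` (optionally log-transformed upstream).
#' @param alpha Significance level used for the trend label.
#' @param log_ratios If `TRUE`, fit on `log(ratio)`; zero ratios are then
#'   dropped. Default `FALSE` (raw normalized iBAQ, as plotted).
#' @param drop_zeros If `TRUE`, exclude zero ratios from the fit: a zero
#'   iBAQ cell in MaxQuant output is a missing value, and a handful of
#'   dropout zeros otherwise dominate the residuals. Default `FALSE`
#'   (zeros enter the fit as stated by the ratio definition).
#' @return A `slope_result`: protein_id, slope, intercept, stderr_slope,
#'   p_value, n_used, trend.
#' @export
fit_slope <- function(series, alpha = 0.05, log_ratios = FALSE,
                      drop_zeros = FALSE) {
  x <- as.numeric(series$fractions)
  y <- as.numeric(series$ratios)
  if (drop_zeros && !log_ratios) {
    keep <- y > 0
    x <- x[keep]; y <- y[keep]
  }
  if (log_ratios) {
    keep <- y > 0
    x <- x[keep]; y <- log(y[keep])
  }
  n <- length(x)
  if (n < 3L) abort(sprintf("need >= 3 usable fractions, got %d", n),
                    "bnpcp_insufficient_data_error")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort_value("zero variance in fraction indices")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  # Numerical guard: a fitted change across the window below ~1e-8 of the
  # typical ratio magnitude is floating-point residue of a constant series
  # (0/0 t-statistics otherwise come out arbitrary), not a trend.
  y_scale <- sqrt(mean(y^2))
  if (abs(slope) * (max(x) - min(x)) < 1e-8 * y_scale) slope <- 0
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  s2 <- sum(resid^2) / (n - 2L)
  stderr_slope <- sqrt(s2 / sxx)
  t_stat <- if (stderr_slope == 0) {
    if (slope == 0) 0 else Inf * sign(slope)
  } else slope / stderr_slope
  p_value <- 2 * stats::pt(abs(t_stat), df = n - 2L, lower.tail = FALSE)
  res <- structure(
    list(protein_id = series$protein_id, slope = slope, intercept = intercept,
         stderr_slope = stderr_slope, p_value = p_value, n_used = n,
         trend = NA_character_),
    class = "slope_result"
  )
  res$trend <- classify_trend(res, alpha)
  res
}

#' Classify a fitted slope as flat, ascending or descending
#'
#' Operationalizes the visual "horizontal trend line" call as a t-test on
#' the OLS slope: flat when `p_value >= alpha`, otherwise the slope sign
#' decides ascending (over-represented at high mass) or descending.
#'
#' @param result A `slope_result` from [fit_slope()].
#' @param alpha Significance level in (0, 1).
#' @return One of `"flat"`, `"ascending"`, `"descending"`.
#' @export
classify_trend <- function(result, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort_input("alpha must be in (0, 1)")
  }
  if (result$p_value >= alpha) "flat"
  else if (result$slope > 0) "ascending"
  else "descending"
}

#' Fit slopes for many proteins
#'
#' Convenience wrapper: one [ratio_series()] + [fit_slope()] per protein.
#' Proteins with too few usable fractions are reported with NA estimates
#' and trend `"not_fitted"` rather than failing the batch. Optionally adds
#' Benjamini-Hochberg adjusted p-values across the fitted proteins (the
#' primary trend call stays on the raw p-value; `trend_bh` is reported
#' alongside).
#'
#' @param tab A [quant_table()].
#' @param bait_id Bait identifier.
#' @param protein_ids Proteins to fit (default: all except none).
#' @param window Fraction window, as in [ratio_series()].
#' @param alpha Significance level for trend calls.
#' @param bh If `TRUE`, add `p_bh` and `trend_bh` columns.
#' @param drop_zeros Passed to [fit_slope()].
#' @return data.frame with one row per protein.
#' @export
slope_table <- function(tab, bait_id, protein_ids = NULL,
                        window = c(26L, 36L), alpha = 0.05, bh = FALSE,
                        drop_zeros = FALSE) {
  ids <- protein_ids %||% tab$proteins$protein_id
  rows <- lapply(ids, function(id) {
    res <- tryCatch(fit_slope(ratio_series(tab, id, bait_id, window), alpha,
                              drop_zeros = drop_zeros),
                    bnpcp_error = function(e) NULL)
    if (is.null(res)) {
      data.frame(protein_id = id, slope = NA_real_, intercept = NA_real_,
                 stderr_slope = NA_real_, p_value = NA_real_, n_used = 0L,
                 trend = "not_fitted", stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = id, slope = res$slope, intercept = res$intercept,
                 stderr_slope = res$stderr_slope, p_value = res$p_value,
                 n_used = res$n_used, trend = res$trend, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (bh) {
    fitted <- !is.na(out$p_value)
    out$p_bh <- NA_real_
    out$p_bh[fitted] <- stats::p.adjust(out$p_value[fitted], method = "BH")
    out$trend_bh <- out$trend
    out$trend_bh[fitted & out$p_bh >= alpha] <- "flat"
  }
  out
}
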