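# Migration profiles: per-protein fraction intensities normalized to the
# protein's total intensity across the gel, apparent-MW annotation from a
# marker ladder, and integer-shift replicate alignment by the bait apex.
#
# Fraction indexing is 1-based with fraction 1 = gel bottom = low mass
# (gels are cut bottom to top); every interface in the package uses this
# orientation.

#' Build normalized migration profiles
#'
#' One profile per table record, in table order. Each protein's fraction
#' intensities are divided by the protein's total intensity across the whole
#' profile, so nonzero profiles sum to 1. Normalization uses the intensity
#' matrix; iBAQ is reserved for the stoichiometry module. Zero-total proteins
#' yield all-zero profiles flagged by `total_intensity = 0`.
#'
#' @param tab A [quant_table()].
#' @return A `migration_profiles` object: ids, gene names, a proteins x
#'   fractions matrix `values`, and per-protein `total_intensity`.
#' @export
build_profiles <- function(tab) {
  validate_quant_table(tab)
  totals <- rowSums(tab$intensity)
  values <- tab$intensity
  nz <- totals > 0
  values[nz, ] <- values[nz, , drop = FALSE] / totals[nz]
  values[!nz, ] <- 0
  structure(
    list(
      ids = tab$proteins$protein_id,
      gene_names = tab$proteins$gene_name,
      values = values,
      total_intensity = unname(totals),
      n_fractions = tab$n_fractions
    ),
    class = "migration_profiles"
  )
}

#' @export
print.migration_profiles <- function(x, ...) {
  cat(sprintf("<migration_profiles> %d proteins x %d fractions (%d zero-total)\n",
              length(x$ids), x$n_fractions, sum(x$total_intensity == 0)))
  invisible(x)
}

#' Extract one protein's profile
#' @param profiles A `migration_profiles` object.
#' @param protein_id Identifier to extract.
#' @return A `migration_profile`: protein_id, values vector, total_intensity.
#' @export
profile_of <- function(profiles, protein_id) {
  i <- match(protein_id, profiles$ids)
  if (is.na(i)) abort_value(sprintf("unknown protein_id: %s", protein_id))
  structure(
    list(
      protein_id = protein_id,
      values = unname(profiles$values[i, ]),
      total_intensity = profiles$total_intensity[i]
    ),
    class = "migration_profile"
  )
}

profile_values <- function(x) {
  if (inherits(x, "migration_profile")) x$values
  else if (is.numeric(x)) as.numeric(x)
  else abort_input("expected a migration_profile or numeric vector")
}

#' Apex fraction of a profile
#'
#' Index of the maximum profile value, ties broken toward the lowest
#' (bottom-most, lowest-mass) fraction.
#'
#' @param x A `migration_profile` or numeric vector; all-zero input is an
#'   error.
#' @return Integer fraction index (1-based).
#' @export
apex_fraction <- function(x) {
  v <- profile_values(x)
  if (all(v == 0)) abort_value("apex undefined for an all-zero profile")
  which.max(v)  # which.max takes the first maximum: the stated tie rule
}

#' Calibrate apparent molecular weight against a marker ladder
#'
#' Piecewise-linear interpolation of log10(mass) against fraction index,
#' exact at the ladder anchors. Gel migration is close to linear in log
#' mass, hence the log-space interpolation. Queries outside the ladder span
#' are refused rather than extrapolated.
#'
#' @param ladder data.frame from [read_marker_ladder()] or
#'   [default_marker_ladder()].
#' @return An `mw_calibration` function: fraction (real-valued) -> kDa.
#' @export
calibrate_mw <- function(ladder) {
  ladder <- validate_ladder(ladder)
  lo <- min(ladder$fraction)
  hi <- max(ladder$fraction)
  fun <- function(fraction) {
    if (any(fraction < lo | fraction > hi)) {
      abort_range(sprintf("fraction outside ladder span [%s, %s]", lo, hi))
    }
    10^stats::approx(ladder$fraction, log10(ladder$mass_kda), xout = fraction)$y
  }
  structure(fun, class = c("mw_calibration", "function"), span = c(lo, hi))
}

#' Align a replicate pair by the bait apex
#'
#' Gel-cutting differences preclude aligning replicates by raw fraction
#' number, so replicate B is shifted by an integer offset that superimposes
#' the bait apexes: `offset = apex_fraction(bait in A) - apex_fraction(bait
#' in B)`. The aligned copy of B is produced by shifting every profile by the
#' offset, zero-padding and truncating at the gel edges (no renormalization;
#' edge loss is reported by the unchanged totals).
#'
#' @param profiles_a,profiles_b `migration_profiles` for the two replicates.
#' @param bait_id Protein identifier of the bait; must be nonzero in both.
#' @param method `"apex"` (the definition above) or `"profile"`: choose the
#'   integer lag minimizing the Manhattan distance between the two bait
#'   profiles. Both agree on clean data; the profile search is robust to a
#'   dropped-out apex cell and is what the pipeline uses.
#' @param max_lag Largest |offset| searched by the `"profile"` method.
#' @return List with `offset` (integer) and `aligned_b` (shifted copy of
#'   `profiles_b`).
#' @export
align_replicates <- function(profiles_a, profiles_b, bait_id,
                             method = c("apex", "profile"), max_lag = 10L) {
  method <- match.arg(method)
  pa <- profile_of(profiles_a, bait_id)
  pb <- profile_of(profiles_b, bait_id)
  if (pa$total_intensity == 0 || pb$total_intensity == 0) {
    abort_value("bait profile is zero in one replicate")
  }
  offset <- if (method == "apex") {
    apex_fraction(pa) - apex_fraction(pb)
  } else {
    va <- repair_isolated_zeros(pa$values)
    vb <- repair_isolated_zeros(pb$values)
    lags <- seq.int(-max_lag, max_lag)
    cost <- vapply(lags, function(l) {
      shifted <- shift_matrix(matrix(vb, nrow = 1), l)[1, ]
      sum(abs(va - shifted))
    }, numeric(1))
    # ties: prefer the smallest shift, then the more negative one
    best <- which(cost == min(cost))
    lags[best[order(abs(lags[best]), lags[best])][1]]
  }
  aligned <- profiles_b
  aligned$values <- shift_matrix(profiles_b$values, offset)
  list(offset = as.integer(offset), aligned_b = aligned)
}

# Shift every row of m by `offset` columns (positive = rightward), zero-pad.
shift_matrix <- function(m, offset) {
  nf <- ncol(m)
  out <- matrix(0, nrow = nrow(m), ncol = nf,
                dimnames = dimnames(m))
  src <- seq_len(nf) - offset
  ok <- src >= 1 & src <= nf
  out[, which(ok)] <- m[, src[ok], drop = FALSE]
  out
}

#' Export a profile matrix as TSV
#'
#' Rows are proteins, columns fractions; with a ladder, an apparent-MW
#' header row (kDa, blank outside the ladder span) is included.
#'
#' @param profiles A `migration_profiles` object.
#' @param path Output path.
#' @param ladder Optional marker ladder for the MW header row.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, ladder = NULL) {
  m <- profiles$values
  df <- data.frame(protein_id = profiles$ids,
                   gene_name = profiles$gene_names,
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- paste0("fraction_", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ladder)) {
    calib <- calibrate_mw(ladder)
    span <- attr(calib, "span")
    f <- seq_len(ncol(m))
    kda <- rep(NA_real_, length(f))
    in_span <- f >= span[1] & f <= span[2]
    kda[in_span] <- calib(f[in_span])
    writeLines(paste(c("# apparent_mass_kda", "",
                       ifelse(is.na(kda), "", sprintf("%.1f", kda))),
                     collapse = "\t"), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
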