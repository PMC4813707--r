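# Bait peak detection and entity assignment.
#
# The bait's migration profile defines the complex entities: each detected
# peak becomes a PeakRegion (label, left/apex/right fraction bounds,
# optional apparent mass). Every profiled protein is then assigned to one,
# both, or neither entity by the share of its profile mass falling inside
# each region.

# Isolated zeros (a zero cell with nonzero cells on both sides) are
# MaxQuant-style missing values, not real absences: Bernoulli dropout
# punches single-cell holes into otherwise smooth peaks. Repair them by
# neighbor interpolation; true zero baselines (runs of zeros) are kept.
repair_isolated_zeros <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  idx <- which(v[-c(1L, n)] == 0 & v[-c(n - 1L, n)] > 0 & v[-c(1L, 2L)] > 0) + 1L
  v[idx] <- (v[idx - 1L] + v[idx + 1L]) / 2
  v
}

# Centered moving average; the window is truncated at the gel edges.
smooth_profile <- function(v, window) {
  if (window == 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Local maxima of s with plateau merging: a run of equal values flanked by
# strictly lower values (or the signal edge) is one candidate peak whose
# apex is the run's lowest index.
plateau_maxima <- function(s) {
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_lower <- i == 1L || r$values[i - 1L] < r$values[i]
    right_lower <- i == k || r$values[i + 1L] < r$values[i]
    if (left_lower && right_lower) out <- c(out, starts[i])
  }
  out
}

# Topographic prominence of the peak at index p: height minus the higher of
# the two bases, where each base is the minimum between the peak and the
# nearest strictly higher point on that side (or the signal edge).
peak_prominence <- function(s, p) {
  h <- s[p]
  base <- function(idx_seq) {
    m <- h
    for (i in idx_seq) {
      if (s[i] > h) break
      if (s[i] < m) m <- s[i]
    }
    m
  }
  left <- if (p > 1L) base(seq.int(p - 1L, 1L)) else h
  right <- if (p < length(s)) base(seq.int(p + 1L, length(s))) else h
  h - max(c(left, right)[c(left, right) < h], 0)
}

# Index of the minimum of s strictly between a and b; for a plateau of
# minima, the middle index (lower middle when even) -- the midpoint rule.
saddle_between <- function(s, a, b) {
  idx <- seq.int(a + 1L, b - 1L)
  m <- min(s[idx])
  at <- idx[s[idx] == m]
  at[ceiling(length(at) / 2)]
}

#' Detect peaks in a migration profile
#'
#' Isolated zero cells (single-fraction dropout) are repaired by neighbor
#' interpolation, the profile is smoothed with a centered moving average of
#' `smooth_window` fractions, local maxima are found (adjacent equal maxima
#' merge into one plateau peak, apex at the lowest index), and peaks whose
#' topographic prominence is below `min_prominence` times the smoothed
#' profile maximum are discarded. Each apex is then refined to the
#' raw-profile maximum of its catchment (between the flanking smoothed
#' minima). Region bounds: between two kept apexes the boundary sits at the
#' midpoint of the refined apexes (lower middle for odd separations), which
#' is insensitive to noise in the shallow inter-peak valley; outward the
#' region extends while the smoothed profile keeps falling, truncated where
#' it drops below 1% of the peak height. Regions are labeled "I", "II", ...
#' from low to high fraction index (fraction 1 = gel bottom = low mass).
#'
#' @param profile A `migration_profile` or numeric vector; must be nonzero.
#' @param min_prominence Minimum prominence as a fraction of the profile
#'   maximum (default 0.25).
#' @param smooth_window Odd moving-average width >= 1. Default 1 (no
#'   smoothing): with multiplicative noise the off-peak baseline is exactly
#'   zero, so smoothing only dilutes dropout-repaired apexes; widen for data
#'   with additive baseline noise.
#' @param calibration Optional [calibrate_mw()] function; annotates each
#'   apex with its apparent mass (NA outside the ladder span).
#' @return A `peak_regions` data.frame: label, left, apex, right,
#'   apex_mass_kda.
#' @export
detect_peaks <- function(profile, min_prominence = 0.25, smooth_window = 1L,
                         calibration = NULL) {
  v_raw <- profile_values(profile)
  if (all(v_raw == 0)) abort_value("cannot detect peaks in an all-zero profile")
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    abort_input("smooth_window must be odd and >= 1")
  }
  v <- repair_isolated_zeros(v_raw)
  s <- smooth_profile(v, as.integer(smooth_window))
  cand <- plateau_maxima(s)
  prom <- vapply(cand, function(p) peak_prominence(s, p), numeric(1))
  keep <- cand[prom >= min_prominence * max(s)]
  if (length(keep) == 0L) keep <- cand[which.max(prom)]
  keep <- sort(keep)

  n <- length(s)
  k <- length(keep)
  # refine each apex to the raw maximum of its catchment
  apexes <- vapply(seq_len(k), function(i) {
    lo <- if (i == 1L) 1L else saddle_between(s, keep[i - 1L], keep[i]) + 1L
    hi <- if (i == k) n else saddle_between(s, keep[i], keep[i + 1L])
    span <- seq.int(lo, hi)
    span[which.max(v[span])]
  }, integer(1))

  lefts <- integer(k); rights <- integer(k)
  # outward walks follow the smoothed topography from the smoothed maximum
  outward <- function(peak, dir) {
    floor_val <- 0.01 * s[peak]
    j <- peak
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > n) break
      if (s[nxt] > s[j] || s[nxt] < floor_val) break
      j <- nxt
    }
    j
  }
  for (i in seq_len(k)) {
    lefts[i] <- if (i == 1L) min(outward(keep[i], -1L), apexes[i])
                else (apexes[i - 1L] + apexes[i]) %/% 2L + 1L
    rights[i] <- if (i == k) max(outward(keep[i], 1L), apexes[i])
                 else (apexes[i] + apexes[i + 1L]) %/% 2L
  }

  mass <- rep(NA_real_, k)
  if (!is.null(calibration)) {
    span <- attr(calibration, "span")
    ok <- apexes >= span[1] & apexes <= span[2]
    if (any(ok)) mass[ok] <- calibration(apexes[ok])
  }
  structure(
    data.frame(
      label = as.character(utils::as.roman(seq_len(k))),
      left = lefts, apex = apexes, right = rights,
      apex_mass_kda = mass, stringsAsFactors = FALSE
    ),
    class = c("peak_regions", "data.frame")
  )
}

validate_regions <- function(regions) {
  if (nrow(regions) == 0L) abort_input("no regions")
  if (any(regions$left > regions$apex | regions$apex > regions$right)) {
    abort_input("region must satisfy left <= apex <= right")
  }
  o <- order(regions$apex)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$left[-1] <= regions$right[-nrow(regions)])) {
    abort_input("regions overlap")
  }
  regions
}

#' Assign a profile to complex entities
#'
#' `share_e` is the sum of the (normalized) profile values over the
#' fractions of region e; `call_e = share_e >= call_threshold`. Isolated
#' zero cells are first repaired as in [detect_peaks()] and the profile
#' renormalized, so a single dropped-out fraction does not silently shrink
#' a share. Profiles whose mass lies >= 80% outside all regions are flagged
#' `outside` (e.g. a monomer band).
#'
#' @param profile A `migration_profile` or numeric vector.
#' @param regions A `peak_regions` data.frame (non-overlapping).
#' @param call_threshold Share required to call membership, in (0, 1).
#' @return An `entity_membership`: protein_id, named `shares`, named
#'   logical `calls`, `outside_share`, `outside` flag.
#' @export
assign_entity <- function(profile, regions, call_threshold = 0.2) {
  if (call_threshold <= 0 || call_threshold >= 1) {
    abort_input("call_threshold must be in (0, 1)")
  }
  regions <- validate_regions(regions)
  v <- repair_isolated_zeros(profile_values(profile))
  if (sum(v) > 0) v <- v / sum(v)
  shares <- vapply(seq_len(nrow(regions)), function(i) {
    sum(v[seq.int(regions$left[i], min(regions$right[i], length(v)))])
  }, numeric(1))
  names(shares) <- regions$label
  calls <- shares >= call_threshold
  outside_share <- max(0, sum(v) - sum(shares))
  structure(
    list(
      protein_id = if (inherits(profile, "migration_profile")) profile$protein_id else NA_character_,
      shares = shares, calls = calls,
      outside_share = outside_share,
      outside = outside_share >= 0.8
    ),
    class = "entity_membership"
  )
}

#' Entity membership table for a whole profile set
#'
#' @param profiles A `migration_profiles` object.
#' @param regions A `peak_regions` data.frame.
#' @param call_threshold As in [assign_entity()].
#' @return data.frame: protein_id, gene_name, share_<label> and
#'   call_<label> per region, outside_share, outside. Zero-total proteins
#'   get NA shares and no calls.
#' @export
entity_assignments <- function(profiles, regions, call_threshold = 0.2) {
  regions <- validate_regions(regions)
  labs <- regions$label
  rows <- lapply(seq_along(profiles$ids), function(i) {
    base <- data.frame(protein_id = profiles$ids[i],
                       gene_name = profiles$gene_names[i],
                       stringsAsFactors = FALSE)
    if (profiles$total_intensity[i] == 0) {
      for (l in labs) { base[[paste0("share_", l)]] <- NA_real_
                        base[[paste0("call_", l)]] <- FALSE }
      base$outside_share <- NA_real_
      base$outside <- FALSE
      return(base)
    }
    em <- assign_entity(profiles$values[i, ], regions, call_threshold)
    for (l in labs) { base[[paste0("share_", l)]] <- unname(em$shares[l])
                      base[[paste0("call_", l)]] <- unname(em$calls[l]) }
    base$outside_share <- em$outside_share
    base$outside <- em$outside
    base
  })
  do.call(rbind, rows)
}

#' Join entity calls, stoichiometry trends and cluster membership
#'
#' One row per protein in the membership table; trend and co-cluster
#' columns are NA/FALSE for proteins absent from those inputs.
#'
#' @param memberships data.frame from [entity_assignments()] (possibly
#'   empty: yields an empty table with the documented header).
#' @param slopes Optional data.frame from [slope_table()].
#' @param co_cluster_members Optional character vector of bait co-cluster
#'   members.
#' @return Combined data.frame.
#' @export
entity_report <- function(memberships, slopes = NULL, co_cluster_members = NULL) {
  if (is.null(memberships) || nrow(memberships) == 0L) {
    out <- data.frame(protein_id = character(0), gene_name = character(0),
                      stringsAsFactors = FALSE)
    out$trend <- character(0)
    out$in_bait_cluster <- logical(0)
    return(out)
  }
  out <- memberships
  if (!is.null(slopes)) {
    i <- match(out$protein_id, slopes$protein_id)
    out$slope <- slopes$slope[i]
    out$p_value <- slopes$p_value[i]
    out$trend <- slopes$trend[i]
  } else {
    out$trend <- NA_character_
  }
  out$in_bait_cluster <- out$protein_id %in% (co_cluster_members %||% character(0))
  out
}
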