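#' Three-point moving median despike of one profile
#'
#' Each interior value is replaced by the median of itself and its two
#' depth neighbors; the endpoints pass through unchanged. Idempotent on its
#' own output for typical isolated spikes.
#'
#' @param x numeric vector of b_bp values ordered by depth
#' @return despiked vector of the same length
#' @export
despike <- function(x) {
  n <- length(x)
  if (n < 3) stop("despike needs at least 3 depth samples")
  out <- stats::runmed(x, k = 3, endrule = "keep")
  as.numeric(out)
}

# per-profile deep (700-750 m) reference mean; NA when no deep samples
deep_mean <- function(depth, value, zmin = 700, zmax = 750) {
  k <- depth >= zmin & depth <= zmax
  if (!any(k)) return(NA_real_)
  mean(value[k])
}

#' Deep-reference alignment of a profile set
#'
#' Each profile is shifted additively so that its mean b_bp over the
#' 700-750 m reference interval equals the fleet-wide median of per-profile
#' deep means. The additive shift preserves within-profile vertical
#' structure exactly. Profiles with no sample in 700-750 m are flagged and
#' excluded.
#'
#' @param profiles data.frame with columns `float_id`, `time`, `depth_m`
#'   and a b_bp column (default `bbp700_m.1`)
#' @param value_col name of the b_bp column
#' @return the input data.frame with the b_bp column aligned, an added
#'   `align_shift` column, and ineligible profiles dropped (count in
#'   attribute `n_excluded`)
#' @export
deep_align <- function(profiles, value_col = "bbp700_m.1") {
  key <- interaction(profiles$float_id, profiles$time, drop = TRUE)
  dm <- vapply(split(seq_len(nrow(profiles)), key), function(ii)
    deep_mean(profiles$depth_m[ii], profiles[[value_col]][ii]), 1.0)
  ok <- !is.na(dm)
  target <- median(dm[ok])
  shift <- target - dm[as.character(key)]
  keep <- !is.na(shift)
  out <- profiles[keep, , drop = FALSE]
  out[[value_col]] <- out[[value_col]] + shift[keep]
  out$align_shift <- shift[keep]
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "align_target") <- target
  out
}

# mean over the 5-20 m surface layer; requires >= 2 samples there
surface_value <- function(depth, value, zmin = 5, zmax = 20) {
  k <- depth >= zmin & depth <= zmax
  if (sum(k) < 2) return(NA_real_)
  mean(value[k])
}

#' Weekly-binned, percentile-trimmed surface series
#'
#' Per profile, the surface value is the mean over 5-20 m (profiles with
#' fewer than two samples there are skipped). Surface values are grouped
#' into consecutive 7-day bins restarting each January 1 so that years are
#' comparable in an interannual overlay; within each bin, values strictly
#' below the 5th or strictly above the 95th percentile (linear
#' interpolation) are removed, then the bin mean is reported. Empty bins
#' are omitted.
#'
#' @param profiles despiked, aligned profile data.frame
#' @param value_col name of the b_bp column
#' @return data.frame with columns `year`, `week`, `value`, `n`
#' @export
surface_weekly <- function(profiles, value_col = "bbp700_m.1") {
  key <- interaction(profiles$float_id, profiles$time, drop = TRUE)
  ii <- split(seq_len(nrow(profiles)), key)
  sv <- vapply(ii, function(i)
    surface_value(profiles$depth_m[i], profiles[[value_col]][i]), 1.0)
  tm <- as.Date(vapply(ii, function(i) profiles$time[i][1], ""))
  ok <- !is.na(sv)
  sv <- sv[ok]; tm <- tm[ok]
  year <- as.integer(format(tm, "%Y"))
  week <- (as.integer(format(tm, "%j")) - 1L) %/% 7L + 1L
  bins <- split(seq_along(sv), interaction(year, week, drop = TRUE))
  rows <- lapply(bins, function(i) {
    v <- sv[i]
    lo <- quantile(v, 0.05, names = FALSE)
    hi <- quantile(v, 0.95, names = FALSE)
    v <- v[v >= lo & v <= hi]
    if (!length(v)) return(NULL)
    data.frame(year = year[i][1], week = week[i][1],
               value = mean(v), n = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(year = integer(), week = integer(),
                      value = numeric(), n = integer()))
  out <- out[order(out$year, out$week), ]
  rownames(out) <- NULL
  out
}

#' Full QC chain: despike, deep align, weekly surface series
#'
#' Convenience wrapper applying [despike()] per profile, [deep_align()]
#' across the fleet, and [surface_weekly()].
#'
#' @param profiles raw profile data.frame
#' @param value_col name of the b_bp column
#' @return list with elements `profiles` (despiked + aligned) and `weekly`
#' @export
argo_qc_chain <- function(profiles, value_col = "bbp700_m.1") {
  key <- interaction(profiles$float_id, profiles$time, drop = TRUE)
  for (i in split(seq_len(nrow(profiles)), key)) {
    o <- order(profiles$depth_m[i])
    profiles[[value_col]][i][o] <- despike(profiles[[value_col]][i][o])
  }
  aligned <- deep_align(profiles, value_col)
  list(profiles = aligned, weekly = surface_weekly(aligned, value_col))
}
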