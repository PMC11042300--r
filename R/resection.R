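# hotspot-anchored resection profiles and tract-length medians

# pick the per-chromosome values for one strand, tolerating unstranded tracks
strand_values <- function(track, strand, chrom) {
  st <- if (is_stranded(track)) strand else "unstranded"
  track$values[[st]][[chrom]]
}

#' Extract an oriented single-side signal profile at a hotspot
#'
#' The right side of a hotspot reads the top strand left-to-right starting at
#' the hotspot midpoint; the left side reads the bottom strand leftwards and
#' is reversed, so in both cases index `d` (0-based) is the signal at distance
#' `d` bp from the midpoint, increasing away from the DSB. For unstranded
#' tracks (e.g. MNase occupancy) the single vector is read in the same
#' orientation.
#'
#' @param track A `strand_track`.
#' @param hotspot A single hotspot (one-row tibble or list with `chrom` and
#'   `midpoint`).
#' @param side `"right"` or `"left"`.
#' @param flank Profile length in bp (> 0).
#' @return Numeric vector of length `flank`; positions falling outside the
#'   chromosome are `NA` and the result carries attribute `truncated = TRUE`.
#' @export
extract_side_profile <- function(track, hotspot, side = c("right", "left"),
                                 flank = 1000) {
  side <- match.arg(side)
  if (flank <= 0) stop_resectr("`flank` must be > 0")
  chrom <- as.character(hotspot$chrom[[1]])
  lens <- layout_lengths(track$layout)
  if (!chrom %in% names(lens)) {
    stop_resectr(sprintf("hotspot chromosome %s not in track layout", chrom))
  }
  m <- as.numeric(hotspot$midpoint[[1]])
  d <- 0:(flank - 1)
  pos0 <- if (side == "right") m + d else m - d
  valid <- pos0 >= 0 & pos0 <= lens[[chrom]] - 1
  v <- rep(NA_real_, flank)
  vals <- strand_values(track, if (side == "right") "top" else "bottom", chrom)
  v[valid] <- vals[pos0[valid] + 1]
  attr(v, "truncated") <- any(!valid)
  v
}

#' Genome-average co-oriented resection profile
#'
#' Averages oriented side profiles over all hotspot sides (bottom-strand
#' profiles are reversed and combined with the top strand), then smooths with
#' a Hann window — the standard display of the global resection landscape as
#' a function of distance from hotspot midpoints.
#'
#' @param track A stranded `strand_track` of resection endpoints.
#' @param hotspots Hotspot tibble (>= 1 row).
#' @param flank Profile length in bp.
#' @param smooth_window Hann window size in bp (see [hann_smooth()]); use 0 to
#'   skip smoothing.
#' @param weight_by_heat If `TRUE`, weight hotspot sides by hotspot heat
#'   rather than equally (default equal weighting).
#' @return A tibble of class `resection_profile` with columns `distance`
#'   (0-based bp from midpoint) and `signal`.
#' @export
coorient_average <- function(track, hotspots, flank = 2000, smooth_window = 100,
                             weight_by_heat = FALSE) {
  hotspots <- as_hotspots(hotspots)
  if (!nrow(hotspots)) stop_resectr("need at least one hotspot")
  acc <- numeric(flank)
  wts <- numeric(flank)
  for (i in seq_len(nrow(hotspots))) {
    h <- hotspots[i, ]
    w <- if (weight_by_heat) h$heat else 1
    for (side in c("right", "left")) {
      p <- extract_side_profile(track, h, side, flank)
      ok <- !is.na(p)
      acc[ok] <- acc[ok] + w * p[ok]
      wts[ok] <- wts[ok] + w
    }
  }
  avg <- ifelse(wts > 0, acc / wts, NA_real_)
  if (smooth_window >= 1) avg <- hann_smooth(avg, smooth_window)
  structure(tibble(distance = 0:(flank - 1), signal = avg),
            class = c("resection_profile", "tbl_df", "tbl", "data.frame"))
}

#' Tract-length distribution at one hotspot
#'
#' Pools the oriented right (top-strand) and left (bottom-strand, reversed)
#' profiles of a hotspot into a single weighted distribution of endpoint
#' distances from the hotspot midpoint — the per-hotspot resection
#' tract-length histogram. Intended for loner hotspots (see
#' [select_loner_hotspots()]) so neighboring DSBs do not contribute.
#'
#' @param track A stranded `strand_track`.
#' @param hotspot One hotspot row.
#' @param flank Maximum distance considered, in bp (default 3 kb, matching the
#'   loner isolation criterion).
#' @return A tibble of class `resection_dist` with columns `distance` and
#'   `weight`; attribute `hotspot_id`, and `empty = TRUE` if total weight is 0.
#' @export
tract_length_distribution <- function(track, hotspot, flank = 3000) {
  r <- extract_side_profile(track, hotspot, "right", flank)
  l <- extract_side_profile(track, hotspot, "left", flank)
  w <- ifelse(is.na(r), 0, r) + ifelse(is.na(l), 0, l)
  out <- structure(tibble(distance = 0:(flank - 1), weight = w),
                   class = c("resection_dist", "tbl_df", "tbl", "data.frame"))
  attr(out, "hotspot_id") <- if ("hotspot_id" %in% names(hotspot)) hotspot$hotspot_id[[1]] else NA_character_
  attr(out, "empty") <- sum(w) <= 0
  out
}

# lower weighted median: smallest distance with cumulative weight >= total/2
weighted_median_lower <- function(distance, weight) {
  tot <- sum(weight)
  if (tot <= 0) return(NA_real_)
  distance[which(cumsum(weight) >= tot / 2)[1]]
}

apply_censor <- function(dist, censor) {
  if (is.null(censor)) return(dist)
  if (length(censor) != 2 || censor[1] < 0 || censor[2] <= censor[1]) {
    stop_resectr("`censor` must be c(min_len, max_len) with 0 <= min < max")
  }
  dist$weight[dist$distance < censor[1] | dist$distance > censor[2]] <- 0
  dist
}

#' Weighted median resection length, with and without censoring
#'
#' The median is the lower weighted median of the distance distribution: the
#' smallest distance at which cumulative weight reaches half the total. The
#' censored median first zeroes weight outside `censor = c(min_len, max_len)`;
#' the default bounds `[40, 2000]` nt exclude endpoints inside the hotspot NDR
#' (unresected or aberrant species) and cap the far tail.
#'
#' @param dist A `resection_dist` (from [tract_length_distribution()]) or any
#'   tibble with `distance` and `weight` columns.
#' @param censor Length-2 numeric `c(min_len, max_len)` in nt, or `NULL` for
#'   no censoring.
#' @return One-row tibble with `median`, `censored_median`, `total_weight`,
#'   `censored_weight`. Medians are `NA` (with a warning for the censored one)
#'   when the corresponding weight is zero.
#' @export
median_resection <- function(dist, censor = c(40, 2000)) {
  med <- weighted_median_lower(dist$distance, dist$weight)
  cdist <- apply_censor(dist, censor)
  cmed <- weighted_median_lower(cdist$distance, cdist$weight)
  if (is.na(cmed) && !is.na(med)) {
    rlang::warn("all weight censored; censored median is NA")
  }
  tibble(median = med, censored_median = cmed,
         total_weight = sum(dist$weight), censored_weight = sum(cdist$weight))
}

#' Pooled median resection length over many hotspots
#'
#' Sums the tract-length distributions position-wise and takes the weighted
#' median of the pooled distribution (pooled median, not a median of
#' per-hotspot medians). Censoring, if requested, is applied to the pooled
#' distribution.
#'
#' @param dists A single `resection_dist` or a list of them, all with the same
#'   distance grid.
#' @param censor As in [median_resection()]; the default `[40, 2000]` nt is
#'   applied unless `NULL`.
#' @return The pooled (censored) median in nt, a single number.
#' @export
pooled_median <- function(dists, censor = c(40, 2000)) {
  pooled <- pool_distributions(dists)
  if (sum(pooled$weight) <= 0) {
    stop_resectr("all distributions are empty", class = "resectr_empty_error")
  }
  pooled <- apply_censor(pooled, censor)
  weighted_median_lower(pooled$distance, pooled$weight)
}

pool_distributions <- function(dists) {
  if (is.data.frame(dists)) dists <- list(dists)
  if (!length(dists)) stop_resectr("need at least one distribution")
  nd <- vapply(dists, nrow, integer(1))
  if (length(unique(nd)) != 1) {
    stop_resectr("distributions must share the same distance grid")
  }
  w <- Reduce(`+`, lapply(dists, function(d) d$weight))
  tibble(distance = dists[[1]]$distance, weight = w)
}

#' Fraction of resection tracts shorter than a threshold
#'
#' Weight at distances strictly below `threshold`, divided by total weight —
#' e.g. the fraction of tracts shorter than 200 nt, a determinant of spore
#' viability when resection is genetically shortened.
#'
#' @param dists A `resection_dist` or list of them (pooled first).
#' @param threshold Distance threshold in nt (exclusive).
#' @return A proportion in `[0, 1]`.
#' @export
fraction_below <- function(dists, threshold) {
  pooled <- pool_distributions(dists)
  tot <- sum(pooled$weight)
  if (tot <= 0) stop_resectr("total weight is zero", class = "resectr_empty_error")
  sum(pooled$weight[pooled$distance < threshold]) / tot
}

#' Difference between two median resection lengths
#'
#' The Exo1 contribution to resection is estimated as the difference between
#' medians with and without Exo1 nuclease activity in an otherwise identical
#' background (e.g. wild type minus exo1-nd).
#'
#' @param a,b Median resection lengths in nt.
#' @return `a - b`, in nt.
#' @examples
#' median_difference(755, 354) # Exo1 contribution with Fun30 present
#' @export
median_difference <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop_resectr("both medians must be finite")
  a - b
}
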