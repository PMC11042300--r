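#' Coerce a data frame to a hotspot table
#'
#' A hotspot is a DSB-hot interval (usually a promoter nucleosome-depleted
#' region) with a relative DSB frequency ("heat"). This helper validates
#' intervals, derives `midpoint = floor((start+end)/2)` and `width`, assigns a
#' stable `hotspot_id` where absent, and sorts by chromosome and start.
#'
#' @param x Data frame with columns `chrom`, `start`, `end` and optionally
#'   `heat` (defaults to uniform) and `hotspot_id`.
#' @return A hotspot tibble with columns `hotspot_id`, `chrom`, `start`,
#'   `end`, `midpoint`, `width`, `heat` (plus any extra columns of `x`).
#' @export
as_hotspots <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    stop_resectr("hotspots need columns `chrom`, `start`, `end`")
  }
  x <- as_tibble(x)
  if (any(x$end <= x$start)) stop_resectr("hotspot intervals must satisfy start < end")
  if (!"heat" %in% names(x)) x$heat <- rep(1 / max(nrow(x), 1), nrow(x))
  if (any(x$heat < 0)) stop_resectr("hotspot heat must be >= 0")
  x$midpoint <- floor((x$start + x$end) / 2)
  x$width <- x$end - x$start
  if (!"hotspot_id" %in% names(x)) {
    x$hotspot_id <- sprintf("hs%04d", seq_len(nrow(x)))
  }
  front <- c("hotspot_id", "chrom", "start", "end", "midpoint", "width", "heat")
  x <- x[, c(front, setdiff(names(x), front))]
  dplyr::arrange(x, .data$chrom, .data$start)
}

#' Select narrow, isolated ("loner") hotspots
#'
#' Tract-length histograms are computed only at narrow hotspots with no other
#' hotspot nearby, so that signal at a given distance can be attributed to the
#' anchoring hotspot. The defaults (width < 400 bp, no neighbor within 3 kb)
#' reproduce the standard loner criterion. Separation is measured edge-to-edge
#' between hotspot intervals by default (most conservative against signal
#' bleed-in), or midpoint-to-midpoint.
#'
#' @param hotspots Hotspot tibble (see [as_hotspots()]).
#' @param max_width Maximum hotspot width in bp (exclusive). Use `Inf` to skip
#'   the width filter.
#' @param min_separation Minimum distance to any other hotspot in bp; hotspots
#'   with a neighbor closer than this are dropped (both of them).
#' @param by `"edge"` (default) or `"midpoint"` distance.
#' @return The retained subset of `hotspots`.
#' @export
select_loner_hotspots <- function(hotspots, max_width = 400,
                                  min_separation = 3000,
                                  by = c("edge", "midpoint")) {
  by <- match.arg(by)
  hotspots <- as_hotspots(hotspots)
  hotspots |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    mutate(
      gap_prev = if (by == "edge") .data$start - lag(.data$end)
                 else .data$midpoint - lag(.data$midpoint),
      gap_next = if (by == "edge") lead(.data$start) - .data$end
                 else lead(.data$midpoint) - .data$midpoint
    ) |>
    ungroup() |>
    filter(
      .data$width < max_width,
      is.na(.data$gap_prev) | .data$gap_prev >= min_separation,
      is.na(.data$gap_next) | .data$gap_next >= min_separation
    ) |>
    select(-"gap_prev", -"gap_next")
}
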