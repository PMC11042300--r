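#' Define a genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths that
#' every signal track in the package is validated against. All coordinates in
#' the package are 0-based, half-open (the bedGraph convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bp (positive).
#'
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chrI", "chrII"), c(2e5, 3e5))
#' @export
genome_layout <- function(chrom, length) {
  layout <- tibble(chrom = as.character(chrom), length = as.numeric(length))
  check_layout(layout)
  layout
}

new_strand_track <- function(layout, values, units, mask_applied) {
  structure(
    list(layout = layout, values = values, units = units,
         mask_applied = mask_applied),
    class = "strand_track"
  )
}

check_values_list <- function(vals, layout, strand) {
  lens <- layout_lengths(layout)
  if (!is.list(vals)) stop_resectr("strand values must be a named list of numeric vectors")
  missing <- setdiff(names(lens), names(vals))
  if (length(missing)) {
    stop_resectr(sprintf("strand `%s` is missing chromosomes: %s",
                         strand, paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(vals), names(lens))
  if (length(unknown)) {
    stop_resectr(sprintf("unknown chromosome(s) in strand `%s`: %s",
                         strand, paste(unknown, collapse = ", ")))
  }
  for (chr in names(lens)) {
    v <- vals[[chr]]
    if (length(v) != lens[[chr]]) {
      stop_resectr(sprintf("values for %s on strand `%s` have length %d, expected %d",
                           chr, strand, length(v), lens[[chr]]))
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_resectr(sprintf("track values must be finite and >= 0 (strand `%s`, %s)",
                           strand, chr))
    }
  }
  vals[names(lens)]
}

#' Construct a strand-specific 1-bp signal track
#'
#' The universal container for per-base genomic signal: either a top/bottom
#' strand pair (S1-seq resection endpoints: top = rightward-moving resection,
#' bottom = leftward) or a single unstranded vector (MNase occupancy, ChIP
#' coverage). Values are raw counts or reads per million (RPM).
#'
#' @param layout Genome layout from [genome_layout()].
#' @param top,bottom Named lists of per-chromosome numeric vectors (one value
#'   per bp), or `NULL`. Supply both or neither.
#' @param unstranded Named list of per-chromosome numeric vectors for an
#'   unstranded track; mutually exclusive with `top`/`bottom`.
#' @param units Unit label, typically `"counts"` or `"rpm"`.
#' @param mask_applied Whether DSB-independent/end regions have already been
#'   masked (see [apply_mask()]); required before [normalize_rpm()].
#'
#' @return An object of class `strand_track`.
#' @export
strand_track <- function(layout, top = NULL, bottom = NULL, unstranded = NULL,
                         units = "counts", mask_applied = FALSE) {
  check_layout(layout)
  stranded <- !is.null(top) || !is.null(bottom)
  if (stranded && !is.null(unstranded)) {
    stop_resectr("supply either `top`+`bottom` or `unstranded`, not both")
  }
  if (stranded) {
    if (is.null(top) || is.null(bottom)) {
      stop_resectr("a stranded track needs both `top` and `bottom`")
    }
    values <- list(top = check_values_list(top, layout, "top"),
                   bottom = check_values_list(bottom, layout, "bottom"))
  } else if (!is.null(unstranded)) {
    values <- list(unstranded = check_values_list(unstranded, layout, "unstranded"))
  } else {
    stop_resectr("no values supplied")
  }
  new_strand_track(layout, values, units, isTRUE(mask_applied))
}

#' Create an all-zero track for a layout
#'
#' @inheritParams strand_track
#' @param stranded If `TRUE` (default) create a top/bottom pair, else a single
#'   unstranded track.
#' @return A `strand_track` of zeros.
#' @export
zero_track <- function(layout, stranded = TRUE, units = "counts") {
  check_layout(layout)
  zeros <- lapply(layout_lengths(layout), numeric)
  if (stranded) {
    strand_track(layout, top = zeros, bottom = zeros, units = units)
  } else {
    strand_track(layout, unstranded = zeros, units = units)
  }
}

is_stranded <- function(track) identical(sort(names(track$values)), c("bottom", "top"))

track_strands <- function(track) names(track$values)

#' @export
print.strand_track <- function(x, ...) {
  tot <- track_total(x)
  cat(sprintf("<strand_track> %s strand(s): %s | %d chromosome(s), %s bp | units: %s | total signal: %.6g | mask_applied: %s\n",
              length(x$values), paste(track_strands(x), collapse = "/"),
              nrow(x$layout), format(sum(x$layout$length), big.mark = ","),
              x$units, tot, x$mask_applied))
  invisible(x)
}

#' Total signal in a track
#'
#' @param track A `strand_track`.
#' @return Sum of all values over all strands and chromosomes.
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(s) sum(vapply(s, sum, numeric(1))), numeric(1)))
}

# apply f(vector) -> vector to every strand/chromosome
track_map <- function(track, f) {
  track$values <- lapply(track$values, function(s) lapply(s, f))
  track
}

#' Sparse tidy view of a track
#'
#' Returns only non-zero positions (a dense per-bp tibble would usually be
#' impractically large).
#'
#' @param x A `strand_track`.
#' @param ... Unused.
#' @return Tibble with columns `strand`, `chrom`, `pos` (0-based) and `value`.
#' @export
tidy.strand_track <- function(x, ...) {
  rows <- purrr::map_dfr(track_strands(x), function(st) {
    purrr::map_dfr(names(x$values[[st]]), function(chr) {
      v <- x$values[[st]][[chr]]
      nz <- which(v != 0)
      tibble(strand = st, chrom = chr, pos = nz - 1, value = v[nz])
    })
  })
  rows
}

#' Zero out masked intervals in a track
#'
#' Masking removes chromosome ends and DSB-independent signal (for example
#' rDNA, telomere-proximal background) before normalization. Masked positions
#' are set to zero and therefore automatically drop out of the
#' reads-per-million denominator in [normalize_rpm()].
#'
#' @param track A `strand_track`.
#' @param mask Tibble with columns `chrom`, `start`, `end` (0-based,
#'   half-open), e.g. from [read_bed3()]. May have zero rows.
#' @return The masked track with `mask_applied = TRUE`.
#' @export
apply_mask <- function(track, mask) {
  lens <- layout_lengths(track$layout)
  if (nrow(mask)) {
    if (!all(mask$chrom %in% names(lens))) {
      bad <- setdiff(unique(mask$chrom), names(lens))
      stop_resectr(sprintf("mask references unknown chromosome(s): %s",
                           paste(bad, collapse = ", ")))
    }
    if (any(mask$end <= mask$start) || any(mask$start < 0) ||
        any(mask$end > lens[mask$chrom])) {
      stop_resectr("mask intervals must satisfy 0 <= start < end <= chromosome length")
    }
    for (st in track_strands(track)) {
      for (i in seq_len(nrow(mask))) {
        chr <- mask$chrom[[i]]
        track$values[[st]][[chr]][(mask$start[[i]] + 1):mask$end[[i]]] <- 0
      }
    }
  }
  track$mask_applied <- TRUE
  track
}

#' Normalize a track to reads per million
#'
#' Scales all values so the total over both strands equals 1e6. Requires that
#' masking has been applied first (possibly with an empty mask), so that masked
#' positions are excluded from the denominator ("reads per million remaining
#' mapped reads"). Idempotent on tracks already in RPM.
#'
#' @param track A masked `strand_track`.
#' @return The track in RPM units.
#' @export
normalize_rpm <- function(track) {
  if (!isTRUE(track$mask_applied)) {
    stop_resectr("apply_mask() must be called before normalize_rpm() (an empty mask is fine)",
                 class = "resectr_order_error")
  }
  tot <- track_total(track)
  if (tot <= 0) {
    stop_resectr("cannot normalize a track with zero total signal",
                 class = "resectr_normalization_error")
  }
  scale <- 1e6 / tot
  track <- track_map(track, function(v) v * scale)
  track$units <- "rpm"
  track
}

#' Average replicate tracks position-wise
#'
#' @param tracks List of `strand_track`s with identical layouts, strands, and
#'   units (replicates are averaged after RPM normalization).
#' @return A `strand_track` holding the position-wise arithmetic mean.
#' @export
average_replicates <- function(tracks) {
  if (!length(tracks)) stop_resectr("need at least one track")
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (!identical(tr$layout, ref$layout)) stop_resectr("tracks have different layouts")
    if (!identical(track_strands(tr), track_strands(ref))) {
      stop_resectr("tracks have different strand structure")
    }
    if (!identical(tr$units, ref$units)) {
      stop_resectr("tracks have mixed units; normalize before averaging",
                   class = "resectr_units_error")
    }
  }
  out <- ref
  nrep <- length(tracks)
  for (st in track_strands(ref)) {
    for (chr in names(ref$values[[st]])) {
      acc <- ref$values[[st]][[chr]]
      for (tr in tracks[-1]) acc <- acc + tr$values[[st]][[chr]]
      out$values[[st]][[chr]] <- acc / nrep
    }
  }
  out$mask_applied <- all(vapply(tracks, function(t) isTRUE(t$mask_applied), logical(1)))
  out
}

# cumulative-sum bin sums for one chromosome vector; returns tibble
bin_sum_vector <- function(v, bin_width, na_aware = FALSE) {
  len <- length(v)
  nb <- ceiling(len / bin_width)
  starts <- (seq_len(nb) - 1) * bin_width
  ends <- pmin(starts + bin_width, len)
  if (na_aware) {
    obs <- !is.na(v)
    cs <- c(0, cumsum(ifelse(obs, v, 0)))
    cn <- c(0, cumsum(obs))
    val <- cs[ends + 1] - cs[starts + 1]
    ndef <- cn[ends + 1] - cn[starts + 1]
    val[ndef == 0] <- NA_real_
  } else {
    cs <- c(0, cumsum(v))
    val <- cs[ends + 1] - cs[starts + 1]
  }
  tibble(start = starts, end = ends, value = val,
         partial = (ends - starts) < bin_width)
}

#' Sum signal in non-overlapping bins
#'
#' Tiles each chromosome from position 0 with `bin_width`-bp bins; the last,
#' possibly shorter, bin is retained and flagged `partial`. Total signal is
#' conserved. For [calibrated_track()]s the binning is missing-aware: a bin
#' sums its non-missing positions and is `NA` only if fully missing.
#'
#' @param x A `strand_track` or `calibrated_track`.
#' @param bin_width Bin width in bp (>= 1).
#' @param ... Unused.
#' @return Tibble with columns `strand` (tracks only), `chrom`, `start`,
#'   `end`, `value`, `partial`.
#' @export
bin_sum <- function(x, bin_width = 1000, ...) UseMethod("bin_sum")

#' @rdname bin_sum
#' @export
bin_sum.strand_track <- function(x, bin_width = 1000, ...) {
  if (bin_width < 1) stop_resectr("`bin_width` must be >= 1")
  purrr::map_dfr(track_strands(x), function(st) {
    purrr::map_dfr(names(x$values[[st]]), function(chr) {
      dplyr::bind_cols(tibble(strand = st, chrom = chr),
                       bin_sum_vector(x$values[[st]][[chr]], bin_width))
    })
  })
}
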