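# spike-in calibrated ChIP-seq: normalization, ratio/difference maps,
# random anchors, binned correlations

new_calibrated_track <- function(layout, values, spike_count, stage) {
  structure(list(layout = layout, values = values, spike_count = spike_count,
                 stage = stage),
            class = "calibrated_track")
}

#' Construct a calibrated ChIP coverage track
#'
#' Unstranded coverage with an explicit missing-value marker (`NA`) and a
#' processing `stage`. Usually created by [spike_normalize()] rather than
#' directly.
#'
#' @param layout Genome layout.
#' @param values Named list of per-chromosome numeric vectors (NA = missing).
#' @param spike_count Spike-in read count used as normalization divisor
#'   (`NA` for ratio/difference stages).
#' @param stage One of `"normalized_input"`, `"normalized_ip"`, `"ratio"`,
#'   `"difference"`.
#' @return A `calibrated_track`.
#' @export
calibrated_track <- function(layout, values,
                             spike_count = NA_real_,
                             stage = c("normalized_ip", "normalized_input",
                                       "ratio", "difference")) {
  stage <- match.arg(stage)
  check_layout(layout)
  lens <- layout_lengths(layout)
  if (!setequal(names(values), names(lens))) {
    stop_resectr("calibrated track values must cover exactly the layout chromosomes")
  }
  for (chr in names(lens)) {
    if (length(values[[chr]]) != lens[[chr]]) {
      stop_resectr(sprintf("values for %s have wrong length", chr))
    }
  }
  if (stage %in% c("normalized_ip", "normalized_input") &&
      (!is.finite(spike_count) || spike_count <= 0)) {
    stop_resectr("normalized stages require spike_count > 0")
  }
  new_calibrated_track(layout, values[names(lens)], spike_count, stage)
}

#' @export
print.calibrated_track <- function(x, ...) {
  nmiss <- sum(vapply(x$values, function(v) sum(is.na(v)), numeric(1)))
  cat(sprintf("<calibrated_track> stage: %s | spike_count: %s | %d chromosome(s) | missing positions: %d\n",
              x$stage, format(x$spike_count), nrow(x$layout), nmiss))
  invisible(x)
}

#' Sparse tidy view of a calibrated track
#'
#' @param x A `calibrated_track`.
#' @param ... Unused.
#' @return Tibble `chrom`, `pos` (0-based), `value` for non-zero, non-missing
#'   positions.
#' @export
tidy.calibrated_track <- function(x, ...) {
  purrr::map_dfr(names(x$values), function(chr) {
    v <- x$values[[chr]]
    nz <- which(!is.na(v) & v != 0)
    tibble(chrom = chr, pos = nz - 1, value = v[nz])
  })
}

#' Spike-in normalization of ChIP coverage
#'
#' Divides every coverage value by the number of reads uniquely mapped to the
#' spike-in genome (e.g. *S. mikatae* chromosomes when spiking *S. cerevisiae*
#' meiotic cultures). Because IP and input from the same culture share the
#' spike-in proportion, this makes coverage quantitatively comparable between
#' samples and sequencing depths.
#'
#' @param coverage An unstranded `strand_track` of raw coverage, or a named
#'   list of per-chromosome numeric vectors.
#' @param spike_count Spike-in read count (> 0).
#' @param stage `"normalized_ip"` or `"normalized_input"`.
#' @return A `calibrated_track`.
#' @export
spike_normalize <- function(coverage, spike_count,
                            stage = c("normalized_ip", "normalized_input")) {
  stage <- match.arg(stage)
  if (!is.finite(spike_count) || spike_count <= 0) {
    stop_resectr("`spike_count` must be > 0")
  }
  if (inherits(coverage, "strand_track")) {
    if (is_stranded(coverage)) stop_resectr("ChIP coverage must be unstranded")
    layout <- coverage$layout
    vals <- coverage$values$unstranded
  } else {
    stop_resectr("`coverage` must be an unstranded strand_track")
  }
  calibrated_track(layout, lapply(vals, function(v) v / spike_count),
                   spike_count = spike_count, stage = stage)
}

check_same_layout <- function(a, b) {
  if (!identical(a$layout, b$layout)) {
    stop_resectr("tracks have different layouts", class = "resectr_layout_error")
  }
}

#' Calibrated IP/input ratio map
#'
#' Divides a spike-normalized IP map by the matching spike-normalized input
#' map, position-wise. Positions whose raw input coverage (normalized value
#' times its spike count) falls below `input_floor` are marked missing and
#' excluded from all downstream averages and correlations.
#'
#' @param ip,input `calibrated_track`s at stages `normalized_ip` and
#'   `normalized_input`.
#' @param input_floor Minimum raw input coverage for the ratio to be defined
#'   (default 1 read).
#' @return A `calibrated_track` at stage `"ratio"`.
#' @export
calibrated_ratio <- function(ip, input, input_floor = 1) {
  check_same_layout(ip, input)
  if (!identical(ip$stage, "normalized_ip") ||
      !identical(input$stage, "normalized_input")) {
    stop_resectr("expected a normalized_ip and a normalized_input track",
                 class = "resectr_stage_error")
  }
  vals <- lapply(names(ip$values), function(chr) {
    i <- ip$values[[chr]]
    n <- input$values[[chr]]
    raw_input <- n * input$spike_count
    out <- i / n
    out[!is.finite(out) | is.na(raw_input) | raw_input < input_floor] <- NA_real_
    out
  })
  names(vals) <- names(ip$values)
  new_calibrated_track(ip$layout, vals, NA_real_, "ratio")
}

#' Difference between two calibrated maps
#'
#' Position-wise `a - b` for two maps at the same stage — e.g. subtracting the
#' DSB-incompetent (catalytically dead Spo11) ratio map from the DSB-competent
#' one isolates the DSB-dependent component of the ChIP signal. The result
#' may be negative; positions missing in either input are missing.
#'
#' @param a,b `calibrated_track`s at the same stage and layout.
#' @return A `calibrated_track` at stage `"difference"`.
#' @export
difference_map <- function(a, b) {
  check_same_layout(a, b)
  if (!identical(a$stage, b$stage)) {
    stop_resectr("maps must be at the same stage", class = "resectr_stage_error")
  }
  vals <- lapply(names(a$values), function(chr) a$values[[chr]] - b$values[[chr]])
  names(vals) <- names(a$values)
  new_calibrated_track(a$layout, vals, NA_real_, "difference")
}

#' @rdname bin_sum
#' @export
bin_sum.calibrated_track <- function(x, bin_width = 1000, ...) {
  if (bin_width < 1) stop_resectr("`bin_width` must be >= 1")
  purrr::map_dfr(names(x$values), function(chr) {
    dplyr::bind_cols(tibble(chrom = chr),
                     bin_sum_vector(x$values[[chr]], bin_width, na_aware = TRUE))
  })
}

#' Draw random genomic anchor positions
#'
#' Uniform positions over the unmasked genome, used as a null control for
#' feature-anchored averages.
#'
#' @param layout Genome layout.
#' @param n Number of positions.
#' @param mask Optional tibble `chrom`, `start`, `end` of excluded intervals.
#' @param seed Integer seed.
#' @return Tibble `chrom`, `position` (0-based), `orientation = "forward"`.
#' @export
random_anchors <- function(layout, n, mask = NULL, seed = 1) {
  check_layout(layout)
  lens <- layout_lengths(layout)
  # complement of the mask = allowed intervals
  allowed <- purrr::map_dfr(names(lens), function(chr) {
    len <- lens[[chr]]
    if (is.null(mask) || !nrow(mask)) return(tibble(chrom = chr, start = 0, end = len))
    msk <- mask[mask$chrom == chr, , drop = FALSE]
    if (!nrow(msk)) return(tibble(chrom = chr, start = 0, end = len))
    msk <- msk[order(msk$start), , drop = FALSE]
    starts <- c(0, msk$end)
    ends <- c(msk$start, len)
    keep <- ends > starts
    tibble(chrom = chr, start = starts[keep], end = ends[keep])
  })
  widths <- allowed$end - allowed$start
  if (!nrow(allowed) || sum(widths) <= 0) {
    stop_resectr("the whole genome is masked; no positions to sample")
  }
  withr::with_seed(check_seed(seed), {
    iv <- sample.int(nrow(allowed), n, replace = TRUE, prob = widths)
    pos <- allowed$start[iv] + floor(runif(n) * widths[iv])
    tibble(chrom = allowed$chrom[iv], position = pos, orientation = "forward")
  })
}

#' Pearson correlation of two maps summed in bins
#'
#' Sums both maps in non-overlapping windows ([bin_sum()], missing-aware) and
#' computes Pearson's r over the bins where both are defined — e.g. the
#' correlation between DSB-dependent ChIP signal and DSB (hotspot) strength.
#'
#' @param a,b `calibrated_track`s on the same layout.
#' @param bin_width Window size in bp (default 1 kb).
#' @return Pearson's r (a single number), with attribute `n_bins`. `NA` with
#'   a warning if either map has zero variance across bins.
#' @export
binned_correlation <- function(a, b, bin_width = 1000) {
  check_same_layout(a, b)
  ba <- bin_sum(a, bin_width)
  bb <- bin_sum(b, bin_width)
  ok <- !is.na(ba$value) & !is.na(bb$value)
  if (sum(ok) < 2) stop_resectr("need at least 2 bins defined in both maps")
  x <- ba$value[ok]
  y <- bb$value[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("zero variance in binned signal; correlation undefined")
    r <- NA_real_
  } else {
    r <- cor(x, y)
  }
  structure(r, n_bins = sum(ok))
}
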