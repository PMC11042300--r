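# two-species spike-in ChIP-seq simulator

#' ChIP-seq simulation parameters
#'
#' Condition presets model a chromatin-associated factor that is recruited in
#' response to DSBs: `SPO11` (DSB-competent; peaks at hotspots and at axis
#' sites), `spo11_yf` (catalytically dead; no hotspot peaks, basal axis
#' enrichment), `untagged` (no antigen; both amplitudes forced to 0).
#'
#' @param condition One of `"SPO11"`, `"spo11_yf"`, `"untagged"`.
#' @param basal Mean background coverage (Poisson rate per bp).
#' @param hotspot_amp,axis_amp Gaussian peak amplitudes at hotspot midpoints
#'   and axis sites (>= 0; `NULL` = condition default).
#' @param peak_sd Peak standard deviation in bp.
#' @param spike_reads_ip,spike_reads_input Spike-in read counts (> 0).
#' @param heat_coupling In `[0, 1]`: 0 = equal hotspot peak amplitudes, 1 =
#'   amplitudes fully proportional to hotspot heat (mean preserved).
#' @return A list of class `chip_sim_params`.
#' @export
chip_sim_params <- function(condition = c("SPO11", "spo11_yf", "untagged"),
                            basal = 5, hotspot_amp = NULL, axis_amp = NULL,
                            peak_sd = 200, spike_reads_ip = 50000,
                            spike_reads_input = 50000, heat_coupling = 1) {
  condition <- match.arg(condition)
  defaults <- switch(condition,
    SPO11    = list(h = 25, a = 15),
    spo11_yf = list(h = 0,  a = 8),
    untagged = list(h = 0,  a = 0)
  )
  p <- list(condition = condition, basal = basal,
            hotspot_amp = hotspot_amp %||% defaults$h,
            axis_amp = axis_amp %||% defaults$a,
            peak_sd = peak_sd,
            spike_reads_ip = as.integer(spike_reads_ip),
            spike_reads_input = as.integer(spike_reads_input),
            heat_coupling = check_prob(heat_coupling, "heat_coupling"))
  if (p$hotspot_amp < 0 || p$axis_amp < 0) stop_resectr("amplitudes must be >= 0")
  if (p$spike_reads_ip <= 0 || p$spike_reads_input <= 0) {
    stop_resectr("spike read counts must be > 0")
  }
  if (condition == "untagged" && (p$hotspot_amp > 0 || p$axis_amp > 0)) {
    stop_resectr("the untagged condition has no specific signal; amplitudes must be 0")
  }
  structure(p, class = "chip_sim_params")
}

# add a Gaussian bump (truncated at 4 sd) to a coverage mean vector
add_gaussian_peak <- function(v, center, amp, sd) {
  if (amp <= 0) return(v)
  half <- ceiling(4 * sd)
  idx0 <- max(0, center - half):min(length(v) - 1, center + half)
  v[idx0 + 1] <- v[idx0 + 1] + amp * exp(-(idx0 - center)^2 / (2 * sd^2))
  v
}

#' Simulate spike-in calibrated ChIP coverage
#'
#' IP coverage is Poisson counts around a mean of `basal` plus Gaussian peaks
#' at hotspot midpoints (amplitude `hotspot_amp`, optionally coupled to
#' hotspot heat) and at axis sites (`axis_amp`); input coverage is Poisson
#' around `basal` only. Spike-in read counts are returned verbatim for
#' [spike_normalize()].
#'
#' @param genome Result of [make_genome()].
#' @param hotspots Hotspot tibble.
#' @param axis_sites Tibble with `chrom`, `position` of axis-site anchors
#'   (e.g. Rec114 peak positions); may have zero rows.
#' @param params A [chip_sim_params()].
#' @param seed Integer seed.
#' @return A list with `ip` and `input` (unstranded count `strand_track`s),
#'   `spike_reads` (named vector `ip`, `input`), and `params`.
#' @export
simulate_chip <- function(genome, hotspots, axis_sites = NULL,
                          params = chip_sim_params(), seed = 1) {
  layout <- genome$layout
  hotspots <- as_hotspots(hotspots)
  lens <- layout_lengths(layout)
  heat_scale <- if (nrow(hotspots)) {
    (1 - params$heat_coupling) +
      params$heat_coupling * hotspots$heat * nrow(hotspots) / sum(hotspots$heat)
  } else {
    numeric(0)
  }
  means <- lapply(lens, function(len) rep(params$basal, len))
  for (i in seq_len(nrow(hotspots))) {
    chr <- hotspots$chrom[[i]]
    means[[chr]] <- add_gaussian_peak(means[[chr]], hotspots$midpoint[[i]],
                                      params$hotspot_amp * heat_scale[i],
                                      params$peak_sd)
  }
  if (!is.null(axis_sites) && nrow(axis_sites)) {
    bad <- setdiff(unique(axis_sites$chrom), names(lens))
    if (length(bad)) stop_resectr("axis sites on unknown chromosome(s)")
    for (i in seq_len(nrow(axis_sites))) {
      chr <- axis_sites$chrom[[i]]
      means[[chr]] <- add_gaussian_peak(means[[chr]], axis_sites$position[[i]],
                                        params$axis_amp, params$peak_sd)
    }
  }
  withr::with_seed(check_seed(seed), {
    ip <- lapply(means, function(m) as.numeric(rpois(length(m), m)))
    input <- lapply(lens, function(len) as.numeric(rpois(len, params$basal)))
    list(ip = strand_track(layout, unstranded = ip, units = "counts"),
         input = strand_track(layout, unstranded = input, units = "counts"),
         spike_reads = c(ip = params$spike_reads_ip,
                         input = params$spike_reads_input),
         params = c(unclass(params), list(seed = seed)))
  })
}
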