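# strand-polarized resection endpoint (S1-seq) simulators

#' Resection simulation parameters and mutant presets
#'
#' Two-step resection model: an MRX/Sae2 nick is placed at a uniform offset
#' from the DSB within `mrx_nick_offset_range`; when Exo1 nuclease is active,
#' digestion then proceeds outward through the flanking nucleosome array,
#' traversing each *present* nucleosome with probability `pass_prob` and
#' terminating in the proximal linker of the first non-traversed nucleosome
#' (`linker_stop = TRUE`) or at its midpoint otherwise. Presets encode the
#' genetic backgrounds: `wild_type` (Exo1 active, high traversal),
#' `exo1_nd` (nuclease-dead Exo1: nick positions only), `fun30_null`
#' (remodeler absent: lower traversal and nicking held closer to the NDR
#' edge), `fun30_exo1_nd` (both), and `sae2_null` (no nicking: unresected
#' endpoints at the DSB).
#'
#' @param preset One of `"wild_type"`, `"exo1_nd"`, `"fun30_null"`,
#'   `"fun30_exo1_nd"`, `"sae2_null"`.
#' @param mrx_nick_offset_range Length-2 bp interval for the nick offset.
#' @param exo1_active Logical; Exo1 exonuclease extension.
#' @param pass_prob Per-nucleosome traversal probability in `[0, 1]`.
#' @param linker_stop Terminate in the linker proximal to the blocking
#'   nucleosome (default `TRUE`).
#' @param depth Mean endpoints per hotspot side (> 0).
#' @return A list of class `resection_params`. Explicit arguments override
#'   the preset defaults.
#' @export
resection_params <- function(preset = c("wild_type", "exo1_nd", "fun30_null",
                                        "fun30_exo1_nd", "sae2_null"),
                             mrx_nick_offset_range = NULL, exo1_active = NULL,
                             pass_prob = NULL, linker_stop = TRUE, depth = 50) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    wild_type     = list(range = c(20, 160), exo1 = TRUE,  pass = 0.75),
    exo1_nd       = list(range = c(20, 160), exo1 = FALSE, pass = 0),
    fun30_null    = list(range = c(20, 90),  exo1 = TRUE,  pass = 0.5),
    fun30_exo1_nd = list(range = c(20, 90),  exo1 = FALSE, pass = 0),
    sae2_null     = list(range = c(0, 0),    exo1 = FALSE, pass = 0)
  )
  p <- list(preset = preset,
            mrx_nick_offset_range = mrx_nick_offset_range %||% defaults$range,
            exo1_active = exo1_active %||% defaults$exo1,
            pass_prob = pass_prob %||% defaults$pass,
            linker_stop = isTRUE(linker_stop), depth = depth)
  check_prob(p$pass_prob, "pass_prob")
  if (p$depth <= 0) stop_resectr("`depth` must be > 0")
  if (length(p$mrx_nick_offset_range) != 2 ||
      p$mrx_nick_offset_range[1] > p$mrx_nick_offset_range[2]) {
    stop_resectr("`mrx_nick_offset_range` must be c(min, max) with min <= max")
  }
  structure(p, class = "resection_params")
}

# walk one batch of endpoints outward through a present-nucleosome array;
# positions and nucleosome midpoints are in oriented coordinates (increasing
# away from the DSB)
extend_through_nucleosomes <- function(pos, nuc_mids, pass_prob, linker_stop,
                                       half_width, spacing) {
  if (!length(pos)) return(pos)
  n_pass <- if (pass_prob >= 1) rep(Inf, length(pos)) else rgeom(length(pos), 1 - pass_prob)
  out <- pos
  for (i in seq_along(pos)) {
    ahead <- nuc_mids[nuc_mids - half_width > pos[i]]
    k <- n_pass[i]
    if (k < length(ahead)) {
      blocker <- ahead[k + 1]
      out[i] <- if (linker_stop) blocker - half_width - 1 else blocker
    } else if (length(ahead)) {
      out[i] <- max(ahead) + spacing # ran out of the phased array
    }
  }
  out
}

#' Simulate strand-specific S1-seq endpoint tracks (mechanistic model)
#'
#' Allocates DSBs to hotspots by a multinomial on hotspot heat (total
#' `depth * n_hotspots` DSBs), samples each DSB position uniformly within its
#' hotspot NDR, and resects the two sides independently under
#' [resection_params()]: the right side emits a top-strand endpoint at
#' `DSB + tract`, the left side a mirror-symmetric bottom-strand endpoint.
#' Endpoints beyond the chromosome ends are clipped (excluded from the track,
#' flagged in the truth table). Nucleosome gating uses the `present`
#' nucleosomes from [simulate_nucleosomes()], so low-occupancy (open)
#' hotspots get longer tracts.
#'
#' @param genome Result of [make_genome()].
#' @param hotspots Hotspot tibble.
#' @param nucleosomes Nucleosome tibble from [simulate_nucleosomes()]
#'   (required when Exo1 is active; may be `NULL` otherwise).
#' @param params A [resection_params()].
#' @param seed Integer seed.
#' @return A list with `track` (stranded count `strand_track`), `truth`
#'   (tibble `hotspot_id`, `chrom`, `side`, `dsb`, `endpoint`, `tract`,
#'   `clipped`), `n_dsb`, and `params`.
#' @export
simulate_s1seq <- function(genome, hotspots, nucleosomes = NULL,
                           params = resection_params(), seed = 1) {
  layout <- genome$layout
  hotspots <- as_hotspots(hotspots)
  lens <- layout_lengths(layout)
  if (params$exo1_active && is.null(nucleosomes)) {
    stop_resectr("Exo1-active simulation needs a nucleosome table")
  }
  model <- if (!is.null(nucleosomes)) attr(nucleosomes, "model") else nucleosome_model()
  half <- floor(model$nuc_width / 2)
  truth <- withr::with_seed(check_seed(seed), {
    n_total <- round(params$depth * nrow(hotspots))
    alloc <- as.vector(rmultinom(1, n_total, hotspots$heat))
    purrr::map_dfr(seq_len(nrow(hotspots)), function(i) {
      nd <- alloc[i]
      if (nd == 0) return(NULL)
      h <- hotspots[i, ]
      dsb <- floor(runif(nd, h$start, h$end))
      purrr::map_dfr(c("right", "left"), function(side) {
        sgn <- if (side == "right") 1 else -1
        if (params$preset == "sae2_null") {
          ep <- dsb
        } else {
          off <- round(runif(nd, params$mrx_nick_offset_range[1],
                             params$mrx_nick_offset_range[2]))
          # oriented coordinates: distance grows away from the DSB
          pos <- sgn * dsb + off
          if (params$exo1_active) {
            nm <- nucleosomes[nucleosomes$hotspot_id == h$hotspot_id &
                                nucleosomes$side == side & nucleosomes$present, ]
            mids <- sort(sgn * nm$midpoint)
            pos <- extend_through_nucleosomes(pos, mids, params$pass_prob,
                                              params$linker_stop, half,
                                              model$spacing)
          }
          ep <- sgn * pos
        }
        tibble(hotspot_id = h$hotspot_id, chrom = h$chrom, side = side,
               dsb = dsb, endpoint = ep, tract = sgn * (ep - dsb),
               clipped = ep < 0 | ep > lens[[h$chrom]] - 1)
      })
    })
  })
  track <- endpoints_to_track(layout, truth)
  list(track = track, truth = truth, n_dsb = nrow(truth) / 2,
       params = c(unclass(params), list(seed = seed, generator = "mechanistic")))
}

# tally unclipped endpoints into a stranded count track
endpoints_to_track <- function(layout, truth) {
  lens <- layout_lengths(layout)
  top <- lapply(lens, numeric)
  bottom <- lapply(lens, numeric)
  keep <- truth[!truth$clipped, , drop = FALSE]
  for (chr in unique(keep$chrom)) {
    sub <- keep[keep$chrom == chr, ]
    top[[chr]] <- add_counts_at(top[[chr]], sub$endpoint[sub$side == "right"])
    bottom[[chr]] <- add_counts_at(bottom[[chr]], sub$endpoint[sub$side == "left"])
  }
  strand_track(layout, top = top, bottom = bottom, units = "counts")
}

#' Simulate S1-seq endpoints with log-normal tract lengths
#'
#' Distribution-level generator: each hotspot side receives exactly
#' `endpoints_per_side` endpoints whose distances from the hotspot midpoint
#' are log-normal with the requested median and log-sd — the design used for
#' median-recovery experiments, where the generative median is known exactly.
#' Right-side endpoints go to the top strand at `midpoint + L`, left-side to
#' the bottom strand at `midpoint - L`.
#'
#' @param genome Result of [make_genome()].
#' @param hotspots Hotspot tibble.
#' @param median_nt Generative median tract length in nt.
#' @param sigma Log-sd of the log-normal tract-length distribution.
#' @param endpoints_per_side Endpoints per hotspot side.
#' @param seed Integer seed.
#' @return As [simulate_s1seq()]: list with `track`, `truth`, `params`.
#' @export
simulate_s1seq_direct <- function(genome, hotspots, median_nt, sigma = 0.4,
                                  endpoints_per_side = 50, seed = 1) {
  layout <- genome$layout
  hotspots <- as_hotspots(hotspots)
  lens <- layout_lengths(layout)
  if (median_nt <= 0) stop_resectr("`median_nt` must be > 0")
  truth <- withr::with_seed(check_seed(seed), {
    purrr::map_dfr(seq_len(nrow(hotspots)), function(i) {
      h <- hotspots[i, ]
      purrr::map_dfr(c("right", "left"), function(side) {
        sgn <- if (side == "right") 1 else -1
        tract <- round(rlnorm(endpoints_per_side, log(median_nt), sigma))
        ep <- h$midpoint + sgn * tract
        tibble(hotspot_id = h$hotspot_id, chrom = h$chrom, side = side,
               dsb = h$midpoint, endpoint = ep, tract = tract,
               clipped = ep < 0 | ep > lens[[h$chrom]] - 1)
      })
    })
  })
  track <- endpoints_to_track(layout, truth)
  list(track = track, truth = truth,
       params = list(median_nt = median_nt, sigma = sigma,
                     endpoints_per_side = endpoints_per_side, seed = seed,
                     generator = "lognormal"))
}
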