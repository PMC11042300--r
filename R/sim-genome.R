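# synthetic genomes, hotspots and nucleosome arrays with known ground truth

#' Generate a synthetic genome with DSB hotspots
#'
#' Places hotspot NDR intervals on equal-length chromosomes, by default with a
#' minimum pairwise edge-to-edge separation (so the whole set satisfies the
#' loner isolation criterion), away from chromosome ends. Hotspot heats are
#' drawn from a long-tailed log-normal and normalized to sum to 1; NDR widths
#' are sampled within `ndr_width_range` (narrow, promoter-NDR-like intervals).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 10 kb).
#' @param n_hotspots Total number of hotspots (split evenly over chromosomes).
#' @param seed Integer seed; identical inputs give identical output.
#' @param min_separation Minimum edge-to-edge distance between hotspots in bp;
#'   set to 0 to disable the separation constraint.
#' @param margin Keep-out distance from chromosome ends in bp.
#' @param ndr_width_range Range of NDR widths in bp.
#' @param heat_sdlog Log-sd of the log-normal heat distribution.
#' @return A list with `layout` (a [genome_layout()]) and `hotspots` (a
#'   hotspot tibble sorted per chromosome, heats summing to 1).
#' @export
make_genome <- function(n_chrom = 1, chrom_length = 1e5, n_hotspots = 10,
                        seed = 1, min_separation = 3000, margin = 5000,
                        ndr_width_range = c(120, 300), heat_sdlog = 1) {
  if (chrom_length < 1e4) stop_resectr("`chrom_length` must be >= 10,000 bp")
  layout <- genome_layout(sprintf("chr%02d", seq_len(n_chrom)),
                          rep(chrom_length, n_chrom))
  if (n_hotspots == 0) {
    hs <- as_hotspots(tibble(chrom = character(), start = numeric(),
                             end = numeric(), heat = numeric()))
    return(list(layout = layout, hotspots = hs, seed = seed))
  }
  per_chrom <- diff(round(seq(0, n_hotspots, length.out = n_chrom + 1)))
  max_w <- max(ndr_width_range)
  hs <- withr::with_seed(check_seed(seed), {
    rows <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      avail <- chrom_length - 2 * margin
      sep <- if (min_separation > 0) min_separation + max_w else max_w
      slack <- avail - (k - 1) * sep
      if (slack <= 0) {
        stop_resectr(sprintf("chromosome too short to place %d hotspots with %d bp separation",
                             k, min_separation),
                     class = "resectr_placement_error")
      }
      u <- sort(runif(k, 0, slack))
      mids <- round(margin + u + (seq_len(k) - 1) * sep)
      w <- round(runif(k, ndr_width_range[1], ndr_width_range[2]))
      tibble(chrom = layout$chrom[ci],
             start = mids - floor(w / 2), end = mids - floor(w / 2) + w)
    })
    rows$heat <- rlnorm(nrow(rows), 0, heat_sdlog)
    rows$heat <- rows$heat / sum(rows$heat)
    rows
  })
  list(layout = layout, hotspots = as_hotspots(hs), seed = seed)
}

#' Nucleosome array model
#'
#' @param spacing Distance between neighboring nucleosome midpoints in bp
#'   (repeat length; default 165 = 147 bp core + 18 bp linker).
#' @param nuc_width Nucleosome footprint in bp (default 147).
#' @param occupancy Per-nucleosome probability that the nucleosome is present
#'   in a given cell (0-1).
#' @param fuzz Standard deviation of positional jitter in bp.
#' @return A list of class `nucleosome_model`.
#' @export
nucleosome_model <- function(spacing = 165, nuc_width = 147, occupancy = 0.85,
                             fuzz = 10) {
  check_prob(occupancy, "occupancy")
  if (spacing <= nuc_width) {
    stop_resectr("`spacing` must exceed `nuc_width` (positive linker length)")
  }
  if (fuzz < 0) stop_resectr("`fuzz` must be >= 0")
  structure(list(spacing = spacing, nuc_width = nuc_width,
                 occupancy = occupancy, fuzz = fuzz),
            class = "nucleosome_model")
}

# raised-cosine footprint kernel for one nucleosome
nucleosome_kernel <- function(nuc_width) {
  half <- floor(nuc_width / 2)
  x <- (-half):half
  cos(pi * x / nuc_width)^2
}

#' Place phased nucleosome arrays flanking hotspot NDRs
#'
#' Records the +1, +2, ... nucleosome midpoints on each side of every hotspot
#' NDR (midpoint of nucleosome i at `(i - 1/2) * spacing` beyond the NDR
#' edge, jittered by `fuzz`), samples per-nucleosome presence as
#' Bernoulli(occupancy), and builds an MNase-like unstranded occupancy track
#' as the superposition of raised-cosine footprints of the present
#' nucleosomes. A per-hotspot `occupancy` column in `hotspots` overrides the
#' model occupancy, which lets simulations plant open versus closed chromatin.
#'
#' @param genome Result of [make_genome()] (or any list with `layout`).
#' @param hotspots Hotspot tibble.
#' @param model A [nucleosome_model()].
#' @param seed Integer seed.
#' @param n_flank Number of nucleosomes recorded per hotspot side.
#' @return A list with `nucleosomes` (tibble `hotspot_id`, `chrom`, `side`,
#'   `index`, `midpoint`, `present`) and `occupancy` (unstranded
#'   `strand_track`); the model is attached as attribute `model` of the
#'   nucleosome tibble.
#' @export
simulate_nucleosomes <- function(genome, hotspots, model = nucleosome_model(),
                                 seed = 1, n_flank = 12) {
  layout <- genome$layout
  hotspots <- as_hotspots(hotspots)
  lens <- layout_lengths(layout)
  half <- floor(model$nuc_width / 2)
  nuc <- withr::with_seed(check_seed(seed), {
    grid <- tidyr::expand_grid(hs = seq_len(nrow(hotspots)),
                               side = c("right", "left"),
                               index = seq_len(n_flank))
    occ <- if ("occupancy" %in% names(hotspots)) {
      hotspots$occupancy[grid$hs]
    } else {
      rep(model$occupancy, nrow(grid))
    }
    offset <- round(model$spacing / 2) + (grid$index - 1) * model$spacing
    jitter <- if (model$fuzz > 0) round(rnorm(nrow(grid), 0, model$fuzz)) else 0
    mid <- ifelse(grid$side == "right",
                  hotspots$end[grid$hs] + offset,
                  hotspots$start[grid$hs] - offset) + jitter
    tibble(hotspot_id = hotspots$hotspot_id[grid$hs],
           chrom = hotspots$chrom[grid$hs],
           side = grid$side, index = grid$index, midpoint = mid,
           present = runif(nrow(grid)) < occ) |>
      filter(.data$midpoint - half >= 0,
             .data$midpoint + half <= lens[.data$chrom] - 1) |>
      arrange(.data$chrom, .data$midpoint)
  })
  kernel <- nucleosome_kernel(model$nuc_width)
  vals <- lapply(lens, numeric)
  present <- nuc[nuc$present, , drop = FALSE]
  for (i in seq_len(nrow(present))) {
    chr <- present$chrom[[i]]
    idx <- (present$midpoint[[i]] - half):(present$midpoint[[i]] + half) + 1
    vals[[chr]][idx] <- vals[[chr]][idx] + kernel
  }
  attr(nuc, "model") <- model
  list(nucleosomes = nuc,
       occupancy = strand_track(layout, unstranded = vals, units = "occupancy"))
}
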