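# shared in-code fixtures; everything is generated, nothing read from disk

tiny_layout <- function(len = 1000, n = 1) {
  genome_layout(sprintf("chr%d", seq_len(n)), rep(len, n))
}

# a stranded track from explicit per-chromosome vectors
track_from_vectors <- function(top, bottom, layout = NULL) {
  if (is.null(layout)) layout <- genome_layout(names(top), lengths_of(top))
  strand_track(layout, top = top, bottom = bottom)
}

lengths_of <- function(vl) vapply(vl, length, numeric(1))

random_sparse_vector <- function(len, n_nonzero = 50) {
  v <- numeric(len)
  idx <- sample.int(len, n_nonzero)
  v[idx] <- round(runif(n_nonzero, 0.5, 20), 3)
  v
}

random_stranded_track <- function(len = 5000, n_chrom = 2, n_nonzero = 80) {
  layout <- tiny_layout(len, n_chrom)
  mk <- function() setNames(lapply(layout$chrom, function(ch)
    random_sparse_vector(len, n_nonzero)), layout$chrom)
  strand_track(layout, top = mk(), bottom = mk())
}

# direct O(n*L) convolution with truncated-kernel renormalization at edges:
# the independent oracle for hann_smooth / parzen_smooth
direct_window_smooth <- function(x, kernel) {
  n <- length(x)
  h <- (length(kernel) - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    k <- kernel[j - i + h + 1]
    out[i] <- sum(x[j] * k) / sum(k)
  }
  out
}

# brute-force lower weighted median over an explicit expansion
oracle_weighted_median <- function(distance, weight) {
  tot <- sum(weight)
  cw <- 0
  for (i in seq_along(distance)) {
    cw <- cw + weight[i]
    if (cw >= tot / 2) return(distance[i])
  }
  NA_real_
}

# the shared median-recovery dataset (200 loner hotspots, 50 endpoints/side),
# built lazily once per test run
median_recovery_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(median_nt, seed = 17) {
    key <- paste0("m", median_nt, "_", seed)
    if (is.null(cache[[key]])) {
      g <- make_genome(n_chrom = 4, chrom_length = 5e5, n_hotspots = 200,
                       seed = seed)
      sim <- simulate_s1seq_direct(g, g$hotspots, median_nt = median_nt,
                                   sigma = 0.4, endpoints_per_side = 50,
                                   seed = seed)
      loners <- select_loner_hotspots(g$hotspots)
      dists <- lapply(seq_len(nrow(loners)), function(i) {
        tract_length_distribution(sim$track, loners[i, ], flank = 3000)
      })
      cache[[key]] <- list(genome = g, sim = sim, loners = loners,
                           dists = dists)
    }
    cache[[key]]
  }
})
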