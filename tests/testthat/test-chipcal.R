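# spike-in normalization, ratio/difference maps, random anchors, correlations

chip_fixture <- function(seed = 21) {
  g <- make_genome(n_chrom = 2, chrom_length = 2e5, n_hotspots = 30,
                   seed = 11)
  axis <- tibble::tibble(chrom = rep(g$layout$chrom, each = 8),
                         position = rep(round(seq(15000, 185000,
                                                  length.out = 8)), 2))
  list(genome = g, axis = axis,
       # equal planted amplitudes (25 >> 5 x Poisson sd of the basal 5),
       # so every hotspot peak is recoverable by construction
       spo11 = simulate_chip(g, g$hotspots, axis,
                             chip_sim_params("SPO11", heat_coupling = 0),
                             seed = seed),
       yf = simulate_chip(g, g$hotspots, axis,
                          chip_sim_params("spo11_yf", heat_coupling = 0),
                          seed = seed + 1))
}

test_that("spike normalization divides by the spike count", {
  withr::local_seed(2)
  layout <- tiny_layout(500)
  tr <- strand_track(layout, unstranded = list(chr1 = random_sparse_vector(500)))
  one <- spike_normalize(tr, 1, "normalized_ip")
  expect_equal(one$values$chr1, tr$values$unstranded$chr1)
  k <- spike_normalize(tr, 250, "normalized_ip")
  expect_equal(k$values$chr1, tr$values$unstranded$chr1 / 250)
  expect_error(spike_normalize(tr, 0), "spike_count")
})

test_that("calibrated ratios are 1 for ip == input and missing below the floor", {
  layout <- tiny_layout(300)
  v <- c(rep(4, 200), rep(0, 100))
  tr <- strand_track(layout, unstranded = list(chr1 = v))
  ip <- spike_normalize(tr, 100, "normalized_ip")
  input <- spike_normalize(tr, 100, "normalized_input")
  rat <- calibrated_ratio(ip, input, input_floor = 1)
  expect_equal(rat$values$chr1[1:200], rep(1, 200))
  expect_true(all(is.na(rat$values$chr1[201:300]))) # zero input: missing
  # stage checking
  expect_error(calibrated_ratio(ip, ip), class = "resectr_stage_error")
  # element-wise oracle on random coverage
  withr::local_seed(3)
  a <- pmax(rpois(300, 6), 0)
  b <- pmax(rpois(300, 6), 0)
  ra <- calibrated_ratio(
    spike_normalize(strand_track(layout, unstranded = list(chr1 = as.numeric(a))), 70, "normalized_ip"),
    spike_normalize(strand_track(layout, unstranded = list(chr1 = as.numeric(b))), 55, "normalized_input"),
    input_floor = 1)
  oracle <- ifelse(b >= 1, (a / 70) / (b / 55), NA_real_)
  expect_equal(ra$values$chr1, oracle)
})

test_that("spike-in calibration is depth invariant", {
  withr::local_seed(5)
  layout <- tiny_layout(400)
  cov <- as.numeric(rpois(400, 8))
  inp <- as.numeric(rpois(400, 8) + 1)
  mk <- function(v, spike, stage) {
    spike_normalize(strand_track(layout, unstranded = list(chr1 = v)),
                    spike, stage)
  }
  for (c_scale in c(0.5, 3, 17)) {
    r1 <- calibrated_ratio(mk(cov, 100, "normalized_ip"),
                           mk(inp, 90, "normalized_input"))
    r2 <- calibrated_ratio(mk(cov * c_scale, 100 * c_scale, "normalized_ip"),
                           mk(inp, 90, "normalized_input"))
    expect_equal(r1$values$chr1, r2$values$chr1, tolerance = 1e-12)
  }
})

test_that("difference maps subtract position-wise with missing propagation", {
  withr::local_seed(6)
  layout <- tiny_layout(200)
  mk <- function(v) calibrated_track(layout, list(chr1 = v), stage = "ratio")
  a <- mk(runif(200))
  z <- mk(numeric(200))
  expect_equal(difference_map(a, a)$values$chr1, numeric(200))
  expect_equal(difference_map(a, z)$values$chr1, a$values$chr1)
  b <- mk(runif(200))
  b$values$chr1[50] <- NA
  d <- difference_map(a, b)
  expect_equal(d$values$chr1[-50], a$values$chr1[-50] - b$values$chr1[-50])
  expect_true(is.na(d$values$chr1[50]))
  ip <- calibrated_track(layout, list(chr1 = runif(200)), 10, "normalized_ip")
  expect_error(difference_map(a, ip), class = "resectr_stage_error")
})

test_that("random anchors are seeded, mask-aware and uniform", {
  layout <- tiny_layout(10000, n = 2)
  a1 <- random_anchors(layout, 500, seed = 3)
  a2 <- random_anchors(layout, 500, seed = 3)
  expect_identical(a1, a2)
  full_mask <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0, end = 10000)
  expect_error(random_anchors(layout, 10, mask = full_mask), "masked")
  # positions avoid the mask
  half_mask <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0, end = 5000)
  am <- random_anchors(layout, 2000, mask = half_mask, seed = 4)
  expect_true(all(am$position >= 5000))
  # chi-square uniformity over 20 bins at large n
  big <- random_anchors(tiny_layout(20000), 1e5, seed = 9)
  counts <- table(cut(big$position, breaks = seq(0, 20000, by = 1000)))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 1e-4)
})

test_that("binned correlations match the textbook formula and flag degeneracy", {
  withr::local_seed(10)
  layout <- tiny_layout(5000)
  va <- runif(5000)
  mk <- function(v) calibrated_track(layout, list(chr1 = v), stage = "ratio")
  a <- mk(va)
  expect_equal(as.numeric(binned_correlation(a, a, 500)), 1)
  neg <- mk(-va + 2)
  expect_equal(as.numeric(binned_correlation(a, neg, 500)), -1)
  vb <- runif(5000)
  b <- mk(vb)
  r <- binned_correlation(a, b, 250)
  xa <- colSums(matrix(va, nrow = 250))
  xb <- colSums(matrix(vb, nrow = 250))
  oracle <- sum((xa - mean(xa)) * (xb - mean(xb))) /
    sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
  expect_equal(as.numeric(r), oracle)
  expect_warning(rc <- binned_correlation(a, mk(rep(1, 5000)), 500),
                 "zero variance")
  expect_true(is.na(rc))
})

test_that("the DSB-dependent difference map recovers planted hotspot peaks", {
  fx <- chip_fixture()
  g <- fx$genome
  ipn <- spike_normalize(fx$spo11$ip, fx$spo11$spike_reads[["ip"]], "normalized_ip")
  ipy <- spike_normalize(fx$yf$ip, fx$yf$spike_reads[["ip"]], "normalized_ip")
  dm <- parzen_smooth(difference_map(ipn, ipy), 1000)
  peak_heights <- vapply(seq_len(nrow(g$hotspots)), function(i) {
    m <- g$hotspots$midpoint[i]
    max(dm$values[[g$hotspots$chrom[i]]][(m - 300):(m + 300) + 1], na.rm = TRUE)
  }, numeric(1))
  # background: absolute smoothed difference in the feature-free end margin
  # (hotspots sit >= 5 kb from ends, axis sites >= 15 kb)
  bg <- stats::quantile(abs(dm$values[[1]][1:4000]), 0.99)
  recall <- mean(peak_heights > bg)
  expect_gte(recall, 0.95)
  # random positions show no enrichment at the anchor
  rnd <- random_anchors(g$layout, 200, seed = 12)
  avg_rnd <- anchored_average(dm, rnd, flank = 500, smooth = 0)
  avg_hot <- anchored_average(dm, tibble::tibble(chrom = g$hotspots$chrom,
                                                 position = g$hotspots$midpoint),
                              flank = 500, smooth = 0)
  expect_gt(avg_hot$value[avg_hot$offset == 0],
            10 * abs(avg_rnd$value[avg_rnd$offset == 0]))
})

test_that("binned correlation with planted heat rises with coupling", {
  g <- make_genome(n_chrom = 1, chrom_length = 2e5, n_hotspots = 25, seed = 31)
  heat_vals <- list(chr01 = numeric(2e5))
  heat_vals$chr01[g$hotspots$midpoint + 1] <- g$hotspots$heat
  heat_map <- calibrated_track(g$layout, heat_vals, stage = "ratio")
  cors <- vapply(c(0, 1), function(cpl) {
    sp <- simulate_chip(g, g$hotspots, NULL,
                        chip_sim_params("SPO11", heat_coupling = cpl), seed = 41)
    yf <- simulate_chip(g, g$hotspots, NULL,
                        chip_sim_params("spo11_yf", heat_coupling = cpl), seed = 42)
    dm <- difference_map(
      spike_normalize(sp$ip, sp$spike_reads[["ip"]], "normalized_ip"),
      spike_normalize(yf$ip, yf$spike_reads[["ip"]], "normalized_ip"))
    as.numeric(binned_correlation(dm, heat_map, 1000))
  }, numeric(1))
  expect_gt(cors[2], 0)
  expect_gt(cors[2], cors[1])
})

test_that("untagged and linearity properties of the ChIP simulator hold", {
  g <- make_genome(n_chrom = 1, chrom_length = 5e4, n_hotspots = 5, seed = 3)
  expect_error(chip_sim_params("untagged", hotspot_amp = 5), "untagged")
  un <- simulate_chip(g, g$hotspots, NULL, chip_sim_params("untagged"),
                      seed = 1)
  # IP and input share the basal-only model: means agree within noise
  expect_lt(abs(mean(un$ip$values$unstranded[[1]]) -
                  mean(un$input$values$unstranded[[1]])), 0.1)
  # doubling amplitudes and basal doubles expected coverage
  p1 <- chip_sim_params("SPO11", basal = 4, hotspot_amp = 10, axis_amp = 0)
  p2 <- chip_sim_params("SPO11", basal = 8, hotspot_amp = 20, axis_amp = 0)
  s1 <- simulate_chip(g, g$hotspots, NULL, p1, seed = 5)
  s2 <- simulate_chip(g, g$hotspots, NULL, p2, seed = 5)
  m1 <- mean(s1$ip$values$unstranded[[1]])
  m2 <- mean(s2$ip$values$unstranded[[1]])
  expect_equal(m2 / m1, 2, tolerance = 0.03)
})
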