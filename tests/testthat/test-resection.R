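# oriented profiles, loner selection, tract distributions, weighted medians

make_impulse_track <- function(len = 4000, mid = 2000, dist = 100, value = 1) {
  top <- list(chr1 = numeric(len))
  bottom <- list(chr1 = numeric(len))
  top$chr1[mid + dist + 1] <- value     # 0-based mid+dist
  bottom$chr1[mid - dist + 1] <- value
  strand_track(tiny_layout(len), top = top, bottom = bottom)
}

one_hotspot <- function(mid = 2000, width = 200, chrom = "chr1") {
  as_hotspots(tibble::tibble(chrom = chrom, start = mid - width / 2,
                             end = mid + width / 2, heat = 1))
}

test_that("side profiles read away from the DSB on the correct strand", {
  tr <- make_impulse_track(dist = 100)
  h <- one_hotspot()
  r <- extract_side_profile(tr, h, "right", 500)
  l <- extract_side_profile(tr, h, "left", 500)
  expect_equal(which(r == 1) - 1, 100) # 0-based index = distance
  expect_equal(r, l, ignore_attr = TRUE) # mirror-symmetric input
  # random track against an index-arithmetic oracle
  withr::local_seed(5)
  tr2 <- random_stranded_track(len = 4000, n_chrom = 1)
  h2 <- one_hotspot(mid = 2111)
  expect_equal(extract_side_profile(tr2, h2, "right", 300),
               tr2$values$top$chr1[2111 + 1 + 0:299], ignore_attr = TRUE)
  expect_equal(extract_side_profile(tr2, h2, "left", 300),
               tr2$values$bottom$chr1[2111 + 1 - 0:299], ignore_attr = TRUE)
  # out-of-range positions are NA and flagged
  edge <- extract_side_profile(tr2, one_hotspot(mid = 3900), "right", 300)
  expect_true(attr(edge, "truncated"))
  expect_true(all(is.na(edge[101:300])))
})

test_that("co-oriented genome averages equal a direct loop oracle", {
  withr::local_seed(6)
  tr <- random_stranded_track(len = 20000, n_chrom = 1, n_nonzero = 400)
  hs <- as_hotspots(tibble::tibble(chrom = "chr1",
                                   start = c(2000, 7000, 13000),
                                   end = c(2200, 7300, 13150)))
  flank <- 800
  prof <- coorient_average(tr, hs, flank = flank, smooth_window = 0)
  acc <- numeric(flank)
  for (i in seq_len(nrow(hs))) {
    m <- hs$midpoint[i]
    acc <- acc + tr$values$top$chr1[m + 1 + 0:(flank - 1)] +
      tr$values$bottom$chr1[m + 1 - 0:(flank - 1)]
  }
  expect_equal(prof$signal, acc / (2 * nrow(hs)))
  # all-zero tracks give a zero profile; impulses survive smoothing in place
  z <- coorient_average(zero_track(tr$layout), hs, flank = flank)
  expect_equal(z$signal, numeric(flank))
  imp <- coorient_average(make_impulse_track(dist = 500), one_hotspot(),
                          flank = 800, smooth_window = 100)
  expect_equal(which.max(imp$signal) - 1, 500)
  expect_equal(sum(imp$signal), 1, tolerance = 1e-9)
})

test_that("loner selection drops wide and crowded hotspots", {
  single <- tibble::tibble(chrom = "chr1", start = 5000, end = 5200, heat = 1)
  expect_equal(nrow(select_loner_hotspots(single)), 1)
  pair <- tibble::tibble(chrom = "chr1", start = c(5000, 6200),
                         end = c(5200, 6400), heat = c(1, 1))
  expect_equal(nrow(select_loner_hotspots(pair)), 0) # 1 kb apart: both dropped
  wide <- tibble::tibble(chrom = "chr1", start = 5000, end = 5600, heat = 1)
  expect_equal(nrow(select_loner_hotspots(wide)), 0) # width 600 >= 400
})

test_that("loner selection matches an all-pairs brute force on random layouts", {
  withr::local_seed(9)
  for (rep in 1:5) {
    hs <- as_hotspots(tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      start = sample.int(80000, 40),
      heat = 1
    ) |> dplyr::mutate(end = start + sample(100:600, 40, replace = TRUE)))
    got <- select_loner_hotspots(hs, max_width = 400, min_separation = 3000)
    keep <- vapply(seq_len(nrow(hs)), function(i) {
      if (hs$width[i] >= 400) return(FALSE)
      others <- hs[-i, ]
      others <- others[others$chrom == hs$chrom[i], ]
      if (!nrow(others)) return(TRUE)
      gaps <- pmax(others$start - hs$end[i], hs$start[i] - others$end)
      all(gaps >= 3000)
    }, logical(1))
    expect_setequal(got$hotspot_id, hs$hotspot_id[keep])
  }
})

test_that("tract distributions pool both oriented sides", {
  tr <- make_impulse_track(dist = 130)
  d <- tract_length_distribution(tr, one_hotspot(), flank = 500)
  expect_equal(d$weight[d$distance == 130], 2) # point mass, both sides
  expect_equal(sum(d$weight), 2)
  # symmetric input: pooled distribution is twice one side, same shape
  r <- extract_side_profile(tr, one_hotspot(), "right", 500)
  expect_equal(d$weight, 2 * as.numeric(r))
  z <- tract_length_distribution(zero_track(tr$layout), one_hotspot())
  expect_true(attr(z, "empty"))
})

test_that("weighted medians follow the lower-median convention and censoring", {
  uni <- tibble::tibble(distance = 1:999, weight = 1)
  expect_equal(median_resection(uni, censor = NULL)$median, 500)
  pm <- tibble::tibble(distance = 0:400, weight = as.numeric(0:400 == 130))
  expect_equal(median_resection(pm, censor = NULL)$median, 130)
  mix <- tibble::tibble(distance = c(100, 200, 900), weight = c(1, 1, 2))
  res <- median_resection(mix, censor = c(0, 800))
  expect_equal(res$median, 200)
  # censoring at 800 leaves weights {100: 1, 200: 1}; under the lower-median
  # convention (smallest distance with cumulative weight >= half the total)
  # the censored median is 100, consistent with the two-point-mass case below
  expect_equal(res$censored_median, 100)
  expect_equal(res$censored_median,
               oracle_weighted_median(c(100, 200), c(1, 1)))
  # censor bounds covering the full support equal the uncensored median
  expect_equal(median_resection(mix, censor = c(0, 1e6))$censored_median,
               median_resection(mix, censor = NULL)$median)
  # empty after censoring: flagged missing
  expect_warning(out <- median_resection(pm, censor = c(200, 300)),
                 "censored")
  expect_true(is.na(out$censored_median))
})

test_that("medians match a cumulative-sum oracle on random distributions", {
  withr::local_seed(123)
  for (i in 1:200) {
    k <- sample(2:30, 1)
    d <- tibble::tibble(distance = sort(sample.int(2000, k)),
                        weight = runif(k, 0, 5))
    expect_equal(median_resection(d, censor = NULL)$median,
                 oracle_weighted_median(d$distance, d$weight))
  }
})

test_that("pooling conserves weight and takes the pooled (not per-hotspot) median", {
  a <- tibble::tibble(distance = 0:500, weight = as.numeric(0:500 == 100))
  b <- tibble::tibble(distance = 0:500, weight = as.numeric(0:500 == 300))
  expect_equal(pooled_median(list(a, b), censor = NULL), 100) # lower median
  expect_equal(pooled_median(list(a, a), censor = NULL), 100)
  pooled <- resectr:::pool_distributions(list(a, b))
  expect_equal(sum(pooled$weight), sum(a$weight) + sum(b$weight))
  expect_error(pooled_median(list(tibble::tibble(distance = 0:10, weight = 0))),
               class = "resectr_empty_error")
})

test_that("fraction_below uses a strict threshold on pooled weight", {
  pm <- tibble::tibble(distance = 0:400, weight = as.numeric(0:400 == 130))
  expect_equal(fraction_below(pm, 200), 1)
  expect_equal(fraction_below(pm, 0), 0)
  withr::local_seed(4)
  d <- tibble::tibble(distance = 0:999, weight = runif(1000))
  expect_equal(fraction_below(d, 250),
               sum(d$weight[d$distance < 250]) / sum(d$weight))
})

test_that("median differences subtract and shifting endpoints shifts medians exactly", {
  expect_equal(median_difference(500, 500), 0)
  # monotonicity: +k shift of every endpoint moves the median by exactly +k
  withr::local_seed(31)
  w <- numeric(3000)
  w[200:900] <- runif(701)
  base <- tibble::tibble(distance = 0:2999, weight = w)
  shifted <- tibble::tibble(distance = 0:2999,
                            weight = c(numeric(150), w[1:2850]))
  for (censor in list(NULL, c(40, 2000))) {
    m0 <- median_resection(base, censor = censor)
    m1 <- median_resection(shifted, censor = censor)
    expect_equal(m1$median, m0$median + 150)
  }
})

test_that("pooled median recovers the generative median on synthetic loner data", {
  fx <- median_recovery_fixture(500, seed = 23)
  med <- pooled_median(fx$dists, censor = c(40, 2000))
  expect_true(abs(med - 500) / 500 < 0.05)
})
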