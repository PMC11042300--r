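# synthetic genomes, nucleosome arrays, endpoint tracks, tetrad generators

test_that("genomes are seeded, heats normalized, and placement errors raised", {
  g <- make_genome(1, 1e5, 10, seed = 1)
  expect_equal(nrow(g$hotspots), 10)
  expect_equal(sum(g$hotspots$heat), 1)
  expect_true(all(diff(g$hotspots$midpoint) > 0)) # sorted per chromosome
  expect_true(all(g$hotspots$start >= 0 & g$hotspots$end <= 1e5))
  g2 <- make_genome(1, 1e5, 10, seed = 1)
  expect_identical(g, g2)
  g0 <- make_genome(1, 1e5, 0, seed = 4)
  expect_equal(nrow(g0$hotspots), 0)
  expect_error(make_genome(1, 1e4, 50, seed = 1),
               class = "resectr_placement_error")
})

test_that("every simulator is bit-identical under a repeated seed", {
  g <- make_genome(1, 1e5, 6, seed = 2)
  n1 <- simulate_nucleosomes(g, g$hotspots, seed = 5)
  n2 <- simulate_nucleosomes(g, g$hotspots, seed = 5)
  expect_identical(n1, n2)
  s1 <- simulate_s1seq(g, g$hotspots, n1$nucleosomes, seed = 6)
  s2 <- simulate_s1seq(g, g$hotspots, n1$nucleosomes, seed = 6)
  expect_identical(s1, s2)
  c1 <- simulate_chip(g, g$hotspots, NULL, seed = 7)
  c2 <- simulate_chip(g, g$hotspots, NULL, seed = 7)
  expect_identical(c1, c2)
  t1 <- simulate_tetrads(tetrad_sim_params(0.2, 0.02, 16, 500, seed = 8))
  t2 <- simulate_tetrads(tetrad_sim_params(0.2, 0.02, 16, 500, seed = 8))
  expect_identical(t1, t2)
  m1 <- simulate_marked_tetrads(15, 0.02, 200, seed = 9)
  m2 <- simulate_marked_tetrads(15, 0.02, 200, seed = 9)
  expect_identical(m1, m2)
})

test_that("nucleosome occupancy tracks reflect presence sampling", {
  # wide separation so the ~2 kb nucleosome arrays of neighbors cannot overlap
  g <- make_genome(1, 1e5, 6, seed = 3, min_separation = 8000)
  # occupancy 0: flat zero track
  n0 <- simulate_nucleosomes(g, g$hotspots,
                             nucleosome_model(occupancy = 0), seed = 1)
  expect_equal(track_total(n0$occupancy), 0)
  expect_true(all(!n0$nucleosomes$present))
  # fuzz 0, occupancy 1: identical repeating peaks at exact spacing
  n1 <- simulate_nucleosomes(g, g$hotspots,
                             nucleosome_model(occupancy = 1, fuzz = 0),
                             seed = 1)
  mids <- n1$nucleosomes |>
    dplyr::filter(hotspot_id == g$hotspots$hotspot_id[1], side == "right") |>
    dplyr::pull(midpoint)
  expect_true(all(diff(mids) == 165))
  v <- n1$occupancy$values$unstranded[[1]]
  expect_equal(v[mids[1] + 1], v[mids[2] + 1])
  expect_equal(max(v), 1, tolerance = 1e-9) # isolated cos^2 peaks, height 1
  # occupancy 0.5 at large n: mean peak height approx half of occupancy-1
  gm <- make_genome(2, 5e5, 80, seed = 6)
  nh <- simulate_nucleosomes(gm, gm$hotspots,
                             nucleosome_model(occupancy = 0.5, fuzz = 0),
                             seed = 2)
  frac_present <- mean(nh$nucleosomes$present)
  se3 <- 3 * sqrt(0.25 / nrow(nh$nucleosomes))
  expect_lt(abs(frac_present - 0.5), se3)
  peak_mean <- mean(nh$occupancy$values$unstranded[[1]][nh$nucleosomes$midpoint[
    nh$nucleosomes$chrom == "chr01"] + 1])
  expect_lt(abs(peak_mean - 0.5), 0.1)
})

test_that("unresected and nick-only presets bound tract lengths by construction", {
  g <- make_genome(1, 1e5, 6, seed = 4)
  nuc <- simulate_nucleosomes(g, g$hotspots, seed = 1)
  sae2 <- simulate_s1seq(g, g$hotspots, nuc$nucleosomes,
                         resection_params("sae2_null", depth = 30), seed = 2)
  expect_true(all(sae2$truth$tract == 0))
  expect_true(all(sae2$truth$endpoint == sae2$truth$dsb))
  nick <- simulate_s1seq(g, g$hotspots, nuc$nucleosomes,
                         resection_params("exo1_nd", depth = 30), seed = 3)
  rng <- resection_params("exo1_nd")$mrx_nick_offset_range
  expect_true(all(nick$truth$tract >= rng[1] & nick$truth$tract <= rng[2]))
})

test_that("endpoint totals are conserved and clipped endpoints excluded", {
  g <- make_genome(1, 1e5, 6, seed = 5)
  nuc <- simulate_nucleosomes(g, g$hotspots, seed = 2)
  sim <- simulate_s1seq(g, g$hotspots, nuc$nucleosomes,
                        resection_params("wild_type", depth = 40), seed = 6)
  expect_equal(track_total(sim$track),
               2 * sim$n_dsb - sum(sim$truth$clipped))
})

test_that("mean tract extension beyond the first nucleosome follows the geometric law", {
  # single central hotspot, full occupancy, no jitter, q = 0.5
  g <- make_genome(1, 1e5, 1, seed = 7)
  nuc <- simulate_nucleosomes(g, g$hotspots,
                              nucleosome_model(occupancy = 1, fuzz = 0),
                              seed = 1, n_flank = 30)
  q <- 0.5
  # keep the nick inside the NDR so every tract meets the +1 nucleosome first
  sim <- simulate_s1seq(g, g$hotspots, nuc$nucleosomes,
                        resection_params("wild_type", pass_prob = q,
                                         mrx_nick_offset_range = c(0, 5),
                                         depth = 2e4), seed = 8)
  model <- attr(nuc$nucleosomes, "model")
  half <- floor(model$nuc_width / 2)
  # oriented endpoint of a tract blocked at the first (+1) nucleosome
  per_side <- nuc$nucleosomes |>
    dplyr::group_by(side) |>
    dplyr::summarise(first = if (side[1] == "right") min(midpoint) else max(midpoint))
  ext <- vapply(c("right", "left"), function(sd) {
    first_mid <- per_side$first[per_side$side == sd]
    ep <- sim$truth$endpoint[sim$truth$side == sd]
    base <- if (sd == "right") first_mid - half - 1 else first_mid + half + 1
    mean(abs(ep - base))
  }, numeric(1))
  s <- model$spacing
  expected <- s * q / (1 - q)
  se3 <- 3 * s * sqrt(q) / (1 - q) / sqrt(2e4)
  expect_lt(abs(mean(ext) - expected), se3 + 2)
})

test_that("a symmetric model gives strand-symmetric distance distributions", {
  g <- make_genome(2, 3e5, 40, seed = 8)
  sim <- simulate_s1seq_direct(g, g$hotspots, median_nt = 400, sigma = 0.5,
                               endpoints_per_side = 125, seed = 9)
  right <- sim$truth$tract[sim$truth$side == "right"]
  left <- sim$truth$tract[sim$truth$side == "left"]
  expect_equal(length(right), 5000)
  ks <- suppressWarnings(stats::ks.test(right, left))
  expect_gt(ks$p.value, 0.001)
})

test_that("tetrad class frequencies converge to the closed-form probabilities", {
  params <- tetrad_sim_params(0.24, 0.04, 16, n_tetrads = 1e5, seed = 10)
  sim <- simulate_tetrads(params)
  expected <- expected_class_probs(0.24, 0.04, 16)$prob
  freq <- sim$counts$count / params$n_tetrads
  se3 <- 3 * sqrt(expected * (1 - expected) / params$n_tetrads)
  expect_true(all(abs(freq - expected) <= se3 + 1e-9))
  # degenerate corners
  all4 <- simulate_tetrads(tetrad_sim_params(0, 0, 16, 200, seed = 1))
  expect_equal(all4$counts$count, c(200, 0, 0, 0, 0))
  all2 <- simulate_tetrads(tetrad_sim_params(0, 1, 16, 200, seed = 1))
  expect_equal(all2$counts$count, c(0, 0, 200, 0, 0))
})

test_that("marked-tetrad simulation round-trips distance and NDJ frequency", {
  expect_equal(unique(simulate_marked_tetrads(0, 0, 100, seed = 1)$true_class),
               "PD")
  expect_equal(unique(simulate_marked_tetrads(20, 1, 100, seed = 2)$true_class),
               "NDJ")
  expect_error(simulate_marked_tetrads(90, 0, 10, seed = 1),
               class = "resectr_parameter_error")
  mt <- simulate_marked_tetrads(20, ndj_rate = 0.02, n = 2e4, seed = 3)
  cl <- classify_tetrads(mt)
  # the generator's labels agree with the classifier (round trip)
  expect_equal(cl$class, mt$true_class[mt$spore == 1])
  cc <- tetrad_class_counts(cl)
  expect_lt(abs(perkins_distance(cc)$cM - 20), 1)
  ndj_hat <- ndj_frequency(cc) / 100
  se3 <- 3 * sqrt(0.02 * 0.98 / 2e4)
  expect_lt(abs(ndj_hat - 0.02), se3)
})

test_that("simulated datasets round-trip through the on-disk formats", {
  g <- make_genome(1, 5e4, 4, seed = 11)
  sim <- simulate_s1seq_direct(g, g$hotspots, 300, endpoints_per_side = 20,
                               seed = 12)
  d <- withr::local_tempdir()
  paths <- write_s1seq_dataset(sim, g$hotspots, d)
  expect_true(all(file.exists(paths)))
  layout <- read_layout(paths[["layout"]])
  expect_equal(layout, g$layout)
  back <- read_track(layout, top = paths[["plus"]], bottom = paths[["minus"]])
  expect_equal(back$values, sim$track$values)
  hs <- read_hotspots(paths[["hotspots"]])
  expect_equal(hs$midpoint, g$hotspots$midpoint)
  meta <- yaml::read_yaml(paths[["params"]])
  expect_equal(meta$median_nt, 300)
  expect_equal(meta$seed, 12)
  tc <- tetrad_counts(60, 20, 10, 6, 4)
  f <- file.path(d, "tetrads.tsv")
  write_tetrad_counts(tc, f)
  expect_equal(read_tetrad_counts(f), tc)
})
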