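# tetrad viability and fluorescent-marker tetrad simulators

#' Tetrad simulation parameters
#'
#' @param r Per-spore random-death (RSD) probability.
#' @param d Per-chromosome MI-NDJ probability.
#' @param C Number of chromosomes (16 for *S. cerevisiae*).
#' @param n_tetrads Number of tetrads to simulate.
#' @param seed Integer seed.
#' @return A list of class `tetrad_sim_params`.
#' @export
tetrad_sim_params <- function(r, d, C = 16, n_tetrads = 1000, seed = 1) {
  check_prob(r, "r")
  check_prob(d, "d")
  if (C < 1) stop_resectr("`C` must be >= 1")
  if (n_tetrads < 1) stop_resectr("`n_tetrads` must be >= 1")
  structure(list(r = r, d = d, C = C, n_tetrads = as.integer(n_tetrads),
                 seed = seed),
            class = "tetrad_sim_params")
}

#' Simulate tetrad viability classes
#'
#' Per tetrad: with probability `1 - (1-d)^C` a meiosis-I nondisjunction
#' event kills exactly two spores (the nullisomic pair; disomes are viable;
#' multiple NDJ events in one tetrad still kill only that pair); every
#' remaining spore then dies independently with probability `r`. Counts are
#' tallied into viable-spore classes 4..0.
#'
#' @param params A [tetrad_sim_params()].
#' @return A list with `counts` (tibble as [tetrad_counts()]) and `tetrads`
#'   (per-tetrad tibble `tetrad`, `ndj`, `n_viable`).
#' @export
simulate_tetrads <- function(params) {
  p_ndj <- 1 - (1 - params$d)^params$C
  tetrads <- withr::with_seed(check_seed(params$seed), {
    ndj <- runif(params$n_tetrads) < p_ndj
    at_risk <- ifelse(ndj, 2L, 4L)
    survivors <- rbinom(params$n_tetrads, at_risk, 1 - params$r)
    tibble(tetrad = seq_len(params$n_tetrads), ndj = ndj,
           n_viable = as.integer(survivors))
  })
  tab <- table(factor(tetrads$n_viable, levels = 4:0))
  list(counts = tibble(n_viable = 4:0, count = as.integer(tab)),
       tetrads = tetrads)
}

# Papazian no-chromatid-interference tetrad-class frequencies for a Poisson
# mean of m exchanges in the interval: TT = 2/3 (1 - exp(-3m/2)),
# PD - NPD = exp(-m)
papazian_class_freqs <- function(m) {
  tt <- 2 / 3 * (1 - exp(-3 * m / 2))
  npd <- (1 - tt - exp(-m)) / 2
  c(PD = 1 - tt - npd, NPD = npd, TT = tt)
}

perkins_of_m <- function(m) {
  f <- papazian_class_freqs(m)
  100 * (f[["TT"]] / 2 + 3 * f[["NPD"]])
}

# invert the Perkins estimator under the Papazian model; sup over m is
# 100*(1/3 + 1/2) = 83.33 cM
m_for_distance <- function(distance_cM) {
  if (distance_cM < 0) stop_resectr("`distance_cM` must be >= 0")
  if (distance_cM == 0) return(0)
  upper <- 50
  if (distance_cM >= perkins_of_m(upper)) {
    stop_resectr("`distance_cM` too large for the tetrad-class model (max ~83.3 cM)",
                 class = "resectr_parameter_error")
  }
  uniroot(function(m) perkins_of_m(m) - distance_cM, c(0, upper),
          tol = 1e-10)$root
}

#' Simulate fluorescent-marker tetrad patterns
#'
#' Generates spore-autonomous two-marker fluorescence patterns for a cross
#' heterozygous for a centromere-linked marker and a distal marker at the
#' requested genetic distance. Non-NDJ tetrads are assigned PD/NPD/TT with
#' the class frequencies of a no-interference (Poisson-exchange) model whose
#' Perkins estimate equals `distance_cM`; NDJ tetrads emit the diagnostic
#' pattern of two viable disomic spores carrying the CEN marker (and both
#' homologs, hence both markers) and two dead marker-less nullisomes.
#'
#' @param distance_cM Genetic distance between the markers in centimorgans
#'   (must be below the ~83.3 cM ceiling of the class model).
#' @param ndj_rate Probability that a tetrad is an MI-NDJ tetrad.
#' @param n Number of tetrads.
#' @param seed Integer seed.
#' @return A tibble with one row per spore: `tetrad`, `spore`, `viable`,
#'   `cen_marker`, `distal_marker`, `true_class` — the input format of
#'   [classify_tetrads()].
#' @export
simulate_marked_tetrads <- function(distance_cM, ndj_rate = 0, n = 1000,
                                    seed = 1) {
  check_prob(ndj_rate, "ndj_rate")
  freqs <- papazian_class_freqs(m_for_distance(distance_cM))
  spore_patterns <- list(
    # columns: cen_marker, distal_marker for the 4 spores
    PD  = cbind(cen = c(TRUE, TRUE, FALSE, FALSE),
                distal = c(TRUE, TRUE, FALSE, FALSE)),
    NPD = cbind(cen = c(TRUE, TRUE, FALSE, FALSE),
                distal = c(FALSE, FALSE, TRUE, TRUE)),
    TT  = cbind(cen = c(TRUE, TRUE, FALSE, FALSE),
                distal = c(TRUE, FALSE, TRUE, FALSE)),
    NDJ = cbind(cen = c(TRUE, TRUE, FALSE, FALSE),
                distal = c(TRUE, TRUE, FALSE, FALSE))
  )
  withr::with_seed(check_seed(seed), {
    cls <- ifelse(runif(n) < ndj_rate, "NDJ",
                  sample(names(freqs), n, replace = TRUE, prob = freqs))
    purrr::map_dfr(seq_len(n), function(i) {
      pat <- spore_patterns[[cls[i]]]
      tibble(tetrad = i, spore = 1:4,
             viable = if (cls[i] == "NDJ") c(TRUE, TRUE, FALSE, FALSE) else rep(TRUE, 4),
             cen_marker = pat[, "cen"], distal_marker = pat[, "distal"],
             true_class = cls[i])
    })
  })
}
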