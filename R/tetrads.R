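# tetrad viability mixture model (random spore death + MI nondisjunction),
# grid-search fitting, Perkins distances and NDJ frequencies

#' Tetrad viability-class tallies
#'
#' @param n4,n3,n2,n1,n0 Tetrad counts with 4..0 viable spores.
#' @return Tibble with columns `n_viable` (4..0) and `count`.
#' @export
tetrad_counts <- function(n4, n3, n2, n1, n0) {
  as_tetrad_counts(tibble(n_viable = 4:0, count = c(n4, n3, n2, n1, n0)))
}

#' @rdname tetrad_counts
#' @param x A data frame with columns `n_viable` and `count`, or a numeric
#'   vector of 5 counts ordered class 4 to 0.
#' @export
as_tetrad_counts <- function(x) {
  if (is.numeric(x) && length(x) == 5) {
    x <- tibble(n_viable = 4:0, count = as.numeric(x))
  }
  if (!all(c("n_viable", "count") %in% names(x))) {
    stop_resectr("tetrad counts need columns `n_viable` and `count`")
  }
  if (!setequal(x$n_viable, 0:4)) stop_resectr("`n_viable` must cover classes 4..0")
  x <- as_tibble(x)[match(4:0, x$n_viable), c("n_viable", "count")]
  if (any(x$count < 0)) stop_resectr("counts must be >= 0")
  if (sum(x$count) <= 0) stop_resectr("total tetrad count must be > 0")
  x
}

# fast internal: probabilities over classes 4..0 as a length-5 vector
class_probs_vec <- function(r, d, C) {
  p_ndj <- 1 - (1 - d)^C
  no_ndj <- dbinom(4:0, 4, 1 - r)
  ndj <- c(0, 0, dbinom(2:0, 2, 1 - r))
  (1 - p_ndj) * no_ndj + p_ndj * ndj
}

#' Expected tetrad viability-class probabilities
#'
#' Mixture model of spore death: with probability `1 - (1-d)^C` a tetrad
#' suffers meiosis-I nondisjunction (MI-NDJ) of at least one of its `C`
#' chromosomes, which kills exactly the two nullisomic spores (disomes are
#' viable); every surviving spore then dies independently with the random
#' spore death (RSD) probability `r`. No-NDJ tetrads contribute a
#' Binomial(4, 1-r) across classes 4..0; NDJ tetrads a Binomial(2, 1-r)
#' across classes 2..0.
#'
#' @param r Per-spore random-death probability.
#' @param d Per-chromosome MI-NDJ probability.
#' @param C Number of chromosomes (16 for *S. cerevisiae*).
#' @return Tibble with columns `n_viable` (4..0) and `prob` (sums to 1).
#' @examples
#' expected_class_probs(0.5, 0, 16) # pure binomial: 1/16, 1/4, 3/8, 1/4, 1/16
#' @export
expected_class_probs <- function(r, d, C = 16) {
  check_prob(r, "r")
  check_prob(d, "d")
  if (C < 1) stop_resectr("`C` must be >= 1")
  tibble(n_viable = 4:0, prob = class_probs_vec(r, d, C))
}

#' Configuration for the tetrad viability grid fit
#'
#' Defaults follow the published algorithm defaults (`ndint = 500`,
#' `rsdint = 500`, `chr = 16`, `anid = 0.035`, `ndm = 10`, RSD bounds 0–0.8,
#' NDJ bounds 0–0.017). `anid` and `ndm` are accepted and recorded for
#' compatibility but are not used by the model implemented here (their
#' semantics are not defined by the model; see the methods vignette). Note
#' that strongly NDJ-elevated mutants need `maxnd` raised above the default
#' so that the grid covers the truth — bounds are fully configurable.
#'
#' @param ndint,rsdint Grid resolutions (number of grid points, >= 2) for the
#'   NDJ and RSD axes.
#' @param chr Chromosome count `C`.
#' @param minnd,maxnd,minrsd,maxrsd Parameter bounds in `[0, 1]`.
#' @param objective `"sse"` (sum of squared differences between expected and
#'   observed class frequencies; default) or `"multinomial_loglik"`.
#' @param anid,ndm Pass-through parameters, recorded but unused.
#' @return A list of class `tetfit_config`.
#' @export
tetfit_config <- function(ndint = 500, rsdint = 500, chr = 16,
                          minnd = 0, maxnd = 0.017, minrsd = 0, maxrsd = 0.8,
                          objective = c("sse", "multinomial_loglik"),
                          anid = 0.035, ndm = 10) {
  objective <- match.arg(objective)
  if (ndint < 2 || rsdint < 2) stop_resectr("grid resolutions must be >= 2")
  if (!(0 <= minnd && minnd < maxnd && maxnd <= 1) ||
      !(0 <= minrsd && minrsd < maxrsd && maxrsd <= 1)) {
    stop_resectr("bounds must be ordered and within [0, 1]")
  }
  structure(list(ndint = ndint, rsdint = rsdint, chr = chr,
                 minnd = minnd, maxnd = maxnd, minrsd = minrsd, maxrsd = maxrsd,
                 objective = objective, anid = anid, ndm = ndm),
            class = "tetfit_config")
}

#' Decompose spore death into RSD and MI-NDJ by grid search
#'
#' Exhaustively fits the [expected_class_probs()] mixture to an observed
#' tetrad viability-class distribution over a `rsdint` x `ndint` grid of
#' (RSD rate r, per-chromosome MI-NDJ rate d). The default objective is the
#' sum of squared differences between expected and observed class
#' frequencies; a multinomial log-likelihood objective is available. Ties are
#' broken toward smaller d, then smaller r. Per-spore death shares are the
#' closed forms `ndj_death_share = P_ndj/2` and
#' `rsd_death_share = r (1 - P_ndj/2)` with `P_ndj = 1 - (1-d)^C`.
#'
#' @param observed Tetrad counts (see [tetrad_counts()]).
#' @param config A [tetfit_config()].
#' @return An object of class `tetfit` with elements `r_hat`, `d_hat`,
#'   `p_ndj`, `rsd_death_share`, `ndj_death_share`, `expected_viability`,
#'   `observed_viability`, `classes` (tibble of observed and fitted class
#'   frequencies), `objective`, `objective_value`, `grid_step` and `config`.
#' @export
tetfit <- function(observed, config = tetfit_config()) {
  observed <- as_tetrad_counts(observed)
  n <- sum(observed$count)
  freq <- observed$count / n
  r_grid <- seq(config$minrsd, config$maxrsd, length.out = config$rsdint)
  d_grid <- seq(config$minnd, config$maxnd, length.out = config$ndint)
  # class probabilities factorize into an r part (binomial survivor counts)
  # and a d part (NDJ mixture weight)
  b4 <- t(vapply(r_grid, function(r) dbinom(4:0, 4, 1 - r), numeric(5)))
  b2 <- t(vapply(r_grid, function(r) c(0, 0, dbinom(2:0, 2, 1 - r)), numeric(5)))
  obj <- matrix(NA_real_, nrow = config$rsdint, ncol = config$ndint)
  for (j in seq_along(d_grid)) {
    p_ndj <- 1 - (1 - d_grid[j])^config$chr
    e <- (1 - p_ndj) * b4 + p_ndj * b2
    if (config$objective == "sse") {
      obj[, j] <- rowSums(sweep(e, 2, freq, "-")^2)
    } else {
      ll <- e
      ll[] <- ifelse(e > 0, log(e), ifelse(rep(observed$count, each = nrow(e)) > 0, -Inf, 0))
      obj[, j] <- -as.vector(ll %*% observed$count)
    }
  }
  best <- min(obj)
  cand <- which(obj == best, arr.ind = TRUE)
  # ties: smallest d, then smallest r
  cand <- cand[order(cand[, "col"], cand[, "row"]), , drop = FALSE]
  ri <- cand[1, "row"]
  di <- cand[1, "col"]
  r_hat <- r_grid[ri]
  d_hat <- d_grid[di]
  p_ndj <- 1 - (1 - d_hat)^config$chr
  fitted <- class_probs_vec(r_hat, d_hat, config$chr)
  classes <- tibble(n_viable = 4:0, observed = freq, fitted = fitted)
  structure(list(
    r_hat = r_hat, d_hat = d_hat, p_ndj = p_ndj,
    ndj_death_share = 0.5 * p_ndj,
    rsd_death_share = r_hat * (1 - 0.5 * p_ndj),
    expected_viability = 100 * (1 - r_hat) * (1 - 0.5 * p_ndj),
    observed_viability = spore_viability(observed),
    classes = classes, n = n,
    objective = config$objective, objective_value = best,
    grid_step = c(r = diff(r_grid[1:2]), d = diff(d_grid[1:2])),
    config = config
  ), class = "tetfit")
}

#' @export
print.tetfit <- function(x, ...) {
  cat(sprintf(paste0(
    "<tetfit> n = %d tetrads | objective: %s = %.4g\n",
    "  RSD rate r = %.4f | per-chromosome MI-NDJ rate d = %.5f (P_ndj = %.3f)\n",
    "  per-spore death shares: RSD %.1f%%, MI-NDJ %.1f%% | expected viability %.1f%% (observed %.1f%%)\n"),
    x$n, x$objective, x$objective_value, x$r_hat, x$d_hat, x$p_ndj,
    100 * x$rsd_death_share, 100 * x$ndj_death_share,
    x$expected_viability, x$observed_viability))
  invisible(x)
}

#' @export
tidy.tetfit <- function(x, ...) {
  tibble(term = c("r", "d", "p_ndj", "rsd_death_share", "ndj_death_share"),
         estimate = c(x$r_hat, x$d_hat, x$p_ndj,
                      x$rsd_death_share, x$ndj_death_share))
}

#' @export
glance.tetfit <- function(x, ...) {
  tibble(r_hat = x$r_hat, d_hat = x$d_hat, p_ndj = x$p_ndj,
         rsd_death_share = x$rsd_death_share,
         ndj_death_share = x$ndj_death_share,
         expected_viability = x$expected_viability,
         observed_viability = x$observed_viability,
         objective = x$objective, objective_value = x$objective_value,
         n = x$n)
}

#' Percent spore viability of a tetrad tally
#'
#' @param observed Tetrad counts (see [tetrad_counts()]).
#' @return `100 * sum(class * count) / (4 n)`, in percent.
#' @export
spore_viability <- function(observed) {
  observed <- as_tetrad_counts(observed)
  100 * sum(observed$n_viable * observed$count) / (4 * sum(observed$count))
}

#' Per-chromosome MI-NDJ rate from a death share
#'
#' Inverts the per-spore NDJ death share `share = (1 - (1-d)^C)/2` for the
#' per-chromosome nondisjunction rate `d = 1 - (1 - 2 share)^(1/C)`.
#'
#' @param ndj_death_share Per-spore death share attributable to MI-NDJ
#'   (in `[0, 0.5]`).
#' @param C Number of chromosomes.
#' @return The per-chromosome MI-NDJ probability `d`.
#' @examples
#' per_chromosome_rate_from_share(0.237, 16)
#' @export
per_chromosome_rate_from_share <- function(ndj_death_share, C = 16) {
  if (ndj_death_share < 0 || ndj_death_share > 0.5) {
    stop_resectr("`ndj_death_share` must be in [0, 0.5]",
                 class = "resectr_infeasible_error")
  }
  1 - (1 - 2 * ndj_death_share)^(1 / C)
}

#' Perkins genetic distance from tetrad classes
#'
#' `cM = 100 (TT/2 + 3 NPD) / (PD + NPD + TT)`, with a delta-method standard
#' error from the multinomial class frequencies.
#'
#' @param classes Named numeric/list with `PD`, `NPD`, `TT` counts, or a
#'   one-row data frame with those columns (e.g. from [tetrad_class_counts()]).
#' @return One-row tibble with `cM`, `se`, `n` (scored tetrads).
#' @examples
#' perkins_distance(c(PD = 50, NPD = 10, TT = 40)) # 50 cM
#' @export
perkins_distance <- function(classes) {
  cl <- as.list(classes)
  pd <- as.numeric(cl$PD)
  npd <- as.numeric(cl$NPD)
  tt <- as.numeric(cl$TT)
  if (any(c(pd, npd, tt) < 0)) stop_resectr("class counts must be >= 0")
  n <- pd + npd + tt
  if (n <= 0) stop_resectr("no scorable tetrads", class = "resectr_empty_error")
  p_t <- tt / n
  p_n <- npd / n
  cm <- 100 * (p_t / 2 + 3 * p_n)
  se <- 100 * sqrt((p_t * (1 - p_t) / 4 + 9 * p_n * (1 - p_n) -
                      3 * p_t * p_n) / n)
  tibble(cM = cm, se = se, n = n)
}

#' Classify fluorescent-marker tetrads
#'
#' Classifies each tetrad from the per-spore presence of a centromere-linked
#' marker and a second (distal) marker, plus spore viability. Rules, applied
#' in order: **NDJ** when exactly two spores carry the CEN-linked marker and
#' the two marker-less spores are inviable (the disome/nullisome signature of
#' meiosis-I nondisjunction); otherwise tetrads with any dead spore are
#' **unscorable**; otherwise the joint two-marker pattern assigns **PD**
#' (2 both-marker : 2 no-marker), **NPD** (2:2 both recombinant) or **TT**
#' (1:1:1:1); anything else is **unscorable**.
#'
#' @param patterns Tibble with one row per spore: columns `tetrad`, `spore`,
#'   `viable`, `cen_marker`, `distal_marker` (logical markers). Tetrads must
#'   have exactly 4 spores.
#' @return Tibble with one row per tetrad: `tetrad`, `class` (one of
#'   `"PD"`, `"NPD"`, `"TT"`, `"NDJ"`, `"unscorable"`).
#' @export
classify_tetrads <- function(patterns) {
  need <- c("tetrad", "spore", "viable", "cen_marker", "distal_marker")
  if (!all(need %in% names(patterns))) {
    stop_resectr(sprintf("patterns need columns: %s", paste(need, collapse = ", ")))
  }
  if (any(is.na(patterns$viable)) || any(is.na(patterns$cen_marker)) ||
      any(is.na(patterns$distal_marker))) {
    stop_resectr("malformed pattern: NA in viability or markers")
  }
  sizes <- table(patterns$tetrad)
  if (any(sizes != 4)) stop_resectr("every tetrad must have exactly 4 spores")
  patterns |>
    group_by(.data$tetrad) |>
    summarise(class = classify_one_tetrad(.data$viable, .data$cen_marker,
                                          .data$distal_marker),
              .groups = "drop")
}

classify_one_tetrad <- function(viable, cen, distal) {
  if (sum(cen) == 2 && all(!viable[!cen])) return("NDJ")
  if (any(!viable)) return("unscorable")
  n_ab <- sum(cen & distal)
  n_a <- sum(cen & !distal)
  n_b <- sum(!cen & distal)
  n_none <- sum(!cen & !distal)
  if (n_ab == 2 && n_none == 2) return("PD")
  if (n_a == 2 && n_b == 2) return("NPD")
  if (n_ab == 1 && n_a == 1 && n_b == 1 && n_none == 1) return("TT")
  "unscorable"
}

#' Tally tetrad classifications
#'
#' @param classifications Output of [classify_tetrads()] (tibble with a
#'   `class` column).
#' @return One-row tibble with counts `PD`, `NPD`, `TT`, `NDJ`, `unscorable`.
#' @export
tetrad_class_counts <- function(classifications) {
  lv <- c("PD", "NPD", "TT", "NDJ", "unscorable")
  tab <- table(factor(classifications$class, levels = lv))
  as_tibble(as.list(setNames(as.integer(tab), lv)))
}

#' MI nondisjunction frequency from classified tetrads
#'
#' @param classifications Output of [classify_tetrads()] or of
#'   [tetrad_class_counts()].
#' @return Percent of scorable tetrads (PD + NPD + TT + NDJ) classified NDJ.
#' @export
ndj_frequency <- function(classifications) {
  counts <- if (all(c("PD", "NPD", "TT", "NDJ") %in% names(classifications))) {
    classifications
  } else {
    tetrad_class_counts(classifications)
  }
  scorable <- counts$PD + counts$NPD + counts$TT + counts$NDJ
  if (scorable <= 0) stop_resectr("no scorable tetrads", class = "resectr_empty_error")
  100 * counts$NDJ / scorable
}
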