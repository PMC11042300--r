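# nucleosome-anchored averaging, region quantification, and k-means++
# clustering of per-hotspot-side resection profiles

# extract a +/- flank window around one anchor from a per-chromosome values
# list; reverse-oriented anchors are flipped so profiles read away from the
# hotspot
anchor_window <- function(vals, len, position, orientation, flank) {
  off <- (-flank):flank
  pos0 <- position + off
  valid <- pos0 >= 0 & pos0 <= len - 1
  v <- rep(NA_real_, length(off))
  v[valid] <- vals[pos0[valid] + 1]
  if (identical(orientation, "reverse")) rev(v) else v
}

#' Feature-anchored average profile
#'
#' Averages signal in windows centered on a set of anchors (nucleosome
#' midpoints, DSB hotspot midpoints, Rec114 peaks, tRNA genes, random
#' controls, ...). Reverse-oriented anchors are flipped before averaging so
#' that positive offsets always read away from the hotspot; for stranded
#' tracks, forward anchors read the top strand and reverse anchors the bottom
#' strand (co-orientation), while unstranded and calibrated tracks use their
#' single signal vector. Missing values (outside the chromosome or masked as
#' missing in calibrated tracks) are excluded from the mean.
#'
#' @param x A `strand_track` or [calibrated_track()].
#' @param anchors Tibble with columns `chrom`, `position` (0-based bp) and
#'   optionally `orientation` (`"forward"`/`"reverse"`, default forward).
#' @param flank Half-window in bp; profiles span offsets `-flank..flank`.
#' @param smooth Hann window size for smoothing the averaged profile (default
#'   41 bp); 0 to skip.
#' @param ... Unused.
#' @return A tibble of class `anchor_profile` with columns `offset`, `value`
#'   and `n` (anchors contributing at each offset).
#' @export
anchored_average <- function(x, anchors, flank = 1000, smooth = 41, ...) {
  UseMethod("anchored_average")
}

anchored_average_impl <- function(get_vals, lens, anchors, flank, smooth) {
  if (!nrow(anchors)) stop_resectr("need at least one anchor")
  if (!"orientation" %in% names(anchors)) anchors$orientation <- "forward"
  bad <- setdiff(unique(anchors$chrom), names(lens))
  if (length(bad)) {
    stop_resectr(sprintf("anchors reference unknown chromosome(s): %s",
                         paste(bad, collapse = ", ")))
  }
  width <- 2 * flank + 1
  acc <- numeric(width)
  cnt <- numeric(width)
  for (i in seq_len(nrow(anchors))) {
    v <- anchor_window(get_vals(anchors$chrom[[i]], anchors$orientation[[i]]),
                       lens[[anchors$chrom[[i]]]],
                       anchors$position[[i]], anchors$orientation[[i]], flank)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  avg <- ifelse(cnt > 0, acc / cnt, NA_real_)
  if (smooth >= 1) avg <- hann_smooth(avg, smooth)
  structure(tibble(offset = (-flank):flank, value = avg, n = cnt),
            class = c("anchor_profile", "tbl_df", "tbl", "data.frame"))
}

#' @rdname anchored_average
#' @export
anchored_average.strand_track <- function(x, anchors, flank = 1000, smooth = 41, ...) {
  lens <- layout_lengths(x$layout)
  get_vals <- function(chrom, orientation) {
    strand_values(x, if (identical(orientation, "reverse")) "bottom" else "top", chrom)
  }
  anchored_average_impl(get_vals, lens, anchors, flank, smooth)
}

#' @rdname anchored_average
#' @export
anchored_average.calibrated_track <- function(x, anchors, flank = 1000, smooth = 41, ...) {
  lens <- layout_lengths(x$layout)
  get_vals <- function(chrom, orientation) x$values[[chrom]]
  anchored_average_impl(get_vals, lens, anchors, flank, smooth)
}

#' Define an ordered, contiguous region scheme around an anchor
#'
#' @param label Character vector of region labels.
#' @param start_offset,end_offset Inclusive offsets in bp relative to the
#'   anchor; regions must be non-overlapping and contiguous (each start is the
#'   previous end + 1).
#' @return A tibble usable with [region_percentages()].
#' @examples
#' # NDR and +1 nucleosome around a +1-nucleosome midpoint anchor
#' region_scheme(c("NDR", "plus1"), c(-219, -73), c(-74, 73))
#' @export
region_scheme <- function(label, start_offset, end_offset) {
  sch <- tibble(label = as.character(label),
                start_offset = as.numeric(start_offset),
                end_offset = as.numeric(end_offset))
  sch <- dplyr::arrange(sch, .data$start_offset)
  if (any(sch$end_offset < sch$start_offset)) {
    stop_resectr("each region needs start_offset <= end_offset")
  }
  if (nrow(sch) > 1 &&
      any(sch$start_offset[-1] != sch$end_offset[-nrow(sch)] + 1)) {
    stop_resectr("regions must be contiguous and non-overlapping")
  }
  sch
}

#' Percentage of signal per anchored region
#'
#' Sums an anchored profile over each region of a scheme and expresses the
#' sums as percentages of the total over a set of reference regions (taken as
#' 100%). Used e.g. to quantify how much endpoint signal falls within the +1
#' nucleosome versus the NDR.
#'
#' @param profile An `anchor_profile` (from [anchored_average()]).
#' @param scheme A [region_scheme()].
#' @param reference_labels Labels whose summed signal is the 100% denominator
#'   (default: all labels).
#' @return Tibble with `label`, `signal`, `percent`.
#' @export
region_percentages <- function(profile, scheme, reference_labels = NULL) {
  reference_labels <- reference_labels %||% scheme$label
  if (!all(reference_labels %in% scheme$label)) {
    stop_resectr("`reference_labels` must be a subset of the scheme labels")
  }
  sums <- vapply(seq_len(nrow(scheme)), function(i) {
    sel <- profile$offset >= scheme$start_offset[[i]] &
      profile$offset <= scheme$end_offset[[i]]
    sum(profile$value[sel], na.rm = TRUE)
  }, numeric(1))
  denom <- sum(sums[scheme$label %in% reference_labels])
  if (denom == 0) stop_resectr("reference regions carry zero signal",
                               class = "resectr_zero_denominator")
  tibble(label = scheme$label, signal = sums, percent = 100 * sums / denom)
}

#' Build the per-hotspot-side profile matrix for clustering
#'
#' For each sufficiently isolated hotspot (no other hotspot within
#' `min_separation`), takes the 1-bp S1-seq signal over `flank` bp to the
#' right (top strand) and left (bottom strand, reversed) of the midpoint —
#' one row per hotspot side. Each row has its minimum subtracted (background,
#' defined as the lowest signal within the profile) and is normalized to its
#' total, removing DSB-frequency differences so clustering sees only the
#' spatial distribution. Rows whose post-subtraction sum is zero are dropped.
#'
#' @param track A stranded `strand_track` (normalized).
#' @param hotspots Hotspot tibble.
#' @param min_separation Isolation radius in bp (default 1 kb); measured
#'   edge-to-edge, no width filter.
#' @param flank Profile length in bp (default 1 kb; 1-bp resolution).
#' @return A numeric matrix of class `profile_matrix` (rows = hotspot sides,
#'   columns = distances 0..flank-1, each row summing to 1), with attributes
#'   `info` (tibble `row`, `hotspot_id`, `side`) and `dropped` (tibble of
#'   dropped degenerate sides).
#' @export
prepare_cluster_profiles <- function(track, hotspots, min_separation = 1000,
                                     flank = 1000) {
  hotspots <- select_loner_hotspots(as_hotspots(hotspots), max_width = Inf,
                                    min_separation = min_separation)
  if (!nrow(hotspots)) stop_resectr("no isolated hotspots to profile")
  rows <- list()
  info <- list()
  dropped <- list()
  for (i in seq_len(nrow(hotspots))) {
    h <- hotspots[i, ]
    for (side in c("right", "left")) {
      p <- extract_side_profile(track, h, side, flank)
      p[is.na(p)] <- 0
      p <- p - min(p)
      s <- sum(p)
      rec <- tibble(hotspot_id = h$hotspot_id, side = side)
      if (s > 0) {
        rows[[length(rows) + 1]] <- p / s
        info[[length(info) + 1]] <- rec
      } else {
        dropped[[length(dropped) + 1]] <- rec
      }
    }
  }
  if (!length(rows)) stop_resectr("all profiles are degenerate (flat)")
  mat <- do.call(rbind, rows)
  info <- dplyr::bind_rows(info)
  info$row <- seq_len(nrow(info))
  rownames(mat) <- paste(info$hotspot_id, info$side, sep = ":")
  structure(mat, class = c("profile_matrix", class(mat)),
            info = info,
            dropped = if (length(dropped)) dplyr::bind_rows(dropped) else tibble(hotspot_id = character(), side = character()))
}

# k-means++ seeding: rows of x, k distinct centers
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  for (j in seq_len(k - 1) + 1) {
    d2[centers[seq_len(j - 1)]] <- 0
    if (sum(d2) <= 0) {
      pool <- setdiff(seq_len(n), centers[seq_len(j - 1)])
      centers[j] <- if (length(pool) == 1) pool else sample(pool, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ], "-")^2))
  }
  centers
}

#' Cluster resection profiles with seeded k-means++
#'
#' Euclidean k-means with k-means++ initialization, best of `n_init` seeded
#' restarts by total within-cluster sum of squares; deterministic given
#' `seed`. Clusters are relabeled in increasing order of the centroid's
#' signal-weighted mean distance from the hotspot midpoint, so cluster 1 is
#' always the shortest-resection group — making cluster identities
#' reproducible and row-order invariant.
#'
#' @param x A `profile_matrix` from [prepare_cluster_profiles()] (any numeric
#'   matrix with rows as profiles works).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed controlling the restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param n_init Number of k-means++ restarts.
#' @return An object of class `profile_clusters`: list with `k`,
#'   `assignments` (tibble `hotspot_id`, `side`, `cluster` when row metadata
#'   is available, else `row`, `cluster`), `centroids` (k x ncol matrix),
#'   `sizes`, `tot_withinss`, `degenerate`.
#' @export
kmeanspp_cluster <- function(x, k = 3, seed = 1, max_iter = 300, n_init = 10) {
  mat <- unclass(x)
  attr(mat, "info") <- NULL
  attr(mat, "dropped") <- NULL
  if (!is.matrix(mat)) stop_resectr("`x` must be a matrix of profiles")
  if (k > nrow(mat)) stop_resectr("`k` exceeds the number of profiles")
  n_distinct <- nrow(unique(mat))
  degenerate <- n_distinct < k
  if (degenerate) {
    rlang::warn(sprintf("only %d distinct profiles for k = %d; clustering distinct profiles (degenerate clusters flagged)",
                        n_distinct, k))
  }
  k_eff <- min(k, n_distinct)
  fit <- withr::with_seed(check_seed(seed), {
    best <- NULL
    for (rep in seq_len(n_init)) {
      umat <- unique(mat)
      init_rows <- kmeanspp_init(umat, k_eff)
      km <- withCallingHandlers(
        kmeans(mat, centers = umat[init_rows, , drop = FALSE],
               iter.max = max_iter, algorithm = "Lloyd"),
        warning = function(w) {
          # empty-cluster / convergence warnings are expected in discarded
          # restarts; only the best-of-n_init fit is kept
          if (grepl("empty cluster|did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  # canonical relabeling: by centroid signal-weighted mean distance
  d <- seq_len(ncol(mat)) - 1
  cen_mean_dist <- apply(fit$centers, 1, function(cc) {
    s <- sum(cc)
    if (s <= 0) Inf else sum(d * cc) / s
  })
  ord <- order(cen_mean_dist)
  relabel <- match(seq_len(k_eff), ord)
  cluster <- relabel[fit$cluster]
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k_eff)
  info <- attr(x, "info")
  assignments <- if (!is.null(info)) {
    tibble(hotspot_id = info$hotspot_id, side = info$side, cluster = cluster)
  } else {
    tibble(row = seq_len(nrow(mat)), cluster = cluster)
  }
  structure(list(k = k_eff, k_requested = k, assignments = assignments,
                 centroids = centroids,
                 sizes = as.integer(table(factor(cluster, levels = seq_len(k_eff)))),
                 tot_withinss = fit$tot.withinss, degenerate = degenerate),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("<profile_clusters> k = %d | sizes: %s | total WCSS: %.4g%s\n",
              x$k, paste(x$sizes, collapse = ", "), x$tot_withinss,
              if (x$degenerate) " | DEGENERATE" else ""))
  invisible(x)
}

#' @export
tidy.profile_clusters <- function(x, ...) x$assignments

#' @export
glance.profile_clusters <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), tot_withinss = x$tot_withinss,
         degenerate = x$degenerate)
}

#' Per-cluster raw signal averages and pooled median resection lengths
#'
#' For each cluster, averages the raw (not background-subtracted, not
#' row-normalized) oriented S1-seq profiles and, when an MNase occupancy track
#' is supplied, the matching oriented MNase profiles; and computes the pooled
#' weighted-median resection length of the cluster's sides. This is the basis
#' for overlaying resection patterns on premeiotic chromatin structure.
#'
#' @param clusters A `profile_clusters` with hotspot-side assignments.
#' @param track The raw stranded S1-seq `strand_track`.
#' @param hotspots The hotspot tibble the clustering was built from.
#' @param mnase Optional unstranded `strand_track` of nucleosome occupancy.
#' @param flank Profile length in bp (defaults to the centroid width).
#' @param censor Censor bounds passed to [pooled_median()] (`NULL` = none).
#' @return An object of class `cluster_summary`: list with `summary` (tibble
#'   `cluster`, `n`, `median_resection`, `mean_mnase`) and `profiles` (tibble
#'   `cluster`, `distance`, `s1`, `mnase`). Empty clusters are flagged with
#'   `NA` summaries.
#' @export
cluster_summaries <- function(clusters, track, hotspots, mnase = NULL,
                              flank = ncol(clusters$centroids), censor = NULL) {
  hotspots <- as_hotspots(hotspots)
  asg <- clusters$assignments
  if (!all(c("hotspot_id", "side") %in% names(asg))) {
    stop_resectr("cluster assignments lack hotspot-side metadata")
  }
  missing_ids <- setdiff(asg$hotspot_id, hotspots$hotspot_id)
  if (length(missing_ids)) {
    stop_resectr(sprintf("assignments reference unknown hotspots: %s",
                         paste(head(missing_ids, 3), collapse = ", ")))
  }
  hs_idx <- match(asg$hotspot_id, hotspots$hotspot_id)
  summaries <- list()
  profiles <- list()
  for (cl in seq_len(clusters$k)) {
    sel <- which(asg$cluster == cl)
    if (!length(sel)) {
      rlang::warn(sprintf("cluster %d is empty", cl))
      summaries[[cl]] <- tibble(cluster = cl, n = 0L,
                                median_resection = NA_real_, mean_mnase = NA_real_)
      next
    }
    s1_acc <- numeric(flank)
    mn_acc <- numeric(flank)
    dists <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      i <- sel[j]
      h <- hotspots[hs_idx[i], ]
      p <- as.vector(extract_side_profile(track, h, asg$side[i], flank))
      p[is.na(p)] <- 0
      s1_acc <- s1_acc + p
      dists[[j]] <- tibble(distance = 0:(flank - 1), weight = p)
      if (!is.null(mnase)) {
        q <- as.vector(extract_side_profile(mnase, h, asg$side[i], flank))
        q[is.na(q)] <- 0
        mn_acc <- mn_acc + q
      }
    }
    s1_mean <- s1_acc / length(sel)
    mn_mean <- if (is.null(mnase)) rep(NA_real_, flank) else mn_acc / length(sel)
    med <- tryCatch(pooled_median(dists, censor = censor),
                    resectr_empty_error = function(e) NA_real_)
    summaries[[cl]] <- tibble(cluster = cl, n = length(sel),
                              median_resection = med,
                              mean_mnase = mean(mn_mean))
    profiles[[cl]] <- tibble(cluster = cl, distance = 0:(flank - 1),
                             s1 = s1_mean, mnase = mn_mean)
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 profiles = dplyr::bind_rows(profiles)),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
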