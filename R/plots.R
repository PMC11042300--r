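# ggplot2 autoplot methods for the package's result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_area labs
#'   facet_wrap position_dodge sec_axis scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot a genome-average co-oriented resection profile
#'
#' @param object A `resection_profile` from [coorient_average()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resection_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$distance, y = .data$signal)) +
    geom_line(color = "#2166ac") +
    labs(x = "distance from hotspot midpoint (nt)",
         y = "mean S1-seq signal (co-oriented)")
}

#' Plot a tract-length distribution
#'
#' @param object A `resection_dist` from [tract_length_distribution()].
#' @param binwidth Histogram bin width in nt.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resection_dist <- function(object, binwidth = 50, ...) {
  df <- as_tibble(object)
  df$bin <- floor(df$distance / binwidth) * binwidth
  df <- dplyr::summarise(dplyr::group_by(df, .data$bin),
                         weight = sum(.data$weight), .groups = "drop")
  ggplot(df, aes(x = .data$bin, y = .data$weight)) +
    geom_col(width = binwidth, fill = "#4393c3") +
    labs(x = "resection tract length (nt)", y = "signal")
}

#' Plot a feature-anchored average profile
#'
#' @param object An `anchor_profile` from [anchored_average()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.anchor_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$value)) +
    geom_line(color = "#b2182b") +
    labs(x = "offset from anchor (bp)", y = "mean signal")
}

#' Plot cluster centroid profiles
#'
#' @param object A `profile_clusters` from [kmeanspp_cluster()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_clusters <- function(object, ...) {
  cen <- object$centroids
  df <- purrr::map_dfr(seq_len(nrow(cen)), function(i) {
    tibble(cluster = factor(i), distance = seq_len(ncol(cen)) - 1,
           value = cen[i, ])
  })
  ggplot(df, aes(x = .data$distance, y = .data$value, color = .data$cluster)) +
    geom_line() +
    labs(x = "distance from hotspot midpoint (nt)",
         y = "centroid (normalized signal)", color = "cluster")
}

#' Plot per-cluster S1-seq and MNase overlays
#'
#' @param object A `cluster_summary` from [cluster_summaries()].
#' @param ... Unused.
#' @return A ggplot faceted by cluster, with the raw S1-seq average as a line
#'   and the MNase average as a shaded area (rescaled to the S1-seq range).
#' @export
autoplot.cluster_summary <- function(object, ...) {
  prof <- object$profiles
  has_mnase <- any(is.finite(prof$mnase))
  g <- ggplot(prof, aes(x = .data$distance))
  if (has_mnase) {
    scale <- max(prof$s1, na.rm = TRUE) /
      max(prof$mnase[is.finite(prof$mnase)], 1e-12)
    g <- g + geom_area(aes(y = .data$mnase * scale), fill = "grey80")
  }
  g + geom_line(aes(y = .data$s1), color = "#2166ac") +
    facet_wrap(~cluster, labeller = "label_both") +
    labs(x = "distance from hotspot midpoint (nt)",
         y = "mean raw S1-seq (line) / scaled MNase (grey)")
}

#' Plot observed versus fitted tetrad viability classes
#'
#' @param object A `tetfit`.
#' @param ... Unused.
#' @return A ggplot of class frequencies.
#' @export
autoplot.tetfit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$classes, c("observed", "fitted"),
                            names_to = "source", values_to = "freq")
  ggplot(df, aes(x = factor(.data$n_viable, levels = 4:0), y = .data$freq,
                 fill = .data$source)) +
    geom_col(position = position_dodge()) +
    labs(x = "viable spores per tetrad", y = "frequency", fill = NULL)
}
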