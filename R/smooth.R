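# window smoothing shared by the resection, chromatin and ChIP modules

# symmetric unit-sum kernel; effective length is window+1 when window is even
# (so a "100-bp Hann window" is the usual odd 101-point kernel) and window
# when window is odd (a "41-bp" kernel has 41 points)
window_kernel <- function(window, type = c("hann", "parzen")) {
  type <- match.arg(type)
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop_resectr("`window` must be a single number >= 1")
  }
  L <- if (window %% 2 == 0) window + 1 else window
  h <- (L - 1) / 2
  if (h == 0) return(1)
  j <- seq(-h, h)
  k <- switch(type,
              hann = 0.5 * (1 + cos(pi * j / h)),
              parzen = 1 - abs(j) / (h + 1))
  k / sum(k)
}

# linear convolution via FFT, trimmed to "same" alignment
conv_same <- function(x, kernel) {
  n <- length(x)
  L <- length(kernel)
  if (L == 1L) return(x * kernel)
  h <- (L - 1) / 2
  m <- nextn(n + L - 1, 2)
  X <- fft(c(x, rep(0, m - n)))
  K <- fft(c(kernel, rep(0, m - L)))
  full <- Re(fft(X * K, inverse = TRUE)) / m
  full[(h + 1):(h + n)]
}

# missing- and edge-aware weighted-mean smoothing: at each defined position,
# the kernel is renormalized over the in-range, non-missing support
smooth_vector <- function(x, kernel) {
  if (length(kernel) == 1L) return(x)
  obs <- !is.na(x)
  num <- conv_same(ifelse(obs, x, 0), kernel)
  wt <- conv_same(as.numeric(obs), kernel)
  out <- rep(NA_real_, length(x))
  ok <- obs & wt > .Machine$double.eps^0.5
  out[ok] <- num[ok] / wt[ok]
  out
}

#' Hann-window smoothing
#'
#' Convolution with a symmetric, unit-sum Hann (raised-cosine) kernel, the
#' smoothing used for genome-average resection profiles (100-bp window) and
#' nucleosome-anchored metaprofiles (41-bp window). Edges and missing values
#' are handled by renormalizing the kernel over the available support, so
#' total signal is conserved for signals supported away from the edges.
#'
#' @param x Numeric vector (may contain `NA` for missing).
#' @param window Window size in bp; the kernel has `window+1` points when
#'   `window` is even, `window` when odd (always an odd-length kernel).
#' @return Smoothed numeric vector, same length as `x`.
#' @examples
#' hann_smooth(c(rep(0, 50), 1, rep(0, 50)), window = 10)
#' @export
hann_smooth <- function(x, window = 100) {
  smooth_vector(as.numeric(x), window_kernel(window, "hann"))
}

#' Parzen (triangular) window smoothing
#'
#' Sliding triangular-window smoothing as applied to calibrated ChIP-seq
#' ratio and difference maps (1-kb window). Missing positions (e.g. ratio
#' positions below the input floor) stay missing and are excluded from
#' neighboring windows by kernel renormalization.
#'
#' @param x Numeric vector or a [calibrated_track()].
#' @param window Window size in bp (kernel length as in [hann_smooth()]).
#' @param ... Unused.
#' @return Object of the same type as `x`, smoothed.
#' @export
parzen_smooth <- function(x, window = 1000, ...) UseMethod("parzen_smooth")

#' @rdname parzen_smooth
#' @export
parzen_smooth.numeric <- function(x, window = 1000, ...) {
  smooth_vector(x, window_kernel(window, "parzen"))
}

#' @rdname parzen_smooth
#' @export
parzen_smooth.calibrated_track <- function(x, window = 1000, ...) {
  k <- window_kernel(window, "parzen")
  x$values <- lapply(x$values, smooth_vector, kernel = k)
  x
}
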