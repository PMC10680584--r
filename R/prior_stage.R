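# Stage 1: per-channel a-priori probability fields and global/local
# foreground masks.

#' Multi-class Otsu thresholds on a 256-bin histogram
#'
#' Exhaustive search over all threshold pairs (for `classes = 3`) or single
#' thresholds (for `classes = 2`), maximizing between-class variance.
#' Thresholds are returned as 0-based bin indices; a pixel with value `v`
#' falls in bin `min(floor(v * 256), 255)` and is above threshold `t` when
#' its bin strictly exceeds `t`.
#'
#' @param x Numeric vector or matrix of values in `[0, 1]`.
#' @param classes 2 or 3.
#' @param nbins Number of histogram bins.
#' @return Integer vector of `classes - 1` bin-index thresholds (ascending).
#' @export
otsu_thresholds <- function(x, classes = 3L, nbins = 256L) {
  b <- pmin(as.integer(floor(as.numeric(x) * nbins)), nbins - 1L)
  h <- tabulate(b + 1L, nbins)
  n <- sum(h)
  if (n == 0) stop("empty input")
  w <- cumsum(h)
  s <- cumsum(h * (seq_len(nbins) - 1))
  total <- s[nbins]
  # class stats for bins (a+1)..b, 0-based thresholds a<b
  cls_w <- function(a, b) w[b + 1L] - ifelse(a < 0, 0, w[a + 1L])
  cls_s <- function(a, b) s[b + 1L] - ifelse(a < 0, 0, s[a + 1L])
  if (classes == 2L) {
    t <- 0:(nbins - 2L)
    w1 <- cls_w(-1L, t); s1 <- cls_s(-1L, t)
    w2 <- n - w1; s2 <- total - s1
    v <- ifelse(w1 > 0 & w2 > 0, s1^2 / w1 + s2^2 / w2, -Inf)
    return(t[which.max(v)])
  }
  if (classes != 3L) stop("classes must be 2 or 3")
  occupied <- which(h > 0) - 1L
  if (length(occupied) < 3L)
    stop("fewer than 3 distinct histogram bins")
  best <- -Inf; bt <- c(0L, 1L)
  for (t1 in 0:(nbins - 3L)) {
    w1 <- cls_w(-1L, t1)
    if (w1 == 0) next
    s1 <- cls_s(-1L, t1)
    t2 <- (t1 + 1L):(nbins - 2L)
    w2 <- cls_w(t1, t2); s2 <- cls_s(t1, t2)
    w3 <- n - w1 - w2; s3 <- total - s1 - s2
    v <- ifelse(w2 > 0 & w3 > 0, s1^2 / w1 + s2^2 / w2 + s3^2 / w3, -Inf)
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; bt <- c(t1, t2[k]) }
  }
  bt
}

#' Initial channel foreground estimate
#'
#' Gaussian-smooth the channel and keep pixels strictly above the lower of
#' the two thresholds found by three-class Otsu. Used only to select the
#' pixel sample from which the channel's a-priori intensity CDF is built.
#' If the smoothed image has fewer than three distinct histogram bins, the
#' estimate falls back to a single two-class Otsu threshold (with a message).
#'
#' @param I Normalized channel matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Logical matrix, `TRUE` on foreground.
#' @export
initial_foreground <- function(I, sigma = 3) {
  stopifnot(sigma > 0)
  sm <- as.matrix(EBImage::gblur(I, sigma = sigma))
  sm <- pmin(pmax(sm, 0), 1)
  b <- pmin(floor(sm * 256), 255)
  if (length(unique(as.vector(b))) < 3) {
    if (length(unique(as.vector(b))) < 2) return(matrix(FALSE, nrow(I), ncol(I)))
    message("fewer than 3 distinct smoothed levels; using two-class Otsu")
    thr <- otsu_thresholds(sm, classes = 2L)
  } else {
    thr <- otsu_thresholds(sm, classes = 3L)[1]
  }
  b > thr
}

#' A-priori probability field from the foreground intensity CDF
#'
#' Builds the empirical cumulative distribution of channel intensities over
#' the foreground pixels only, and evaluates it at every pixel of the image:
#' the a-priori probability of a pixel being nucleus (channel 1) or membrane
#' (channel 2) grows with its marker intensity and equals 1 at the foreground
#' maximum.
#'
#' @param I Normalized channel matrix.
#' @param fg Logical foreground mask from [initial_foreground()].
#' @return Numeric matrix of probabilities in `[0, 1]`.
#' @export
apriori_probability <- function(I, fg) {
  stopifnot(identical(dim(I), dim(fg)))
  if (!any(fg))
    stop("empty foreground estimate; review sigma / threshold settings")
  F <- ecdf(I[fg])
  matrix(F(I), nrow(I), ncol(I))
}

#' Local mean suppression filter (LMSF)
#'
#' Zeroes every pixel whose intensity falls below `t0` times the mean
#' intensity of its `(2*n0+1)^2` window; other pixels pass unchanged. The
#' window sum uses zero padding outside the image and the divisor is always
#' the full window size, so border pixels see a deflated mean. Detects the
#' dark valleys separating closely packed nuclei or membrane ridges.
#'
#' @param I Normalized channel matrix.
#' @param t0 Ratio threshold in (0, 1).
#' @param n0 Window half-width in pixels.
#' @return Filtered matrix: each pixel is either 0 or its original value.
#' @export
lmsf <- function(I, t0 = 0.5, n0 = 5L) {
  stopifnot(t0 > 0, t0 < 1, n0 >= 1)
  lmsf_cpp(I, t0, as.integer(n0))
}

#' A-priori global mask
#'
#' A pixel is foreground when it survives the LMSF at every scale in
#' `n0_list` (each scale applied independently to the original channel) and
#' its a-priori probability is at least `p_min`.
#'
#' @param I Normalized channel matrix.
#' @param Pe A-priori probability field from [apriori_probability()].
#' @param t0 LMSF ratio threshold.
#' @param n0_list Integer vector of LMSF half-widths.
#' @param p_min Prior refinement threshold.
#' @return Logical matrix.
#' @export
global_mask <- function(I, Pe, t0 = 0.5, n0_list = c(5L, 10L, 20L, 40L),
                        p_min = 0.01) {
  keep <- matrix(TRUE, nrow(I), ncol(I))
  for (n0 in n0_list) keep <- keep & (lmsf(I, t0, n0) != 0)
  keep & (Pe >= p_min)
}

#' Gradient adaptive smoothing (GAS)
#'
#' One iteration of gradient-weighted 3x3 smoothing: each neighbour
#' contributes with weight `exp(-d^2 / (2 * k0^2))`, where `d` is its local
#' gradient magnitude (central differences, replicated borders), and the
#' weighted sum is normalized by the total weight. Flat regions are averaged
#' while strong edges, carrying large gradients, are preserved.
#'
#' @param I Normalized channel matrix.
#' @param k0 Smoothing scale.
#' @return Smoothed matrix.
#' @export
gas <- function(I, k0 = 1) {
  stopifnot(k0 > 0)
  nr <- nrow(I); nc <- ncol(I)
  pad <- function(M) {  # replicate-pad by 1
    M2 <- rbind(M[1, , drop = FALSE], M, M[nr, , drop = FALSE])
    cbind(M2[, 1, drop = FALSE], M2, M2[, nc, drop = FALSE])
  }
  P <- pad(I)
  # central differences on the padded image, evaluated at the interior
  gx <- (P[3:(nr + 2), 2:(nc + 1)] - P[1:nr, 2:(nc + 1)]) / 2
  gy <- (P[2:(nr + 1), 3:(nc + 2)] - P[2:(nr + 1), 1:nc]) / 2
  w <- exp(-(gx^2 + gy^2) / (2 * k0^2))
  PW <- pad(w)
  PI <- P
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (dx in 0:2) for (dy in 0:2) {
    wk <- PW[dx + 1:nr, dy + 1:nc]
    num <- num + PI[dx + 1:nr, dy + 1:nc] * wk
    den <- den + wk
  }
  num / den
}

#' A-priori local mask
#'
#' Applies a per-pixel two-class Otsu threshold over a disk neighbourhood of
#' radius `r0` to the GAS-smoothed channel; pixels above their local
#' threshold are foreground. Because local thresholding is noisy where no
#' tissue is present, the result is restricted to the global mask.
#'
#' @param I_gas GAS-smoothed channel matrix.
#' @param r0 Disk radius in pixels.
#' @param Mg_channel Logical global mask for the same channel.
#' @return Logical matrix (subset of `Mg_channel`).
#' @export
local_mask <- function(I_gas, r0 = 5L, Mg_channel = NULL) {
  stopifnot(r0 >= 1)
  lo <- local_otsu_cpp(pmin(pmax(I_gas, 0), 1), as.integer(r0)) == 1L
  if (!is.null(Mg_channel)) lo <- lo & Mg_channel
  lo
}
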