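# Independent brute-force reference implementations used as oracles.

# plain double-loop LMSF (zero padding, fixed divisor)
lmsf_oracle <- function(I, t0, n0) {
  nr <- nrow(I); nc <- ncol(I)
  out <- matrix(0, nr, nc)
  win <- (2 * n0 + 1)^2
  for (j in 1:nc) for (i in 1:nr) {
    s <- sum(I[max(1, i - n0):min(nr, i + n0),
               max(1, j - n0):min(nc, j + n0)])
    m <- s / win
    v <- I[i, j]
    out[i, j] <- if (m <= 0 || v / m < t0) 0 else v
  }
  out
}

# per-pixel gradient-adaptive smoothing with replicate borders
gas_oracle <- function(I, k0) {
  nr <- nrow(I); nc <- ncol(I)
  cl <- function(i, n) min(max(i, 1), n)
  w <- matrix(0, nr, nc)
  for (j in 1:nc) for (i in 1:nr) {
    gx <- (I[cl(i + 1, nr), j] - I[cl(i - 1, nr), j]) / 2
    gy <- (I[i, cl(j + 1, nc)] - I[i, cl(j - 1, nc)]) / 2
    w[i, j] <- exp(-(gx^2 + gy^2) / (2 * k0^2))
  }
  out <- matrix(0, nr, nc)
  for (j in 1:nc) for (i in 1:nr) {
    num <- 0; den <- 0
    for (dj in -1:1) for (di in -1:1) {
      ii <- cl(i + di, nr); jj <- cl(j + dj, nc)
      num <- num + I[ii, jj] * w[ii, jj]
      den <- den + w[ii, jj]
    }
    out[i, j] <- num / den
  }
  out
}

# exhaustive three-class Otsu over all 256-bin threshold pairs
otsu3_oracle <- function(x, nbins = 256L) {
  b <- pmin(floor(as.numeric(x) * nbins), nbins - 1L)
  h <- tabulate(b + 1L, nbins)
  best <- -Inf; bt <- c(0L, 1L)
  for (t1 in 0:(nbins - 3L)) for (t2 in (t1 + 1L):(nbins - 2L)) {
    i1 <- 1:(t1 + 1L); i2 <- (t1 + 2L):(t2 + 1L); i3 <- (t2 + 2L):nbins
    w1 <- sum(h[i1]); w2 <- sum(h[i2]); w3 <- sum(h[i3])
    if (w1 == 0 || w2 == 0 || w3 == 0) next
    s1 <- sum(h[i1] * (i1 - 1)); s2 <- sum(h[i2] * (i2 - 1))
    s3 <- sum(h[i3] * (i3 - 1))
    v <- s1^2 / w1 + s2^2 / w2 + s3^2 / w3
    if (v > best) { best <- v; bt <- c(t1, t2) }
  }
  bt
}

# per-pixel sliding-window two-class Otsu over a disk, brute force
local_otsu_oracle <- function(I, r0) {
  nr <- nrow(I); nc <- ncol(I)
  bin <- pmin(pmax(floor(I * 256), 0), 255)
  out <- matrix(0L, nr, nc)
  for (j in 1:nc) for (i in 1:nr) {
    vals <- integer(0)
    for (dj in -r0:r0) for (di in -r0:r0) {
      if (di * di + dj * dj > r0 * r0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      vals <- c(vals, bin[ii, jj])
    }
    if (min(vals) == max(vals)) { out[i, j] <- 0L; next }
    best <- -1; tbest <- min(vals)
    n <- length(vals); sumAll <- sum(vals)
    for (t in min(vals):(max(vals) - 1L)) {
      inB <- vals <= t
      wB <- sum(inB); wF <- n - wB
      if (wB == 0 || wF == 0) next
      mB <- sum(vals[inB]) / wB; mF <- (sumAll - sum(vals[inB])) / wF
      v <- wB * wF * (mB - mF)^2
      if (v > best) { best <- v; tbest <- t }
    }
    out[i, j] <- if (bin[i, j] > tbest) 1L else 0L
  }
  out
}

# optimal one-to-one assignment (exhaustive over permutations) maximizing
# the number of matched pairs with IoU > threshold
optimal_match_oracle <- function(pred, gt, thr) {
  pids <- sort(unique(pred[pred > 0]))
  gids <- sort(unique(gt[gt > 0]))
  iou <- function(p, g) {
    a <- pred == p; b <- gt == g
    sum(a & b) / sum(a | b)
  }
  M <- outer(pids, gids, Vectorize(iou))
  ok <- M > thr
  np <- length(pids); ng <- length(gids)
  best <- 0L
  idx <- seq_len(ng)
  if (np == 0 || ng == 0) return(list(TP = 0L))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perms(v[-k])) out <- c(out, list(c(v[k], p)))
    out
  }
  # try all injections of predictions into gt slots (pad with 0 = unmatched)
  slots <- c(idx, rep(0L, max(0, np - ng)))
  for (p in perms(slots)) {
    tp <- 0L
    for (k in seq_len(np)) if (p[k] > 0 && ok[k, p[k]]) tp <- tp + 1L
    if (tp > best) best <- tp
  }
  list(TP = best)
}

# expected concavity depth of two fused equal circles of radius r whose
# centres are d apart: distance from the neck crevice to the external
# tangent line
fused_disk_depth <- function(r, d) r - sqrt(r^2 - (d / 2)^2)
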