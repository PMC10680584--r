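# Stage 2: contrast-based likelihood and posterior global/local semantic
# label maps.

#' Contrast-based likelihood map
#'
#' Quantifies the visual contrast between the two channels as a signed score
#' in `[-1, 1]`: `-1` is strong nucleus evidence, `+1` strong membrane
#' evidence, `0` no evidence. The raw contrast
#' `L0 = (I2 - I1) / (I2 + I1)` is evaluated wherever either channel exceeds
#' its minimum intensity over the corresponding local-mask support, and then
#' kept only where its sign is consistent with the matching global mask
#' (negative contrast requires nucleus global mask, positive requires
#' membrane global mask).
#'
#' @param img A [two_channel_image()].
#' @param M1l,M2l Logical local masks (nucleus, membrane).
#' @param M1g,M2g Logical global masks (nucleus, membrane).
#' @return Numeric matrix in `[-1, 1]`, with attributes `i1`, `i2` (the
#'   channel minima over the local-mask supports).
#' @export
contrast_likelihood <- function(img, M1l, M2l, M1g, M2g) {
  I1 <- img$I1; I2 <- img$I2
  i1 <- if (any(M1l)) min(I1[M1l]) else { warning("empty nucleus local mask; using i1 = 0"); 0 }
  i2 <- if (any(M2l)) min(I2[M2l]) else { warning("empty membrane local mask; using i2 = 0"); 0 }
  qual <- (I1 > i1) | (I2 > i2)
  denom <- I1 + I2
  L0 <- matrix(0, nrow(I1), ncol(I1))
  ok <- qual & denom > 0
  L0[ok] <- (I2[ok] - I1[ok]) / denom[ok]
  L <- matrix(0, nrow(I1), ncol(I1))
  keep <- (L0 < 0 & M1g) | (L0 > 0 & M2g)
  L[keep] <- L0[keep]
  attr(L, "i1") <- i1
  attr(L, "i2") <- i2
  L
}

#' Saturate the a-priori probability on the local mask
#'
#' Sets the a-priori probability to 1 wherever the local mask is 1; other
#' pixels keep their prior value.
#'
#' @param Pe A-priori probability matrix.
#' @param Ml Logical local mask.
#' @return Numeric matrix in `[0, 1]`.
#' @export
saturate_prior <- function(Pe, Ml) {
  stopifnot(identical(dim(Pe), dim(Ml)))
  Ps <- Pe
  Ps[Ml] <- 1
  Ps
}

#' Posterior global probability fields
#'
#' Convex combination of the saturated prior and the likelihood magnitude:
#' where the likelihood favours the nucleus (`L < 0`) the nucleus posterior
#' is `P1s + (1 - P1s) * |L|` and the membrane posterior is 0, and
#' symmetrically for `L > 0`. At every pixel at most one of the two fields is
#' non-zero and both lie in `[0, 1]`.
#'
#' @param P1s,P2s Saturated prior matrices from [saturate_prior()].
#' @param L Likelihood matrix from [contrast_likelihood()].
#' @return List with matrices `P1g`, `P2g`.
#' @export
posterior_global <- function(P1s, P2s, L) {
  P1g <- matrix(0, nrow(L), ncol(L))
  P2g <- matrix(0, nrow(L), ncol(L))
  neg <- L < 0; pos <- L > 0
  P1g[neg] <- P1s[neg] + (1 - P1s[neg]) * abs(L[neg])
  P2g[pos] <- P2s[pos] + (1 - P2s[pos]) * L[pos]
  list(P1g = P1g, P2g = P2g)
}

#' Posterior local probability fields
#'
#' Restricts each channel's a-priori probability to its local-mask support;
#' all other pixels get probability 0.
#'
#' @param P1e,P2e A-priori probability matrices.
#' @param M1l,M2l Logical local masks.
#' @return List with matrices `P1l`, `P2l`.
#' @export
posterior_local <- function(P1e, P2e, M1l, M2l) {
  P1l <- matrix(0, nrow(P1e), ncol(P1e)); P1l[M1l] <- P1e[M1l]
  P2l <- matrix(0, nrow(P2e), ncol(P2e)); P2l[M2l] <- P2e[M2l]
  list(P1l = P1l, P2l = P2l)
}

#' Semantic labels from a pair of probability fields
#'
#' Assigns each pixel to background (0), nucleus (1) or membrane (2). Pixels
#' where both probabilities are zero are always background. In `argmax` mode
#' the larger probability wins and positive ties go to the nucleus (which
#' protects downstream nucleus seeding). In `kmeans` mode the non-background
#' `(P1, P2)` pairs are partitioned into three clusters initialized at
#' (0,0), (1,0) and (0,1); each cluster is labelled by its centre (nucleus
#' when the first coordinate dominates, background when the centre is closer
#' to the origin than to either axis anchor).
#'
#' @param P1,P2 Probability matrices in `[0, 1]`.
#' @param mode `"argmax"` (default) or `"kmeans"`.
#' @param seed RNG seed for k-means (deterministic given the seed).
#' @return Integer matrix with values in `{0, 1, 2}`.
#' @export
semantic_labels <- function(P1, P2, mode = c("argmax", "kmeans"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(P1), dim(P2)))
  out <- matrix(0L, nrow(P1), ncol(P1))
  bg <- P1 == 0 & P2 == 0
  if (mode == "argmax") {
    out[!bg & P1 >= P2] <- 1L
    out[!bg & P2 > P1] <- 2L
    return(out)
  }
  idx <- which(!bg)
  if (!length(idx)) return(out)
  feats <- cbind(P1[idx], P2[idx])
  anchors <- rbind(c(0, 0), c(1, 0), c(0, 1))
  # keep only anchors that are nearest for at least one point; degenerate
  # clouds (fewer than two usable anchors or too few distinct points) fall
  # back to the argmax rule
  d2 <- sapply(1:3, function(k)
    (feats[, 1] - anchors[k, 1])^2 + (feats[, 2] - anchors[k, 2])^2)
  if (is.null(dim(d2))) d2 <- matrix(d2, ncol = 3)
  near <- max.col(-d2, ties.method = "first")
  use <- sort(unique(near))
  if (length(use) < 2 || nrow(unique(feats)) <= length(use)) {
    out[idx[feats[, 1] >= feats[, 2]]] <- 1L
    out[idx[feats[, 2] > feats[, 1]]] <- 2L
    return(out)
  }
  km <- local({
    restore <- .Random.seed_exists()
    on.exit(restore())
    set.seed(seed)
    kmeans(feats, centers = anchors[use, , drop = FALSE], iter.max = 50)
  })
  lab_of_center <- apply(km$centers, 1, function(ct) {
    if (max(ct) < 0.5) 0L
    else if (ct[1] >= ct[2]) 1L else 2L
  })
  out[idx] <- lab_of_center[km$cluster]
  out
}

# save/restore the global RNG state around seeded sub-computations
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
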