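# Object-level evaluation: IoU-threshold matching, F1 scores and curves.

# pairwise IoU table between two label maps: data.frame(pred, gt, iou)
iou_pairs <- function(pred, gt) {
  stopifnot(identical(dim(pred), dim(gt)))
  area_p <- tabulate(pred[pred > 0])
  area_g <- tabulate(gt[gt > 0])
  both <- pred > 0 & gt > 0
  if (!any(both))
    return(data.frame(pred = integer(), gt = integer(), iou = numeric()))
  p <- pred[both]; g <- gt[both]
  key <- paste(p, g)
  inter <- tapply(rep(1L, length(key)), key, sum)
  pg <- do.call(rbind, strsplit(names(inter), " ", fixed = TRUE))
  pi <- as.integer(pg[, 1]); gi <- as.integer(pg[, 2])
  iou <- as.numeric(inter) / (area_p[pi] + area_g[gi] - as.numeric(inter))
  data.frame(pred = pi, gt = gi, iou = iou)
}

#' Match predicted and ground-truth objects at an IoU threshold
#'
#' One-to-one matching: candidate pairs with IoU strictly above the
#' threshold are accepted greedily in descending IoU (ties broken by
#' smaller ground-truth id, then smaller predicted id), each object used at
#' most once.
#'
#' @param pred,gt Integer instance label matrices of identical shape.
#' @param iou_threshold IoU threshold in (0, 1].
#' @return List with counts `TP`, `FP`, `FN`, the threshold, and a
#'   data.frame `pairs` (`pred`, `gt`, `iou`) of accepted matches.
#' @export
match_objects <- function(pred, gt, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  n_pred <- length(unique(pred[pred > 0]))
  n_gt <- length(unique(gt[gt > 0]))
  pairs <- iou_pairs(pred, gt)
  pairs <- pairs[pairs$iou > iou_threshold, , drop = FALSE]
  pairs <- pairs[order(-pairs$iou, pairs$gt, pairs$pred), , drop = FALSE]
  used_p <- integer(0); used_g <- integer(0)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (pairs$pred[k] %in% used_p || pairs$gt[k] %in% used_g) next
    keep[k] <- TRUE
    used_p <- c(used_p, pairs$pred[k]); used_g <- c(used_g, pairs$gt[k])
  }
  matched <- pairs[keep, , drop = FALSE]
  rownames(matched) <- NULL
  TP <- nrow(matched)
  list(TP = TP, FP = n_pred - TP, FN = n_gt - TP,
       iou_threshold = iou_threshold, pairs = matched)
}

#' F1 score from match counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`. The empty-versus-empty case
#' (`TP = FP = FN = 0`) is defined as 1 with a warning.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return F1 score in `[0, 1]`.
#' @export
f1_score <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP == 0 && FP == 0 && FN == 0) {
    warning("no objects in either map; defining F1 = 1")
    return(1)
  }
  2 * TP / (2 * TP + FP + FN)
}

#' F1 curve over a grid of IoU thresholds
#'
#' @param pred,gt Integer instance label matrices of identical shape.
#' @param thresholds Strictly increasing thresholds in (0, 1].
#' @return Object of class `f1_curve`: data.frame with columns
#'   `threshold`, `TP`, `FP`, `FN`, `f1`.
#' @export
f1_curve <- function(pred, gt, thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0),
            all(thresholds <= 1))
  rows <- lapply(thresholds, function(t) {
    m <- match_objects(pred, gt, t)
    data.frame(threshold = t, TP = m$TP, FP = m$FP, FN = m$FN,
               f1 = suppressWarnings(f1_score(m$TP, m$FP, m$FN)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("f1_curve", "data.frame")
  out
}

#' @export
plot.f1_curve <- function(x, ...) {
  plot(x$threshold, x$f1, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "IoU threshold", ylab = "F1 score", ...)
  invisible(x)
}

#' Pointwise median F1 curve over a dataset
#'
#' @param curves List of `f1_curve` objects sharing one threshold grid.
#' @param band Percentile band as two probabilities (default 2.5-97.5).
#' @return Data.frame with `threshold`, `median`, `lower`, `upper`.
#' @export
median_f1_over_dataset <- function(curves, band = c(0.025, 0.975)) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$threshold
  for (cv in curves)
    if (!isTRUE(all.equal(cv$threshold, grid)))
      stop("curves must share one threshold grid")
  M <- sapply(curves, `[[`, "f1")
  if (is.null(dim(M))) M <- matrix(M, ncol = length(curves))
  data.frame(threshold = grid,
             median = apply(M, 1, median),
             lower = apply(M, 1, quantile, probs = band[1]),
             upper = apply(M, 1, quantile, probs = band[2]))
}
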