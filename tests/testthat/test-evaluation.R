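test_that("object matching satisfies the conservation identities", {
  set.seed(40)
  b <- small_bundle(seed = 40, n_cells = 12, size = 300)
  pred <- b$gt_nuclei
  m <- match_objects(pred, b$gt_nuclei, 0.5)
  expect_equal(m$TP, 12); expect_equal(m$FP, 0); expect_equal(m$FN, 0)
  # identities on an imperfect prediction
  pred2 <- pred; pred2[pred2 == 3] <- 0          # drop one object
  m2 <- match_objects(pred2, b$gt_nuclei, 0.5)
  expect_equal(m2$TP + m2$FN, 12)
  expect_equal(m2$TP + m2$FP, 11)
})

test_that("objects eroded to 40% of their area fail the 0.5 threshold", {
  m <- matrix(0L, 50, 50)
  m[draw_disk(matrix(FALSE, 50, 50), c(15, 15), 9)] <- 1L
  m[draw_disk(matrix(FALSE, 50, 50), c(35, 35), 9)] <- 2L
  shrunk <- matrix(0L, 50, 50)
  for (i in 1:2) {
    px <- which(m == i)
    keep <- px[seq_len(ceiling(0.4 * length(px)))]
    shrunk[keep] <- i
  }
  res <- match_objects(shrunk, m, 0.5)
  expect_equal(res$TP, 0)                        # IoU 0.4 < 0.5 forced
  expect_equal(res$FN, 2)
})

test_that("greedy matching equals optimal assignment on small maps", {
  set.seed(41)
  for (k in 1:5) {
    gt <- matrix(0L, 40, 40)
    ctrs <- cbind(sample(8:32, 4), sample(8:32, 4))
    for (i in 1:4) gt[draw_disk(matrix(FALSE, 40, 40), ctrs[i, ], 4)] <- i
    pred <- matrix(0L, 40, 40)
    for (i in 1:4) {
      sh <- ctrs[i, ] + sample(-2:2, 2, TRUE)
      pred[draw_disk(matrix(FALSE, 40, 40), sh, sample(3:5, 1))] <- i
    }
    thr <- 0.3
    expect_equal(match_objects(pred, gt, thr)$TP,
                 optimal_match_oracle(pred, gt, thr)$TP)
  }
})

test_that("F1 reproduces hand-enumerated values", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(0, 5, 7), 0)
  expect_equal(f1_score(8, 2, 4), 16 / 22)
  expect_warning(v <- f1_score(0, 0, 0), "F1 = 1")
  expect_equal(v, 1)
})

test_that("F1 curves are non-increasing and exact on identical maps", {
  b <- small_bundle(seed = 42, n_cells = 8, size = 220)
  cv <- f1_curve(b$gt_nuclei, b$gt_nuclei)
  expect_true(all(cv$f1 == 1))
  res <- suppressMessages(run_unseg(b$image))
  cv2 <- f1_curve(res$nuclei, b$gt_nuclei)
  expect_true(all(diff(cv2$f1) <= 1e-12))
  # toy map: curve equals per-threshold recomputation
  for (t in c(0.25, 0.5, 0.75)) {
    k <- which.min(abs(cv2$threshold - t))
    m <- match_objects(res$nuclei, b$gt_nuclei, cv2$threshold[k])
    expect_equal(cv2$f1[k], suppressWarnings(f1_score(m$TP, m$FP, m$FN)))
  }
})

test_that("uniform dilation scores at least as well as uniform erosion", {
  b <- small_bundle(seed = 43, n_cells = 8, size = 220)
  gt <- b$gt_nuclei
  grown <- unseg:::geodesic_flood_cpp(matrix(1, nrow(gt), ncol(gt)), gt,
                                      matrix(TRUE, nrow(gt), ncol(gt)))
  dil <- grown$labels; dil[grown$cost > 2] <- 0L
  ero <- gt
  ero[!unseg:::erode_disk(gt > 0, 2L)] <- 0L
  cd <- f1_curve(dil, gt); ce <- f1_curve(ero, gt)
  expect_true(all(cd$f1 >= ce$f1))
  expect_gt(sum(cd$f1 - ce$f1), 0)               # strictly better somewhere
})

test_that("median curves and percentile bands follow the sort oracle", {
  grid <- seq(0.1, 0.9, by = 0.1)
  mk <- function(f1s) structure(data.frame(threshold = grid, TP = 1, FP = 0,
                                           FN = 0, f1 = f1s),
                                class = c("f1_curve", "data.frame"))
  same <- mk(rep(0.7, 9))
  med <- median_f1_over_dataset(list(same, same, same))
  expect_equal(med$median, rep(0.7, 9))
  expect_equal(med$lower, rep(0.7, 9))            # zero-width band
  three <- median_f1_over_dataset(list(mk(rep(0.2, 9)), mk(rep(0.5, 9)),
                                       mk(rep(0.8, 9))))
  expect_equal(three$median, rep(0.5, 9))
  set.seed(44)
  curves <- lapply(1:7, function(i) mk(sort(runif(9), decreasing = TRUE)))
  med7 <- median_f1_over_dataset(curves)
  M <- sapply(curves, `[[`, "f1")
  expect_equal(med7$median, apply(M, 1, function(v) sort(v)[4]))
  bad <- mk(rep(0.5, 9)); bad$threshold <- grid + 0.01
  expect_error(median_f1_over_dataset(list(same, bad)), "grid")
})
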