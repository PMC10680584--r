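test_that("steepest concave point is sub-pixel for convex shapes", {
  disk <- draw_disk(matrix(FALSE, 40, 40), c(20, 20), 15)
  expect_lte(steepest_concave_point(disk)$depth, 1)   # pixelization only
  rect <- matrix(FALSE, 30, 30); rect[8:22, 5:25] <- TRUE
  expect_equal(steepest_concave_point(rect)$depth, 0)
  tiny <- matrix(FALSE, 5, 5); tiny[2, 2] <- TRUE; tiny[2, 3] <- TRUE
  expect_equal(steepest_concave_point(tiny)$depth, 0)
})

test_that("concavity depth of fused disks matches closed form and hull oracle", {
  for (geom in list(c(10, 16), c(12, 18))) {
    r <- geom[1]; d <- geom[2]
    m <- draw_disk(matrix(FALSE, 60, 80), c(30, 30), r)
    m <- draw_disk(m, c(30, 30 + d), r)
    scp <- steepest_concave_point(m)
    # closed form up to pixelization of the crevice and of the hull
    expect_lt(abs(scp$depth - fused_disk_depth(r, d)), 1.1)
    # brute force: max over boundary pixels of min distance to any hull edge
    bnd <- which(unseg:::boundary_pixels(m))
    rr <- (bnd - 1) %% nrow(m) + 1; cc <- (bnd - 1) %/% nrow(m) + 1
    h <- grDevices::chull(cc, rr)
    H <- cbind(rr, cc)[h, , drop = FALSE]
    dd <- unseg:::dist_to_polygon(cbind(rr, cc), H)$dist
    expect_equal(scp$depth, max(dd), tolerance = 1e-10)
  }
})

test_that("convexity analysis discards, accepts, and flags clusters", {
  m <- matrix(FALSE, 90, 130)
  m <- draw_disk(m, c(20, 20), 10)                  # clean nucleus, ~314 px
  m[60, 60] <- TRUE; m[60, 61] <- TRUE; m[61, 60] <- TRUE  # 3-px speck
  m <- draw_disk(m, c(70, 25), 10)                  # deeply fused pair
  m <- draw_disk(m, c(70, 25 + 18), 10)             # d = 18, depth ~5
  ca <- convexity_analysis(m, unseg_params())
  expect_setequal(ca$class, c("discarded", "NC", "nucleus"))
  expect_equal(ca$class[ca$area <= 20], "discarded")
  expect_equal(ca$class[which.max(ca$scp_depth)], "NC")
  expect_gt(max(ca$scp_depth), 4)
  expect_equal(ca$class[ca$area > 300 & ca$scp_depth < 1], "nucleus")
})

test_that("perturbed watershed is the identity on convex components", {
  disk <- draw_disk(matrix(FALSE, 50, 50), c(25, 25), 14)
  pw <- perturbed_watershed(disk, NULL, unseg_params())
  expect_length(pw, 1)
  expect_equal(pw[[1]], disk)
})

test_that("perturbed watershed splits membrane-cut pairs into partitions", {
  set.seed(20)
  for (s in 1:10) {
    r <- runif(1, 9, 12); f <- runif(1, 1.5, 1.8)
    b <- generate_cluster(2L, radius = r, center_distance_factor = f, seed = s)
    pw <- perturbed_watershed(b$nucleus_mask, b$wall_mask, unseg_params())
    expect_length(pw, 2)
    expect_lte(length(pw), attr(pw, "n_initial"))
    # sub-masks partition the cluster: disjoint, union equals the mask
    expect_false(any(pw[[1]] & pw[[2]]))
    expect_equal(pw[[1]] | pw[[2]], b$nucleus_mask)
    # each sub-mask corresponds to one ground-truth nucleus
    ov <- sapply(pw, function(m) {
      g <- b$gt_nuclei[m]; mean(g == g[g > 0][1])
    })
    expect_true(all(ov > 0.9))
  }
})

test_that("perturbation removes the spurious third seed of a bump cluster", {
  fx <- three_seed_cluster()
  pw <- perturbed_watershed(fx$mask, fx$wall, unseg_params())
  expect_equal(attr(pw, "n_initial"), 3L)
  expect_length(pw, 2)
  # final regions contain the two true centres, one each
  in_region <- sapply(pw, function(m)
    c(m[fx$centers[1, 1], fx$centers[1, 2]],
      m[fx$centers[2, 1], fx$centers[2, 2]]))
  expect_equal(sort(colSums(in_region)), c(1, 1))
})

test_that("virtual cuts split a membrane-free dumbbell that PW leaves whole", {
  b <- generate_cluster(2L, radius = 10, center_distance_factor = 1.6,
                        seed = 1, membrane_wall = FALSE)
  pw <- perturbed_watershed(b$nucleus_mask, NULL, unseg_params())
  expect_length(pw, 1)                         # the pathological case
  vc <- virtual_cuts(b$nucleus_mask, unseg_params())
  expect_length(vc, 2)
  expect_false(any(vc[[1]] & vc[[2]]))
  # each sub-region contains exactly one true centre
  ctr <- round(as.matrix(b$info[, c("center_row", "center_col")]))
  hits <- sapply(vc, function(m) sum(m[ctr]))
  expect_equal(unname(hits), c(1, 1))
  # symmetric dumbbell: the two regions have nearly equal area
  expect_lt(abs(sum(vc[[1]]) - sum(vc[[2]])) / sum(b$nucleus_mask), 0.15)
  expect_error(virtual_cuts(draw_disk(matrix(FALSE, 30, 30), c(15, 15), 10)),
               "non-convex")
})

test_that("segment_nuclei recovers isolated and clustered nuclei", {
  b <- small_bundle(seed = 21, n_cells = 12, size = 300, frac_pairs = 0)
  res <- suppressMessages(run_unseg(b$image))
  expect_equal(res$manifest$n_nuclei, 12)
  m <- match_objects(res$nuclei, b$gt_nuclei, 0.7)
  expect_equal(m$TP, 12)                      # every nucleus IoU >= 0.7
  b2 <- small_bundle(seed = 22, n_cells = 20, size = 380, frac_pairs = 0.5)
  res2 <- suppressMessages(run_unseg(b2$image))
  expect_equal(res2$manifest$n_nuclei, 20)
})

test_that("segment_nuclei is deterministic and empty-safe", {
  empty <- matrix(0L, 40, 40)
  expect_equal(segment_nuclei(empty, empty, unseg_params()), empty)
  b <- small_bundle(seed = 23, n_cells = 6, size = 160)
  sem <- unseg:::semantic_stage(b$image, unseg_params())
  n1 <- segment_nuclei(sem$Mg, sem$Ml, unseg_params())
  n2 <- segment_nuclei(sem$Mg, sem$Ml, unseg_params())
  expect_identical(n1, n2)
  # instances are pairwise disjoint by construction and 8-connected
  for (i in unique(n1[n1 > 0]))
    expect_equal(max(cc_label(n1 == i, 8L)), 1L)
})
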