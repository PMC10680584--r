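test_that("a nucleus inside a complete membrane ring fills the ring", {
  b <- small_bundle(seed = 30, n_cells = 6, size = 200,
                    membrane_completeness = 1, frac_membrane_free = 0,
                    frac_nucleus_free = 0)
  res <- suppressMessages(run_unseg(b$image))
  m <- match_objects(res$cells, b$gt_cells, 0.8)
  expect_gte(m$TP / length(unique(b$gt_cells[b$gt_cells > 0])), 0.8)
  expect_true(all(res$records$origin == "expanded"))
})

test_that("nuclei without membrane evidence fall back to u0-dilation", {
  # single isolated disk nucleus, no membrane anywhere
  nuc <- matrix(0L, 60, 60)
  nuc[draw_disk(matrix(FALSE, 60, 60), c(30, 30), 8)] <- 1L
  p <- unseg_params()
  cells <- expand_nuclei_to_cells(nuc, matrix(FALSE, 60, 60),
                                  matrix(0, 60, 60), p)
  expect_equal(cells > 0, unseg:::dilate_disk(nuc > 0, p$u0))
  expect_equal(attr(cells, "records")$origin, "dilated_fallback")
})

test_that("adjacent cells sharing a wall stay disjoint and meet at the wall", {
  b <- generate_cluster(2L, radius = 11, center_distance_factor = 1.7, seed = 2)
  res <- suppressMessages(run_unseg(b$image))
  expect_equal(res$manifest$n_nuclei, 2)
  expect_equal(res$manifest$n_cells, 2)
  # disjointness is structural; check both nuclei sit in their own cell
  for (i in 1:2) {
    inside <- res$cells[res$nuclei == i]
    expect_true(all(inside == inside[1]) && inside[1] > 0)
  }
})

test_that("nucleus-free cell detection follows the contour/Euler/area rules", {
  p <- unseg_params()
  ring <- function(nr, nc, ctr, rad, width) {
    outer_d <- draw_disk(matrix(FALSE, nr, nc), ctr, rad)
    inner_d <- draw_disk(matrix(FALSE, nr, nc), ctr, rad - width)
    outer_d & !inner_d
  }
  none <- matrix(0L, 70, 70)
  # closed ring enclosing ~400 px (rad 12.3), mean nucleus area 300
  M <- ring(70, 70, c(35, 35), 14, 3)
  out <- detect_nucleus_free_cells(M, none, 300, p)
  expect_length(out, 1)
  expect_gt(sum(out[[1]]), 300 / 2)
  expect_equal(sum(out[[1]]), sum(unseg:::dilate_disk(out[[1]], 0)))  # mask sane
  # open arc: Euler number 1, no enclosure, nothing emitted
  arc <- M; arc[1:35, ] <- FALSE
  expect_length(detect_nucleus_free_cells(arc, none, 300, p), 0)
  # small ring enclosing ~100 px fails the half-mean-area rule
  Msmall <- ring(70, 70, c(35, 35), 7, 3)
  expect_length(detect_nucleus_free_cells(Msmall, none, 300, p), 0)
  # overlap with existing cells suppresses the candidate
  taken <- matrix(0L, 70, 70)
  taken[draw_disk(matrix(FALSE, 70, 70), c(35, 35), 13)] <- 1L
  expect_length(detect_nucleus_free_cells(M, taken, 300, p), 0)
})

test_that("segment_cells combines nucleated and membrane-only cells", {
  b <- small_bundle(seed = 31, n_cells = 12, size = 300,
                    frac_nucleus_free = 0.25, frac_membrane_free = 0)
  res <- suppressMessages(run_unseg(b$image))
  n_rings <- sum(b$info$kind == "ring_only")
  expect_gt(n_rings, 0)
  rec <- res$records
  expect_equal(sum(rec$nucleus_id > 0), res$manifest$n_nuclei)
  expect_equal(sum(rec$origin == "membrane_only"), n_rings)
  # empty input: empty output
  e <- matrix(0L, 30, 30)
  out <- segment_cells(e, e, matrix(0, 30, 30), unseg_params())
  expect_equal(max(out), 0L)
})

test_that("every nucleus lies inside exactly one cell, cells disjoint", {
  for (s in c(32, 33)) {
    b <- small_bundle(seed = s, n_cells = 10, size = 240, frac_pairs = 0.4)
    res <- suppressMessages(run_unseg(b$image))
    nuc <- res$nuclei; cells <- res$cells
    expect_true(all(cells[nuc > 0] > 0))
    cross <- table(nuc[nuc > 0], cells[nuc > 0])
    expect_true(all(rowSums(cross > 0) == 1))
    # each expanded cell contains at most one nucleus
    expect_true(all(colSums(cross > 0) <= 1))
  }
})
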