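test_that("three-class Otsu matches the exhaustive pair-search oracle", {
  set.seed(11)
  for (k in 1:3) {
    x <- c(runif(200, 0, 0.15), runif(150, 0.3, 0.5), runif(100, 0.7, 1))
    expect_identical(otsu_thresholds(x, 3L), as.integer(otsu3_oracle(x)))
  }
})

test_that("initial foreground covers bright disks and is empty on zeros", {
  set.seed(2)
  m <- matrix(FALSE, 96, 96)
  m <- draw_disk(m, c(25, 25), 10)
  m <- draw_disk(m, c(65, 60), 12)
  I <- ifelse(m, 0.8, 0.05) + matrix(rnorm(96 * 96, 0, 0.01), 96)
  I <- pmin(pmax(I, 0), 1)
  fg <- initial_foreground(I, sigma = 3)
  expect_gt(mean(fg[m]), 0.95)              # mask covers the disks
  expect_lt(mean(fg[!m]), 0.15)             # and little of the background
  expect_false(any(initial_foreground(matrix(0, 32, 32) + 0, sigma = 3)))
})

test_that("a-priori probability is the foreground intensity CDF", {
  I <- matrix(c(0.2, 0.5, 0.9, 0.1, 0.5, 0.95), 2)
  fg <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2)
  Pe <- apriori_probability(I, fg)
  expect_equal(Pe[1, 3], 2 / 3)             # query 0.5 on sample {0.2,0.5,0.9}
  expect_equal(Pe[1, 2], 1)                 # foreground maximum
  expect_equal(Pe[2, 3], 1)                 # above the maximum stays 1
  # monotone in intensity
  o <- order(I)
  expect_true(all(diff(Pe[o]) >= 0))
  expect_error(apriori_probability(I, fg & FALSE), "foreground")
})

test_that("LMSF matches the double-loop oracle bit-exactly", {
  set.seed(3)
  I <- matrix(runif(256), 16, 16)
  expect_identical(lmsf(I, 0.5, 2L), lmsf_oracle(I, 0.5, 2))
  expect_identical(lmsf(I, 0.7, 5L), lmsf_oracle(I, 0.7, 5))
})

test_that("LMSF keeps constant images, isolated peaks, and never increases", {
  const <- matrix(0.4, 12, 12)
  expect_equal(lmsf(const, 0.5, 3L), const)       # ratio 1 everywhere
  expect_equal(lmsf(lmsf(const, 0.5, 3L), 0.5, 3L), const)  # idempotent here
  peak <- matrix(0, 15, 15); peak[8, 8] <- 1
  out <- lmsf(peak, 0.5, 5L)
  expect_equal(out[8, 8], 1)                      # ratio 121 >= 0.5
  expect_equal(sum(out), 1)
  set.seed(4)
  I <- matrix(runif(400), 20, 20)
  expect_true(all(lmsf(I, 0.5, 3L) <= I))
})

test_that("global mask zeroes valleys and applies the prior refinement", {
  # two bright blobs separated by a 6-px dark valley
  I <- matrix(0, 40, 60)
  I[10:30, 10:24] <- 0.8
  I[10:30, 31:45] <- 0.8
  Pe <- matrix(1, 40, 60)
  Mg <- global_mask(I, Pe, t0 = 0.5, n0_list = c(5L, 10L), p_min = 0.01)
  expect_false(any(Mg[15:25, 26:29]))             # valley suppressed
  expect_true(all(Mg[15:25, 12:20]))              # blob interiors kept
  # uniform bright image: no valleys, all ones
  expect_true(all(global_mask(matrix(0.7, 20, 20), matrix(1, 20, 20))))
  # prior refinement: surviving pixel with Pe below threshold drops out
  Pe2 <- Pe; Pe2[15, 15] <- 0.005
  Mg2 <- global_mask(I, Pe2, 0.5, c(5L, 10L), 0.01)
  expect_false(Mg2[15, 15])
  expect_true(Mg[15, 15])
})

test_that("GAS matches the per-pixel oracle and preserves edges", {
  const <- matrix(0.3, 10, 10)
  expect_equal(gas(const, 1), const)
  set.seed(5)
  I <- matrix(runif(256), 16, 16)
  expect_lt(max(abs(gas(I, 1) - gas_oracle(I, 1))), 1e-12)
  # step edge: GAS keeps a sharper gradient than a plain 3x3 box filter
  step <- matrix(0, 20, 20); step[, 11:20] <- 1
  g <- gas(step, 1)
  box <- matrix(0, 20, 20)
  pad <- function(M) cbind(M[, 1], M, M[, 20])[c(1, 1:20, 20), ]
  P <- pad(step)
  for (dx in 0:2) for (dy in 0:2) box <- box + P[dx + 1:20, dy + 1:20]
  box <- box / 9
  grad <- function(M) max(abs(M[, 11] - M[, 10]))
  expect_gte(grad(g), grad(box))
})

test_that("local Otsu mask matches brute force and respects restriction", {
  set.seed(6)
  I <- matrix(runif(81, 0, 1), 9, 9)
  expect_identical(local_mask(I, 2L), local_otsu_oracle(I, 2) == 1L)
  # restriction: pixels outside the global mask are always 0
  Mg <- matrix(FALSE, 9, 9); Mg[1:4, ] <- TRUE
  restricted <- local_mask(I, 2L, Mg)
  expect_false(any(restricted[5:9, ]))
  # zero-variance neighbourhood yields background
  expect_false(any(local_mask(matrix(0.5, 9, 9), 2L)))
})

test_that("local masks are subsets of global masks on a full fixture", {
  b <- small_bundle(seed = 9, n_cells = 6, size = 160)
  sem <- unseg:::semantic_stage(b$image, unseg_params())
  expect_true(all(sem$M1g[sem$M1l]))
  expect_true(all(sem$M2g[sem$M2l]))
})
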