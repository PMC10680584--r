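make_fields <- function(nr = 6, nc = 6) {
  list(P1 = matrix(0, nr, nc), P2 = matrix(0, nr, nc))
}

test_that("contrast likelihood follows the signed-contrast definition", {
  I1 <- matrix(c(0.5, 0.8, 0.2, 0.0), 2)
  I2 <- matrix(c(0.5, 0.0, 0.6, 0.0), 2)
  img <- two_channel_image(I1, I2, normalize = FALSE)
  M <- matrix(TRUE, 2, 2)
  L <- contrast_likelihood(img, M, M, M, M)
  expect_equal(L[1, 1], 0)                     # equal channels: no contrast
  expect_equal(L[2, 1], -1)                    # pure nucleus signal
  expect_equal(L[1, 2], 0.4 / 0.8)             # (0.6-0.2)/(0.6+0.2)
  expect_true(all(L >= -1 & L <= 1))
  # sign gating by the global masks
  Mg1 <- matrix(FALSE, 2, 2)
  L2 <- contrast_likelihood(img, M, M, Mg1, M)
  expect_equal(L2[2, 1], 0)                    # nucleus evidence needs M1g
  expect_equal(L2[1, 2], 0.5)
  # empty local mask support falls back to zero minimum with a warning
  expect_warning(contrast_likelihood(img, M & FALSE, M, M, M), "empty")
})

test_that("prior saturation sets local-mask pixels to one and keeps the rest", {
  Pe <- matrix(c(0.3, 0.6, 0.1, 0.9), 2)
  Ml <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  Ps <- saturate_prior(Pe, Ml)
  expect_equal(Ps, matrix(c(1, 0.6, 0.1, 1), 2))
  expect_equal(saturate_prior(Pe, Ml & FALSE), Pe)
})

test_that("posterior global fields realize the convex combination", {
  f <- make_fields(2, 2)
  P1s <- matrix(c(0.4, 1, 0.2, 0.5), 2)
  P2s <- matrix(c(0.3, 0.3, 0.8, 0.5), 2)
  L <- matrix(c(-0.5, -0.5, 0.25, 0), 2)
  pg <- posterior_global(P1s, P2s, L)
  expect_equal(pg$P1g[1, 1], 0.4 + 0.6 * 0.5)  # 0.7
  expect_equal(pg$P1g[2, 1], 1)                # saturation fixed point
  expect_equal(pg$P2g[1, 2], 0.8 + 0.2 * 0.25)
  expect_equal(pg$P1g[2, 2], 0)                # L = 0 pixel
  expect_equal(pg$P2g[2, 2], 0)
  expect_true(all(pg$P1g * pg$P2g == 0))       # exclusivity
})

test_that("posterior exclusivity and bounds hold on random fields", {
  set.seed(10)
  for (k in 1:10) {
    P1s <- matrix(runif(100), 10)
    P2s <- matrix(runif(100), 10)
    L <- matrix(runif(100, -1, 1), 10)
    pg <- posterior_global(P1s, P2s, L)
    expect_true(all(pg$P1g >= 0 & pg$P1g <= 1))
    expect_true(all(pg$P2g >= 0 & pg$P2g <= 1))
    expect_true(all(pg$P1g * pg$P2g == 0))
    expect_true(all(pg$P1g[L < 0] >= P1s[L < 0]))   # monotone enhancement
  }
})

test_that("posterior local fields restrict priors to the local masks", {
  P1e <- matrix(c(0.8, 0.2), 1)
  P2e <- matrix(c(0.5, 0.6), 1)
  M1l <- matrix(c(TRUE, FALSE), 1)
  M2l <- matrix(c(FALSE, TRUE), 1)
  pl <- posterior_local(P1e, P2e, M1l, M2l)
  expect_equal(pl$P1l, matrix(c(0.8, 0), 1))
  expect_equal(pl$P2l, matrix(c(0, 0.6), 1))
  # disjoint local masks: at most one field positive per pixel
  expect_true(all(pl$P1l * pl$P2l == 0))
})

test_that("argmax labels obey the background constraint and nucleus ties", {
  P1 <- matrix(c(0, 0.7, 0, 0.4), 2)
  P2 <- matrix(c(0, 0, 0.7, 0.4), 2)
  lab <- semantic_labels(P1, P2)
  expect_equal(lab, matrix(c(0L, 1L, 2L, 1L), 2))  # tie goes to nucleus
})

test_that("kmeans labelling agrees with argmax on separated clouds", {
  set.seed(12)
  n <- 200
  P1 <- matrix(0, 30, 30); P2 <- matrix(0, 30, 30)
  idx <- sample(900, n)          # remaining pixels form the (0,0) background
  P1[idx] <- c(runif(n / 2, 0.8, 1), runif(n / 2, 0, 0.1))
  P2[idx] <- c(runif(n / 2, 0, 0.1), runif(n / 2, 0.8, 1))
  expect_equal(semantic_labels(P1, P2, "kmeans", seed = 5),
               semantic_labels(P1, P2, "argmax"))
})

test_that("argmax on posterior-local fields reproduces the local supports", {
  b <- small_bundle(seed = 13, n_cells = 5, size = 160)
  sem <- unseg:::semantic_stage(b$image, unseg_params())
  lab <- semantic_labels(sem$P1l, sem$P2l)
  only1 <- sem$M1l & !sem$M2l & sem$P1l > 0
  only2 <- sem$M2l & !sem$M1l & sem$P2l > 0
  expect_true(all(lab[only1] == 1L))
  expect_true(all(lab[only2] == 2L))
})
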