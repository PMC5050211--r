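test_that("isotropic input passes through upsampling unchanged", {
  set.seed(1)
  st <- stack1(array(runif(4 * 4 * 4), c(4, 4, 4)), 0.5)
  expect_identical(upsample_to_isotropic(st), st)
})

test_that("z upsampling interpolates linearly at inserted slice centres", {
  a <- array(0, c(1, 2, 3, 3))
  a[1, 2, , ] <- 10
  st <- image_stack(a, c(1.0, 0.5, 0.5), "constitutive")
  up <- upsample_to_isotropic(st)
  expect_equal(up$spacing_um, c(0.5, 0.5, 0.5))
  expect_identical(dim(up$voxels)[2], 3L)
  expect_true(all(up$voxels[1, 1, , ] == 0))
  expect_true(all(up$voxels[1, 2, , ] == 5))   # midpoint slice
  expect_true(all(up$voxels[1, 3, , ] == 10))
})

test_that("upsampling preserves constants and never overshoots the range", {
  cst <- image_stack(array(3.5, c(1, 5, 4, 4)), c(2, 0.5, 0.5), "c")
  expect_true(all(upsample_to_isotropic(cst)$voxels == 3.5))
  set.seed(2)
  st <- image_stack(array(runif(6 * 8 * 8, -2, 9), c(1, 6, 8, 8)),
                    c(1.0, 0.4, 0.4), "c")
  up <- upsample_to_isotropic(st)
  expect_gte(min(up$voxels), min(st$voxels))
  expect_lte(max(up$voxels), max(st$voxels))
})

test_that("anisotropic lateral spacing is an unsupported geometry", {
  st <- image_stack(array(0, c(1, 2, 2, 2)), c(1, 0.5, 0.6), "c")
  expect_error(upsample_to_isotropic(st), "y and x spacings differ")
})

test_that("the averaging filter preserves constants and spreads an impulse uniformly", {
  cst <- stack1(array(4, c(5, 5, 5)))
  expect_equal(smooth_stack(cst, 1)$voxels, cst$voxels)

  a <- array(0, c(7, 7, 7)); a[4, 4, 4] <- 27
  sm <- smooth_stack(stack1(a), 1)$voxels[1, , , ]
  expect_equal(sm[3:5, 3:5, 3:5], array(1, c(3, 3, 3)))
  expect_equal(sum(sm), 27)
  expect_error(smooth_stack(cst, -1), ">= 0")
})

test_that("reflect-padded smoothing matches direct summation, corners included", {
  set.seed(3)
  a <- array(runif(125), c(5, 5, 5))
  got <- smooth_stack(stack1(a), 1)$voxels[1, , , ]
  expect_equal(got, box_brute(a, 1), tolerance = 1e-12)
  ## corner impulse specifically
  b <- array(0, c(5, 5, 5)); b[1, 1, 1] <- 27
  got_b <- smooth_stack(stack1(b), 1)$voxels[1, , , ]
  expect_equal(got_b, box_brute(b, 1), tolerance = 1e-12)
  expect_equal(got_b[1, 1, 1], 8)   # mirror padding folds 8 copies into the corner
})

test_that("three-class Otsu agrees exactly with exhaustive search on random histograms", {
  set.seed(4)
  for (rep in 1:30) {
    nb <- sample(8:64, 1)
    counts <- rpois(nb, lambda = sample(c(2, 20, 200), nb, replace = TRUE))
    counts[sample(nb, 3)] <- counts[sample(nb, 3)] + 50  # ensure 3 nonempty
    mids <- sort(runif(nb, 0, 255))
    got <- otsu3_thresholds(counts, mids)
    want <- otsu3_brute(counts, mids)
    expect_equal(got$t1, want$t1)
    expect_equal(got$t2, want$t2)
    expect_equal(got$between_class_variance, want$bcv, tolerance = 1e-9)
  }
})

test_that("three-point histograms are perfectly separated with the smallest threshold pair", {
  h <- numeric(256); h[c(1, 129, 256)] <- 100   # intensities 0, 128, 255
  r <- otsu3_thresholds(h)
  expect_identical(unname(r$class_counts), c(100, 100, 100))
  ## any separating pair is optimal; lexicographically smallest is returned
  expect_equal(r$t1, 0.5)
  expect_equal(r$t2, 128.5)
})

test_that("histograms with fewer than three populated bins are degenerate", {
  expect_error(otsu3_thresholds(c(10, 0, 0, 20)), "degenerate")
  expect_error(otsu3_thresholds(c(5)), "degenerate")
})

test_that("segmentation marks classes two and three as foreground by definition", {
  set.seed(5)
  a <- array(0, c(10, 10, 10))
  a[3:6, 3:6, 3:6] <- 1000
  a <- a + sample(0:50, 1000, replace = TRUE)
  st <- stack1(a)
  m <- segment(st, "constitutive")
  t1 <- attr(m, "thresholds")$t1
  expect_identical(m$voxels, array(a > t1, dim(a)))
  expect_true(all(m$voxels[3:6, 3:6, 3:6]))
})

test_that("adding a constant shifts the thresholds but not the mask", {
  set.seed(6)
  a <- array(sample(0:200, 8^3, replace = TRUE), c(8, 8, 8))
  m0 <- segment(stack1(a), "constitutive")
  m1 <- segment(stack1(a + 50), "constitutive")
  expect_equal(attr(m1, "thresholds")$t1, attr(m0, "thresholds")$t1 + 50,
               tolerance = 1e-9)
  expect_equal(attr(m1, "thresholds")$t2, attr(m0, "thresholds")$t2 + 50,
               tolerance = 1e-9)
  expect_identical(m1$voxels, m0$voxels)
})

test_that("constant or two-valued volumes refuse to segment silently", {
  expect_error(segment(stack1(array(5, c(4, 4, 4))), "constitutive"),
               "degenerate")
  two <- array(rep(c(0, 9), 32), c(4, 4, 4))
  expect_error(segment(stack1(two), "constitutive"), "degenerate")
})

test_that("mask union is commutative, associative, idempotent and monotone", {
  set.seed(7)
  mk <- function() binary_mask(array(runif(64) > 0.5, c(4, 4, 4)), 0.5)
  A <- mk(); B <- mk(); C <- mk()
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), 0.5)
  expect_identical(merge_masks(list(A, empty))$voxels, A$voxels)
  expect_identical(merge_masks(list(A, A))$voxels, A$voxels)
  expect_identical(merge_masks(list(A, B))$voxels, merge_masks(list(B, A))$voxels)
  expect_identical(merge_masks(list(A, merge_masks(list(B, C))))$voxels,
                   merge_masks(list(merge_masks(list(A, B)), C))$voxels)
  expect_gte(sum(merge_masks(list(A, B))$voxels), max(sum(A$voxels), sum(B$voxels)))

  small <- binary_mask(array(FALSE, c(3, 3, 3)), 0.5)
  expect_error(merge_masks(list(A, small)), "shape mismatch")

  ## two disjoint single-voxel masks
  m1 <- binary_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), 1)
  m2v <- array(FALSE, c(2, 2, 2)); m2v[2, 2, 2] <- TRUE
  m2 <- binary_mask(m2v, 1)
  expect_identical(sum(merge_masks(list(m1, m2))$voxels), 2L)
})
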