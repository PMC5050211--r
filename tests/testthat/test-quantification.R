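test_that("a full 10-cube volume dissects into 8 cubes of occupancy 125", {
  m <- binary_mask(array(TRUE, c(10, 10, 10)), 0.2)
  raw <- stack1(array(100, c(10, 10, 10)), 0.2)
  cu <- dissect(m, raw, cube_side_vox = 5)
  expect_identical(nrow(cu), 8L)
  expect_true(all(cu$occupancy_vox == 125L))
  expect_true(all(cu$mean_constitutive == 100))
  ## centres of mass sit at the cube geometric centres
  expect_equal(sort(unique(cu$com_z_um)), c(0.5, 1.5))
  expect_equal(sort(unique(cu$com_y_um)), c(0.5, 1.5))
})

test_that("empty masks and single voxels dissect correctly", {
  raw <- stack1(array(7, c(10, 10, 10)), 0.2)
  empty <- dissect(binary_mask(array(FALSE, c(10, 10, 10)), 0.2), raw, 5)
  expect_identical(nrow(empty), 0L)

  mv <- array(FALSE, c(10, 10, 10)); mv[3, 7, 2] <- TRUE
  cu <- dissect(binary_mask(mv, 0.2), raw, 5)
  expect_identical(nrow(cu), 1L)
  expect_identical(cu$occupancy_vox, 1L)
  expect_equal(cu$mean_constitutive, 7)
  expect_equal(c(cu$com_z_um, cu$com_y_um, cu$com_x_um),
               c(2.5, 6.5, 1.5) * 0.2)
  expect_equal(c(cu$cube_z, cu$cube_y, cu$cube_x), c(0, 1, 0))
})

test_that("dissection partitions the foreground, partial border cubes included", {
  set.seed(8)
  for (rep in 1:3) {
    d <- c(7, 11, 9)          # not multiples of 5: forces partial cubes
    mv <- array(runif(prod(d)) > 0.4, d)
    m <- binary_mask(mv, 0.5)
    raw <- stack1(array(runif(prod(d), 0, 100), d), 0.5)
    cu <- dissect(m, raw, 5)
    expect_identical(sum(cu$occupancy_vox), sum(mv))
    expect_true(all(cu$occupancy_vox >= 1))
    ## intensity totals are conserved too
    expect_equal(sum(cu$occupancy_vox * cu$mean_constitutive),
                 sum(raw$voxels[1, , , ][mv]))
  }
})

test_that("dissection validates shapes and cube side", {
  m <- binary_mask(array(TRUE, c(6, 6, 6)), 0.5)
  raw <- stack1(array(0, c(5, 6, 6)), 0.5)
  expect_error(dissect(m, raw), "shapes differ")
  raw2 <- stack1(array(0, c(6, 6, 6)), 0.5)
  expect_error(dissect(m, raw2, cube_side_vox = 7), "exceeds")
})

test_that("local density is exact on full and empty volumes", {
  full <- binary_mask(array(TRUE, c(20, 20, 20)), 0.5)
  expect_equal(local_density(full, c(5, 5, 5), 3), 1.0)
  none <- binary_mask(array(FALSE, c(20, 20, 20)), 0.5)
  expect_equal(local_density(none, c(5, 5, 5), 3), 0.0)
  expect_error(local_density(full, c(5, 5, 5), 0), "radius")
  expect_error(local_density(full, c(50, 5, 5), 3), "outside")
})

test_that("a half-space boundary point has density one half up to the voxel shell", {
  d <- c(24, 24, 24)
  mv <- array(FALSE, d)
  mv[1:12, , ] <- TRUE           # z below the plane is foreground
  m <- binary_mask(mv, 0.5)
  p <- c(6.0, 6.0, 6.0)          # on the plane (z = 12 * 0.5), deep interior
  got <- local_density(m, p, 3)
  want <- density_brute(mv, 0.5, p, 3)
  expect_equal(got, want)        # exact agreement with enumeration
  expect_lt(abs(got - 0.5), 0.1) # one voxel-shell of discretisation
})

test_that("local density equals brute-force ball enumeration on random cases", {
  set.seed(9)
  for (rep in 1:10) {
    d <- c(10, 12, 11)
    mv <- array(runif(prod(d)) > 0.5, d)
    m <- binary_mask(mv, 0.5)
    p <- runif(3, 1, 4)
    r <- runif(1, 0.8, 2.5)
    expect_identical(local_density(m, p, r), density_brute(mv, 0.5, p, r))
  }
})

test_that("density annotation stays within the unit interval and matches pointwise calls", {
  res <- run_dual_reporter(1, params = scene_params(n_single = 30L,
                                                    n_aggregates = 2L,
                                                    cells_per_aggregate = 40L))
  cu <- res$cubes
  expect_true(all(cu$local_density >= 0 & cu$local_density <= 1))
  i <- which.max(cu$occupancy_vox)
  direct <- local_density(res$merged,
                          c(cu$com_z_um[i], cu$com_y_um[i], cu$com_x_um[i]), 3)
  expect_identical(cu$local_density[i], direct)
})

test_that("cube classification reflects per-channel mask overlap", {
  d <- c(10, 10, 10)
  mv <- array(TRUE, d)
  merged <- binary_mask(mv, 0.5)
  raw <- stack1(array(1, d), 0.5)
  cu <- dissect(merged, raw, 5)

  a <- array(FALSE, d); a[1:5, 1:5, 1:5] <- TRUE          # cube (0,0,0) only
  b <- array(FALSE, d); b[1:5, 1:5, 1:5] <- TRUE; b[6:10, , ] <- TRUE
  cu <- classify_cubes(cu, list(curli = binary_mask(a, 0.5),
                                flagella = binary_mask(b, 0.5)))
  first <- cu$cube_z == 0 & cu$cube_y == 0 & cu$cube_x == 0
  expect_true(all(cu$pos_curli[first]))
  expect_true(all(cu$pos_flagella[first]))                 # overlaps both
  expect_false(any(cu$pos_curli[!first]))
  top <- cu$cube_z == 1
  expect_true(all(cu$pos_flagella[top]))
  expect_error(classify_cubes(cu, list(x = binary_mask(array(FALSE, c(4, 4, 4)), 0.5))),
               "shape mismatch")
})
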