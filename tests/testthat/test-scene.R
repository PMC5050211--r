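test_that("identical parameters and seed reproduce an identical scene", {
  a <- generate_scene(seed = 42)
  b <- generate_scene(seed = 42)
  expect_identical(a, b)
  c <- generate_scene(seed = 43)
  expect_false(identical(a$cells, c$cells))
})

test_that("every cell lies inside the domain and carries one class label", {
  for (s in 1:5) {
    sc <- generate_scene(scene_params(pellicle = TRUE), seed = s)
    cl <- sc$cells
    expect_true(all(cl$center_z_um >= 0 & cl$center_z_um <= sc$domain_size_um[1]))
    expect_true(all(cl$center_y_um >= 0 & cl$center_y_um <= sc$domain_size_um[2]))
    expect_true(all(cl$center_x_um >= 0 & cl$center_x_um <= sc$domain_size_um[3]))
    expect_true(all(cl$class %in% c("single", "aggregate", "pellicle")))
    expect_true(all(cl$timer_green > 0))
  }
})

test_that("curli and flagella are strictly exclusive when the mixing parameter is zero", {
  for (s in 1:10) {
    sc <- generate_scene(scene_params(epsilon_double = 0), seed = s)
    expect_identical(sum(sc$cells$curli_on & sc$cells$flagella_on), 0L)
  }
})

test_that("double-positive fraction converges to the mixing parameter over seeds", {
  eps <- 0.1
  fr <- vapply(1:30, function(s) {
    sc <- generate_scene(scene_params(epsilon_double = eps), seed = s)
    mean(sc$cells$curli_on & sc$cells$flagella_on)
  }, numeric(1))
  n_cells <- nrow(generate_scene(scene_params(epsilon_double = eps), seed = 1)$cells)
  se <- sqrt(eps * (1 - eps) / (n_cells * 30))
  expect_lt(abs(mean(fr) - eps), 3 * se + 1e-12)
})

test_that("curli-ON fraction among aggregate cells follows the binomial draw", {
  p <- 0.9
  par <- scene_params(n_single = 0L, n_aggregates = 5L, cells_per_aggregate = 80L,
                      p_curli_given_aggregate = p)
  fr <- vapply(1:50, function(s) {
    sc <- generate_scene(par, seed = s)
    agg <- sc$cells[sc$cells$class == "aggregate", ]
    mean(agg$curli_on)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (400 * 50))
  expect_lt(abs(mean(fr) - p), 3 * se)
})

test_that("impossible aggregate packing raises an explicit error", {
  expect_error(generate_scene(scene_params(aggregate_radius_um = 40),
                              domain_size_um = c(64, 64, 64)),
               "packing")
  expect_error(generate_scene(scene_params(n_aggregates = 100L,
                                           aggregate_radius_um = 10)),
               "packing")
})

test_that("aggregate cells are mutually closer than dispersed singles", {
  nn_dist <- function(p) {
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  for (s in 1:3) {
    sc <- generate_scene(seed = s)
    cl <- sc$cells
    pa <- as.matrix(cl[cl$class == "aggregate", 1:3])
    ps <- as.matrix(cl[cl$class == "single", 1:3])
    expect_lt(nn_dist(pa), nn_dist(ps))
  }
})

test_that("scene truth summary reports classes, fractions and timer ordering", {
  sc <- generate_scene(scene_params(n_single = 100L, n_aggregates = 0L), seed = 3)
  tr <- scene_truth_summary(sc)
  expect_identical(as.integer(tr$class_counts["single"]), 100L)
  expect_identical(length(tr$class_counts), 1L)

  sc2 <- generate_scene(seed = 4)
  tr2 <- scene_truth_summary(sc2)
  expect_identical(tr2$frac_double_positive, 0)
  expect_gt(tr2$mean_timer_ratio_by_class["aggregate"],
            tr2$mean_timer_ratio_by_class["single"])
  expect_equal(unname(tr2$mean_timer_ratio_by_class["aggregate"]), 2.0)
  expect_equal(unname(tr2$mean_timer_ratio_by_class["single"]), 0.5)
})

test_that("probability and count parameters are validated", {
  expect_error(scene_params(p_curli_given_single = 1.2), "probability")
  expect_error(scene_params(epsilon_double = -0.1), "probability")
  expect_error(scene_params(rho_sigmaS = 2), "rho_sigmaS")
  expect_error(scene_params(n_single = -5), "nonnegative")
})

test_that("pellicle cells occupy a slab at the top of the domain", {
  sc <- generate_scene(scene_params(pellicle = TRUE, n_pellicle = 50L,
                                    pellicle_thickness_um = 3), seed = 9)
  pel <- sc$cells[sc$cells$class == "pellicle", ]
  expect_identical(nrow(pel), 50L)
  expect_true(all(pel$center_z_um >= sc$domain_size_um[1] - 3))
  expect_equal(sc$pellicle_z_um, sc$domain_size_um[1] - 1.5)
})
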