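test_that("background subtraction removes the control median and keeps negatives", {
  ev <- data.frame(gfp = c(120, 30, 55))
  ctrl <- data.frame(gfp = c(48, 50, 52))
  out <- subtract_background(ev, ctrl, "gfp")
  expect_equal(out$gfp, c(70, -20, 5))
  self <- subtract_background(ev, ev, "gfp")
  expect_equal(median(self$gfp), 0)
  expect_error(subtract_background(ev, data.frame(gfp = numeric()), "gfp"),
               "empty control")
})

test_that("background subtraction is shift-equivariant", {
  set.seed(13)
  ev <- data.frame(gfp = rnorm(200, 100, 20))
  ctrl <- data.frame(gfp = rnorm(100, 40, 5))
  a <- subtract_background(ev, ctrl, "gfp")
  ev2 <- ev; ev2$gfp <- ev2$gfp + 37
  ctrl2 <- ctrl; ctrl2$gfp <- ctrl2$gfp + 37
  b <- subtract_background(ev2, ctrl2, "gfp")
  expect_equal(a$gfp, b$gfp, tolerance = 1e-12)
})

test_that("the biexponential transform is odd, zero-fixed and logarithmic at large argument", {
  expect_identical(biex_transform(0), 0)
  x <- c(1, 10, 500, 1e4, 3e5)
  expect_equal(biex_transform(-x), -biex_transform(x))
  ## large-argument expansion: asinh(u) -> ln(2u)
  expect_lt(abs(biex_transform(1e4) - log10(2 * 1e4 / 150)), 1e-4)
  expect_error(biex_transform(1, cofactor = 0), "cofactor")
})

test_that("the biexponential transform inverts to ten-digit relative accuracy", {
  x <- c(-1e6, -12345.6, -150, -1, -1e-3, 0, 1e-3, 1, 150, 12345.6, 1e6)
  back <- biex_inverse(biex_transform(x))
  expect_equal(back, x, tolerance = 1e-9)
  ## strictly increasing
  expect_true(all(diff(biex_transform(sort(x))) > 0))
})

test_that("gate percentages are exact complements and ties count OFF", {
  ev <- data.frame(gfp = c(-5, 0, 3, 10))
  g <- gate_on_off(ev, "gfp", threshold = biex_transform(100))
  expect_equal(g$fraction_on, 0)
  expect_equal(g$fraction_off, 100)
  g2 <- gate_on_off(ev, "gfp", threshold = biex_transform(-10))
  expect_equal(g2$fraction_on, 100)
  ## an event exactly at the threshold is OFF
  g3 <- gate_on_off(ev, "gfp", threshold = biex_transform(10))
  expect_equal(g3$fraction_on, 0)
  g4 <- gate_on_off(ev, "gfp", threshold = biex_transform(2.9999))
  expect_equal(g4$fraction_on + g4$fraction_off, 100)
  expect_equal(g4$fraction_on, 50)
  expect_error(gate_on_off(data.frame(gfp = numeric()), "gfp"), "empty")
})

test_that("auto-gating recovers the seeded ON fraction of a separated mixture", {
  errs <- vapply(1:20, function(s) {
    ev <- generate_events(mixture_params(f_on = 0.30, n_events = 50000L, seed = s))
    g <- gate_on_off(ev, "reporter")
    g$fraction_on - 100 * mean(ev$truth == "ON")
  }, numeric(1))
  expect_true(all(abs(errs) < 1.5))
  expect_lt(mean(abs(errs)), 1)
})

test_that("gating error grows as the mixture modes approach", {
  mae_at <- function(mu_on) {
    mean(vapply(1:6, function(s) {
      ev <- generate_events(mixture_params(mu_on = mu_on, n_events = 20000L,
                                           seed = s))
      abs(gate_on_off(ev, "reporter")$fraction_on -
            100 * mean(ev$truth == "ON"))
    }, numeric(1)))
  }
  wide <- mae_at(log(2000)); mid <- mae_at(log(200)); narrow <- mae_at(log(40))
  expect_lte(wide, mid)
  expect_lt(mid, narrow)
})

test_that("summaries are computed per group on the untransformed scale", {
  ev <- data.frame(gfp = c(1, 2, 3, 100, 200),
                   fraction = c("pellicle", "pellicle", "pellicle",
                                "surface", "surface"),
                   time_h = 24)
  s <- summarize_events(ev, "gfp")
  expect_identical(nrow(s), 2L)
  pel <- s[s$fraction == "pellicle", ]
  expect_equal(pel$mean, 2)
  expect_identical(pel$n, 3L)
  ## transforming first would bias the mean of a skewed sample downward
  skewed <- c(1, 2, 5, 1000)
  expect_lt(mean(biex_transform(skewed)), biex_transform(mean(skewed)))
})

test_that("crystal-violet values are normalised by culture density", {
  expect_equal(normalize_cv(0.8, 0.4), 2.0)
  expect_equal(normalize_cv(0.0, 0.5), 0.0)
  expect_error(normalize_cv(0.3, 0), "od600")
})
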