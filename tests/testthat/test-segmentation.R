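test_that("otsu separates a two-valued image at the known variance maximum", {
  img <- matrix(c(rep(0.2, 40), rep(0.8, 60)), 10, 10)
  t <- otsu_threshold(img)
  expect_gt(t, 0.2)
  expect_lt(t, 0.8)
  ## between-class variance at the chosen split, against direct evaluation
  ## with the binned class means (bin centers of 0.2 and 0.8)
  st <- retinaseg:::otsu_stats(img)
  mu0 <- (floor(0.2 * 256) + 0.5) / 256
  mu1 <- (floor(0.8 * 256) + 0.5) / 256
  expect_equal(max(st$g), 0.4 * 0.6 * (mu0 - mu1)^2, tolerance = 1e-12)
  ## 0.4 * 0.6 * 0.6^2 with the class means shifted to bin centers
  expect_equal(max(st$g), 0.0864, tolerance = 0.01)
})

test_that("otsu rejects constant regions and honours the class-mean identity", {
  expect_error(otsu_threshold(matrix(0.5, 8, 8)), "constant")
  set.seed(66)
  img <- matrix(runif(64 * 64), 64, 64)
  st <- retinaseg:::otsu_stats(img)
  expect_lt(max(abs(st$w0 + st$w1 - 1)), 1e-12)
  ## overall mean mu = w0 mu0 + w1 mu1 at every scanned split
  q <- pmin(floor(img * 256), 255)
  mu <- mean((q + 0.5) / 256)
  expect_lt(max(abs(st$w0 * st$mu0 + st$w1 * st$mu1 - mu)), 1e-12)
})

test_that("between-class maximization equals within-class minimization", {
  set.seed(67)
  for (rep in 1:20) {
    img <- matrix(runif(64 * 64)^runif(1, 0.5, 2), 64, 64)
    t <- otsu_threshold(img)
    k_oracle <- within_class_argmin(as.numeric(img))
    expect_equal(t, k_oracle / 256)
  }
})

test_that("otsu restricted to a region ignores outside pixels", {
  img <- matrix(0.9, 16, 16)
  region <- matrix(FALSE, 16, 16)
  region[, 1:8] <- TRUE
  img[, 1:4] <- 0.1
  img[, 5:8] <- 0.7
  t <- otsu_threshold(img, region)
  expect_gt(t, 0.1); expect_lt(t, 0.7)
  expect_error(otsu_threshold(img, matrix(FALSE, 16, 16)), "empty")
})

test_that("pipeline_config validates its fields", {
  expect_s3_class(pipeline_config(), "pipeline_config")
  expect_error(pipeline_config(s_min = -1), "positive|s_min")
  expect_error(pipeline_config(s_min = 5, s_max = 2), "s_min")
  expect_error(pipeline_config(noise_floor_q = 1.2), "noise_floor_q")
})

## Small, fast phantom study conditions for the pipeline tests.
small_spec <- function(...) {
  phantom_spec(seed = 9, size = 160, fov_radius = 66, n_vessels = 3,
               noise_sd = 0, ...)
}

test_that("segment is deterministic and silent outside the FOV", {
  ph <- make_phantom(small_spec())
  s1 <- segment(ph$rgb, fov = ph$fov)
  s2 <- segment(ph$rgb, fov = ph$fov)
  expect_identical(s1$mask, s2$mask)
  expect_false(any(s1$mask[!ph$fov]))
  expect_gt(dice(s1$mask, ph$truth, ph$fov), 0.7)
})

test_that("stage failures are labelled with the failing stage", {
  ph <- make_phantom(small_spec())
  expect_error(segment(ph$rgb, fov = matrix(FALSE, 160, 160)), "stage")
  expect_error(segment(array(2, c(32, 32, 3))), "input")
})

test_that("morphology only removes bright structure, never adds vessels", {
  ph <- make_phantom(small_spec())
  with_m <- segment(ph$rgb, fov = ph$fov, config = pipeline_config())
  without_m <- segment(ph$rgb, fov = ph$fov,
                       config = pipeline_config(morphology = FALSE))
  ## opened response <= raw response pixelwise, so at any common threshold the
  ## opened mask is a subset of the raw one and cannot gain true positives
  expect_true(all(with_m$response <= without_m$response + 1e-15))
  t <- with_m$threshold
  tp_raw <- confusion(without_m$response > t & ph$fov, ph$truth, ph$fov)$tp
  tp_open <- confusion(with_m$response > t & ph$fov, ph$truth, ph$fov)$tp
  expect_gte(tp_raw, tp_open)
})

test_that("the classic-vesselness baseline runs end to end", {
  ph <- make_phantom(small_spec())
  s <- segment(ph$rgb, fov = ph$fov, config = pipeline_config(baseline = TRUE))
  expect_false(any(s$mask[!ph$fov]))
  expect_gt(confusion(s$mask, ph$truth, ph$fov)$tp, 0)
})

test_that("noise estimation recovers the injected level", {
  set.seed(68)
  flat <- matrix(0.5, 128, 128) + matrix(rnorm(128^2, 0, 0.02), 128, 128)
  expect_equal(estimate_noise_sd(flat), 0.02, tolerance = 0.15)
  ramp <- outer(seq(0, 1, length.out = 128), seq(0, 1, length.out = 128), "+") / 2
  expect_lt(estimate_noise_sd(ramp), 1e-3)
})
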