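test_that("gaussian_smooth preserves constants and the impulse peak height", {
  expect_equal(gaussian_smooth(matrix(0.3, 16, 16), 2), matrix(0.3, 16, 16),
               tolerance = 1e-12)
  n <- 65
  imp <- matrix(0, n, n); imp[33, 33] <- 1
  for (s in c(1, 2)) {
    peak <- gaussian_smooth(imp, s)[33, 33]
    expect_lt(abs(peak - 1 / (2 * pi * s^2)) / (1 / (2 * pi * s^2)), 0.01)
  }
  expect_error(gaussian_smooth(imp, 0), "positive")
  expect_error(gaussian_smooth(imp, -1), "positive")
})

test_that("separable smoothing equals full 2-D convolution", {
  set.seed(21)
  img <- matrix(runif(16 * 16), 16, 16)
  s <- 1.3
  g <- retinaseg:::gaussian_kernel_1d(s, 0L)
  expect_lt(max(abs(gaussian_smooth(img, s) - naive_conv2(img, outer(g, g)))),
            1e-10)
})

test_that("hessian_at_scale matches analytic second derivatives", {
  ## constant image: all derivatives vanish
  h0 <- hessian_at_scale(matrix(0.7, 32, 32), 2)
  expect_lt(max(abs(h0$ixx), abs(h0$ixy), abs(h0$iyy)), 1e-12)

  ## quadratic ramp I = x^2: scale-normalized ixx = 2 s^2
  img <- outer(rep(1, 64), (1:64)^2)
  for (s in c(1, 2, 4)) {
    h <- hessian_at_scale(img, s)
    ctr <- h$ixx[29:36, 29:36]
    expect_lt(max(abs(ctr - 2 * s^2)) / (2 * s^2), 0.01)
    expect_lt(max(abs(h$ixy[29:36, 29:36])), 1e-8)
    expect_lt(max(abs(h$iyy[29:36, 29:36])), 1e-8)
  }

  ## rotationally symmetric blob: mixed derivative vanishes at the center
  n <- 41; x <- seq_len(n) - 21
  blob <- exp(-outer(x^2, x^2, "+") / (2 * 4^2))
  expect_lt(abs(hessian_at_scale(blob, 1.5)$ixy[21, 21]), 1e-8)
  expect_error(hessian_at_scale(blob, 0), "positive")
})

test_that("eigen2x2 orders by magnitude with the signed tie-break", {
  mk <- function(ixx, ixy, iyy)
    structure(list(ixx = matrix(ixx, 1, 1), ixy = matrix(ixy, 1, 1),
                   iyy = matrix(iyy, 1, 1), scale = 1), class = "hessian_field")
  e <- eigen2x2(mk(3, 0, 1))
  expect_equal(c(e$lam1[1, 1], e$lam2[1, 1]), c(3, 1))
  ## |+1| = |-1| tie: the larger signed value comes first
  e <- eigen2x2(mk(0, 1, 0))
  expect_equal(c(e$lam1[1, 1], e$lam2[1, 1]), c(1, -1))
})

test_that("eigen2x2 agrees with the characteristic-polynomial roots", {
  set.seed(33)
  n <- 1000
  h <- structure(list(ixx = matrix(rnorm(n), 1), ixy = matrix(rnorm(n), 1),
                      iyy = matrix(rnorm(n), 1), scale = 1),
                 class = "hessian_field")
  e <- eigen2x2(h)
  ## quadratic-formula oracle: roots of lam^2 - tr lam + det = 0
  tr <- h$ixx + h$iyy
  det <- h$ixx * h$iyy - h$ixy^2
  root_hi <- (tr + sqrt(tr^2 - 4 * det)) / 2
  root_lo <- (tr - sqrt(tr^2 - 4 * det)) / 2
  scale <- pmax(abs(tr), abs(det), 1)
  expect_lt(max(abs(e$lam1 + e$lam2 - tr) / scale), 1e-9)
  expect_lt(max(abs(e$lam1 * e$lam2 - det) / scale), 1e-9)
  expect_true(all(abs(e$lam1) >= abs(e$lam2) - 1e-12))
  expect_true(all(pmin(abs(e$lam1 - root_hi), abs(e$lam1 - root_lo)) < 1e-9 * scale))
})

test_that("vesselness response point values behave as designed", {
  ## blob-like structure at unit scale: exp(-(pi/4)^2) * (2 / 2)
  expect_equal(improved_response(eigen_point(2, 2), 1)[1, 1],
               exp(-(pi / 4)^2), tolerance = 1e-9)
  ## printed 4-decimal value, at printed precision
  expect_equal(improved_response(eigen_point(2, 2), 1)[1, 1], 0.5397,
               tolerance = 1e-3)
  ## clean tube at the normalizing amplitude: full response
  expect_equal(improved_response(eigen_point(2, 0), 1)[1, 1], 1)
  ## stronger tube clips at 1
  expect_equal(improved_response(eigen_point(5, 0), 1)[1, 1], 1)
  ## amplitude normalization: response scales as lam1 / (2 s)
  expect_equal(improved_response(eigen_point(1, 0), 2)[1, 1], 0.25)
  ## bright ridge or flat: zero
  expect_equal(improved_response(eigen_point(-3, 0), 1)[1, 1], 0)
  expect_equal(improved_response(eigen_point(0, 0), 1)[1, 1], 0)
})

test_that("response is invariant to adding a constant to the image", {
  set.seed(44)
  img <- gaussian_smooth(matrix(runif(48 * 48), 48, 48), 2)
  r1 <- multiscale_response(img, scale_set(1, 3, 1), normalize = FALSE)
  r2 <- multiscale_response(img + 0.17, scale_set(1, 3, 1), normalize = FALSE)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("multiscale maximum dominates each single-scale response", {
  img <- bar_image(61, sigma = 2.5)
  ss <- scale_set(1, 4, 1)
  ms <- multiscale_response(img, ss, normalize = FALSE)
  for (s in as.numeric(ss)) {
    f <- improved_response(eigen2x2(hessian_at_scale(img, s)), s)
    expect_true(all(ms >= f - 1e-12))
  }
  ## singleton scale set: equals the single-scale response exactly
  one <- multiscale_response(img, scale_set(2, 2, 1), normalize = FALSE)
  f2 <- improved_response(eigen2x2(hessian_at_scale(img, 2)), 2)
  expect_equal(unclass(one), f2, ignore_attr = TRUE)

  expect_error(multiscale_response(img, numeric(0)), "empty")
  expect_error(scale_set(3, 1), "s_min")
})

test_that("multiscale response is deterministic and 90-degree equivariant", {
  img <- bar_image(61, sigma = 3)
  r1 <- multiscale_response(img, scale_set(1, 4, 0.5))
  r2 <- multiscale_response(img, scale_set(1, 4, 0.5))
  expect_identical(unclass(r1), unclass(r2))
  rt <- multiscale_response(t(img), scale_set(1, 4, 0.5))
  expect_lt(max(abs(t(unclass(rt)) - unclass(r1))), 1e-6)
})

test_that("the maximizing scale grows with vessel caliber", {
  argmax_center <- function(sigma) {
    img <- bar_image(121, sigma = sigma)
    r <- multiscale_response(img, scale_set(1, 8, 0.5), normalize = FALSE)
    attr(r, "best_scale")[61, 61]
  }
  expect_gt(argmax_center(5), argmax_center(2))
})

test_that("a matched scale outresponds a 4x oversized scale on the centerline", {
  w <- 3
  img <- bar_image(121, sigma = w)
  f_match <- improved_response(eigen2x2(hessian_at_scale(img, w)), w)
  f_big <- improved_response(eigen2x2(hessian_at_scale(img, 4 * w)), 4 * w)
  expect_gt(f_match[61, 61], f_big[61, 61])
})

test_that("classic vesselness baseline responds on the bar and not on flats", {
  expect_equal(traditional_vesselness(matrix(0.4, 32, 32), scale_set(1, 2, 1)),
               matrix(0, 32, 32))
  img <- bar_image(81, sigma = 3)
  v <- traditional_vesselness(img, scale_set(1, 4, 1))
  expect_gt(v[41, 41], v[41, 10])
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
})
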