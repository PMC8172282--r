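#' Estimate additive noise in a grayscale image
#'
#' Robust noise standard deviation from the residual of the 3 x 3 Laplacian
#' difference operator `[1 -2 1; -2 4 -2; 1 -2 1]`, which annihilates locally
#' planar intensity while responding to white noise with a known gain
#' (Immerkaer's method, median-of-absolute-residuals variant so edges and
#' vessels do not inflate the estimate).
#'
#' @param img Numeric matrix.
#' @param region Optional logical matrix; residuals are collected only where
#'   TRUE (e.g. inside the field of view).
#' @return Estimated noise standard deviation (>= 0).
#' @export
estimate_noise_sd <- function(img, region = NULL) {
  assert_gray(img)
  L <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  r <- matrix(0, nrow(img), ncol(img))
  p <- pad_reflect(img, 1L, 1L)
  for (i in 1:3)
    for (j in 1:3)
      r <- r + L[i, j] * p[i:(i + nrow(img) - 1L), j:(j + ncol(img) - 1L)]
  sel <- if (is.null(region)) TRUE else as.logical(region)
  ## Laplacian gain on iid noise: sd multiplies by sqrt(sum(L^2)) = 6.
  stats::median(abs(r[sel])) / (0.6745 * 6)
}

## 99th-percentile (by default) response of pure white noise of unit standard
## deviation pushed through the same multiscale filter, by a fixed-seed
## simulation on a small patch; linear in the noise level, so callers scale
## the returned unit-level quantile by their estimated sigma. The simulation
## runs at a tiny amplitude to stay clear of the [0, 1] response clipping and
## leaves the caller's RNG state untouched.
noise_response_quantile <- function(scales, lambda_floor = 1e-10, q = 0.99,
                                    patch = 96L) {
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(603979L)
  amp <- 0.01
  noise <- matrix(stats::rnorm(patch * patch, 0, amp), patch, patch)
  resp <- multiscale_response(noise, scales, normalize = FALSE,
                              lambda_floor = lambda_floor)
  as.numeric(stats::quantile(resp, q)) / amp
}
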