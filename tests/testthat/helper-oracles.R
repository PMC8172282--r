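## Independent oracles and fixture builders used across the test files.
## These deliberately avoid the package's own code paths (direct 2-D loops,
## endpoint-marching rasterization, brute-force histogram scans).

## Symmetric-reflection index (edge repeated), as a free function for oracles.
oracle_reflect <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n + 1 - i, i)
  i
}

## Full 2-D correlation with reflective borders, quadruple loop.
naive_conv2 <- function(img, K) {
  kr <- (nrow(K) - 1) / 2
  kc <- (ncol(K) - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      acc <- 0
      for (a in seq_len(nrow(K))) {
        for (b in seq_len(ncol(K))) {
          ii <- oracle_reflect(i + a - kr - 1, nrow(img))
          jj <- oracle_reflect(j + b - kc - 1, ncol(img))
          acc <- acc + K[a, b] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

## Brute-force flat grayscale opening: erosion = min of img(p + b) over the
## structuring-element offsets b, dilation = max of eroded(p - b), windows
## clipped to the image domain, computed pixel by pixel.
naive_open <- function(img, offsets) {
  n <- nrow(img); m <- ncol(img)
  lookup <- function(mat, i, j, miss)
    if (i < 1 || i > n || j < 1 || j > m) miss else mat[i, j]
  ero <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      ero[i, j] <- min(vapply(seq_len(nrow(offsets)), function(k)
        lookup(img, i + offsets[k, 1], j + offsets[k, 2], Inf), numeric(1)))
  dil <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      dil[i, j] <- max(vapply(seq_len(nrow(offsets)), function(k)
        lookup(ero, i - offsets[k, 1], j - offsets[k, 2], -Inf), numeric(1)))
  dil
}

## Endpoint-marching DDA rasterizer: walks unit steps along the major axis
## between the two endpoints, accumulating the minor coordinate and rounding
## half-up. Returns a (dr, dc) offset matrix sorted for comparison.
dda_line <- function(length, angle) {
  theta <- angle * pi / 180
  ux <- cos(theta); uy <- sin(theta)
  k0 <- -((length - 1) %/% 2)
  ks <- seq(k0, length.out = length)
  if (abs(ux) >= abs(uy)) {
    slope <- uy / ux
    pts <- cbind(dr = floor(ks * slope + 0.5), dc = ks)
  } else {
    slope <- ux / uy
    pts <- cbind(dr = ks, dc = floor(ks * slope + 0.5))
  }
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

## Plain global histogram equalization with the (cdf - cdf_min) convention.
global_hist_eq <- function(img, bins = 256) {
  q <- pmin(floor(img * bins), bins - 1)
  counts <- tabulate(as.integer(q) + 1L, nbins = bins)
  cdf <- cumsum(counts)
  cmin <- cdf[which(cdf > 0)[1]]
  n <- length(img)
  map <- if (n > cmin) (cdf - cmin) / (n - cmin) else (seq_len(bins) - 0.5) / bins
  matrix(map[as.integer(q) + 1L], nrow(img), ncol(img))
}

## Dark bar with Gaussian cross-section along columns (vertical bar at the
## center column), on a brighter constant background.
bar_image <- function(n = 101, sigma = 3, depth = 0.5, base = 0.8) {
  x <- seq_len(n) - (n + 1) / 2
  base - depth * matrix(rep(exp(-x^2 / (2 * sigma^2)), each = n), n, n)
}

## Small eigen_field from scalar eigenvalues, for point checks of the
## response function.
eigen_point <- function(lam1, lam2) {
  structure(list(lam1 = matrix(lam1, 1, 1), lam2 = matrix(lam2, 1, 1)),
            class = "eigen_field")
}

## Within-class variance over all histogram splits (independent Otsu oracle):
## returns the split index k (threshold k/bins) minimizing
## w0 * var0 + w1 * var1 computed from binned values.
within_class_argmin <- function(v, bins = 256) {
  q <- pmin(floor(v * bins), bins - 1)
  vq <- (q + 0.5) / bins
  wcv <- rep(NA_real_, bins - 1)
  for (k in seq_len(bins - 1)) {
    lo <- vq[q < k]          # bins 0 .. k-1, i.e. values <= k/bins
    hi <- vq[q >= k]
    if (length(lo) == 0 || length(hi) == 0) next
    pvar <- function(x) mean((x - mean(x))^2)
    wcv[k] <- length(lo) / length(v) * pvar(lo) + length(hi) / length(v) * pvar(hi)
  }
  which.min(wcv)
}
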