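## Internal numeric helpers shared across the pipeline.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @keywords internal
is_gray_image <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x))
}

assert_gray <- function(img, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix (grayscale image)", call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop(what, " contains NA or non-finite values", call. = FALSE)
  invisible(img)
}

assert_rgb <- function(rgb, what = "rgb") {
  d <- dim(rgb)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop(what, " must be an H x W x 3 array (RGB image)", call. = FALSE)
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 1))
    stop(what, " must have all values in [0, 1]", call. = FALSE)
  invisible(rgb)
}

## Symmetric (edge-repeating) reflection indices: for n = 4, pad = 2 the row
## order is 2 1 | 1 2 3 4 | 4 3. Requires pad <= n.
reflect_index <- function(n, pad) {
  if (pad > n)
    stop("padding (", pad, ") exceeds image extent (", n, ")", call. = FALSE)
  c(if (pad > 0) pad:1, seq_len(n), if (pad > 0) n:(n - pad + 1))
}

pad_reflect <- function(m, pad_r, pad_c = pad_r) {
  m[reflect_index(nrow(m), pad_r), reflect_index(ncol(m), pad_c), drop = FALSE]
}

## 1-D correlation along image columns (the x direction), reflective border.
## All kernels used in this package are either even-symmetric or products of
## two odd-symmetric factors, so correlation and convolution coincide.
filter_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- pad_reflect(m, 0L, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * p[, i:(i + ncol(m) - 1L), drop = FALSE]
  out
}

## 1-D correlation along image rows (the y direction), reflective border.
filter_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- pad_reflect(m, r, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
  out
}

## Separable filtering: ky along rows (y), kx along columns (x).
filter_sep <- function(m, ky, kx) filter_rows(filter_cols(m, kx), ky)
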