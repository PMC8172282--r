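#' Extract the green channel of a fundus image
#'
#' Blood vessels show the highest contrast against the retinal background in
#' the green channel, which is therefore the working grayscale image for the
#' whole pipeline. The channel is returned verbatim, with no rescaling.
#'
#' @param rgb H x W x 3 numeric array with values in \[0, 1\].
#' @return Numeric H x W matrix (the G channel).
#' @export
extract_green <- function(rgb) {
  assert_rgb(rgb)
  rgb[, , 2]
}

## Fit per-tile clipped-histogram equalization mappings. Kept separate from
## the interpolation step so tests can inspect the clipped histograms.
## clip_limit is a fraction of the tile pixel count; hist_clipped holds the
## histograms after clipping but before redistribution of the excess.
clahe_fit <- function(img, clip_limit, tile_grid, bins) {
  nr <- tile_grid[1]
  nc <- tile_grid[2]
  h <- nrow(img)
  w <- ncol(img)
  edges_r <- round(seq(0, h, length.out = nr + 1))
  edges_c <- round(seq(0, w, length.out = nc + 1))
  q <- pmin(floor(img * bins), bins - 1)          # bin index 0..bins-1
  maps <- array(0, c(bins, nr, nc))
  hist_raw <- array(0, c(bins, nr, nc))
  hist_clipped <- array(0, c(bins, nr, nc))
  clip_count <- matrix(0, nr, nc)
  for (tr in seq_len(nr)) {
    for (tc in seq_len(nc)) {
      tq <- q[(edges_r[tr] + 1):edges_r[tr + 1],
              (edges_c[tc] + 1):edges_c[tc + 1]]
      n <- length(tq)
      counts <- tabulate(as.integer(tq) + 1L, nbins = bins)
      clip <- clip_limit * n
      clipped <- pmin(counts, clip)
      excess <- sum(counts - clipped)
      hist_raw[, tr, tc] <- counts
      hist_clipped[, tr, tc] <- clipped
      clip_count[tr, tc] <- clip
      cdf <- cumsum(clipped + excess / bins)
      cmin <- cdf[which(cdf > 0)[1]]
      ## a tile whose raw histogram occupies < 2 bins carries no contrast to
      ## stretch: map it to the identity (bin centers) so constant regions
      ## stay constant up to one quantization level
      maps[, tr, tc] <- if (sum(counts > 0) >= 2 && n > cmin) {
        pmin(pmax((cdf - cmin) / (n - cmin), 0), 1)
      } else {
        (seq_len(bins) - 0.5) / bins
      }
    }
  }
  list(maps = maps, hist_raw = hist_raw, hist_clipped = hist_clipped,
       clip_count = clip_count, edges_r = edges_r, edges_c = edges_c,
       q = q, tile_grid = c(nr, nc), bins = bins)
}

## Tile-center coordinate and bracketing/weight vectors for one axis.
clahe_axis_weights <- function(edges, n_pix) {
  centers <- (edges[-length(edges)] + 1 + edges[-1]) / 2
  i <- seq_len(n_pix)
  t0 <- findInterval(i, centers)                 # 0 .. n_tiles
  t1 <- pmin(t0 + 1L, length(centers))
  t0 <- pmax(t0, 1L)
  wt <- ifelse(t1 > t0, (i - centers[t0]) / (centers[t1] - centers[t0]), 0)
  list(t0 = t0, t1 = t1, w = pmin(pmax(wt, 0), 1))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-tile histogram equalization with histogram clipping, the clipped excess
#' redistributed uniformly over the bins, and bilinear interpolation between
#' the mappings of neighbouring tile centers. Clipping bounds the slope of
#' each tile's transfer function, which is what keeps CLAHE from amplifying
#' noise the way plain adaptive equalization does; the clip limit is the only
#' contrast parameter.
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param clip_limit Histogram clip limit as a fraction of the tile pixel
#'   count (default 0.01). Values >= 1 disable clipping.
#' @param tile_grid Integer vector `(rows, cols)` of contextual tiles
#'   (default 8 x 8); every tile must be at least 8 x 8 pixels.
#' @param bins Number of histogram bins over \[0, 1\] (default 256).
#' @return Equalized image, same dimensions, values in \[0, 1\].
#' @export
clahe <- function(img, clip_limit = 0.01, tile_grid = c(8, 8), bins = 256) {
  assert_gray(img)
  if (any(img < 0) || any(img > 1)) stop("img values must lie in [0, 1]", call. = FALSE)
  if (!(clip_limit > 0)) stop("clip_limit must be positive", call. = FALSE)
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1))
    stop("tile_grid must be two integers >= 1", call. = FALSE)
  if (nrow(img) < 8 * tile_grid[1] || ncol(img) < 8 * tile_grid[2])
    stop("image too small for ", tile_grid[1], "x", tile_grid[2],
         " tiles: need at least ", 8 * tile_grid[1], "x", 8 * tile_grid[2],
         " pixels (8x8 per tile)", call. = FALSE)
  fit <- clahe_fit(img, clip_limit, tile_grid, bins)
  rw <- clahe_axis_weights(fit$edges_r, nrow(img))
  cw <- clahe_axis_weights(fit$edges_c, ncol(img))
  qi <- as.integer(fit$q) + 1L
  r0 <- rw$t0[row(img)]; r1 <- rw$t1[row(img)]; wr <- rw$w[row(img)]
  c0 <- cw$t0[col(img)]; c1 <- cw$t1[col(img)]; wc <- cw$w[col(img)]
  m <- fit$maps
  out <- (1 - wr) * (1 - wc) * m[cbind(qi, r0, c0)] +
         (1 - wr) * wc       * m[cbind(qi, r0, c1)] +
         wr       * (1 - wc) * m[cbind(qi, r1, c0)] +
         wr       * wc       * m[cbind(qi, r1, c1)]
  matrix(clip01(out), nrow(img), ncol(img))
}

#' Estimate the field-of-view mask from the image itself
#'
#' The retinal disc is bright in the red channel while the surrounding frame
#' is near black, so the FOV is recovered by Otsu-thresholding the red
#' channel, keeping the largest connected component, and filling its holes.
#' Used when no mask file accompanies the image (DRIVE ships masks, STARE
#' does not).
#'
#' @param rgb H x W x 3 numeric array in \[0, 1\].
#' @return Logical H x W matrix, TRUE inside the field of view.
#' @export
fov_from_image <- function(rgb) {
  assert_rgb(rgb)
  red <- rgb[, , 1]
  t <- tryCatch(otsu_threshold(red),
                error = function(e)
                  stop("FOV estimation failed: ", conditionMessage(e), call. = FALSE))
  mask <- red > t
  if (!any(mask)) stop("FOV estimation failed: empty mask", call. = FALSE)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  filled <- EBImage::fillHull(keep * 1) > 0
  if (mean(filled) < 0.01)
    stop("FOV estimation failed: mask covers less than 1% of the image",
         call. = FALSE)
  matrix(as.logical(filled), nrow(red), ncol(red))
}
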