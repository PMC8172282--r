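#' Specification for a synthetic fundus phantom
#'
#' Parameters of the phantom generator. Defaults emulate the image model the
#' segmentation method assumes: dark curvilinear vessels of diameter 2--12 px
#' on a brighter, radially shaded background inside a circular field of view,
#' with additive white noise. Vessel widths are drawn from a thin-skewed Beta
#' distribution over `width_range` (most retinal vessels are thin; mean
#' diameter ~5 px), and the default vessel count gives a vessel fraction of
#' roughly 10--15% of the FOV, typical of fundus photographs.
#'
#' @param seed Integer RNG seed; the phantom is fully reproducible from it.
#' @param size Image side, pixels (square image).
#' @param fov_radius Radius of the circular field of view, pixels.
#' @param n_vessels Number of vessels to draw.
#' @param width_range Vessel diameter range, pixels; must lie within \[2, 12\].
#' @param contrast Green-channel intensity drop at vessel centerlines
#'   (vessels are darker than the background); must be positive.
#' @param bg_gradient Amplitude of the radial illumination falloff.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param jitter Curvature control: s.d. of the perpendicular displacement of
#'   spline control points, as a fraction of chord length. 0 gives straight
#'   vessels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 0L, size = 256L, fov_radius = 110,
                         n_vessels = 6L, width_range = c(2, 12),
                         contrast = 0.3, bg_gradient = 0.1,
                         noise_sd = 0.02, jitter = 0.12) {
  if (!(size >= 32)) stop("size must be at least 32 px", call. = FALSE)
  if (!(fov_radius > 4 && 2 * fov_radius < size))
    stop("fov_radius must fit inside the image", call. = FALSE)
  if (length(width_range) != 2 || width_range[1] > width_range[2] ||
      width_range[1] < 2 || width_range[2] > 12)
    stop("width_range must be within [2, 12] px", call. = FALSE)
  if (!(contrast > 0)) stop("contrast must be positive (dark vessels)", call. = FALSE)
  if (n_vessels < 0 || noise_sd < 0 || bg_gradient < 0 || jitter < 0)
    stop("n_vessels, noise_sd, bg_gradient and jitter must be non-negative",
         call. = FALSE)
  if (width_range[2] >= fov_radius)
    stop("infeasible spec: vessels wider than the field of view", call. = FALSE)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 fov_radius = fov_radius, n_vessels = as.integer(n_vessels),
                 width_range = width_range, contrast = contrast,
                 bg_gradient = bg_gradient, noise_sd = noise_sd,
                 jitter = jitter),
            class = "phantom_spec")
}

## Smooth random centerline inside the FOV disc: endpoints on a circle of
## radius r_end, interior control points jittered perpendicular to the chord,
## interpolated with natural cubic splines and resampled densely.
phantom_centerline <- function(c0, r_end, jitter) {
  a1 <- stats::runif(1, 0, 2 * pi)
  a2 <- a1 + pi + stats::runif(1, -0.8, 0.8)
  p1 <- c0 + r_end * c(cos(a1), sin(a1))
  p2 <- c0 + r_end * c(cos(a2), sin(a2))
  chord <- sqrt(sum((p2 - p1)^2))
  u <- (p2 - p1) / chord
  perp <- c(-u[2], u[1])
  tt <- seq(0, 1, length.out = 5)
  disp <- c(0, stats::rnorm(3, 0, jitter * chord), 0)
  px <- p1[1] + tt * chord * u[1] + disp * perp[1]
  py <- p1[2] + tt * chord * u[2] + disp * perp[2]
  n_dense <- max(16L, as.integer(ceiling(3 * chord)))
  sx <- stats::spline(tt, px, n = n_dense)$y
  sy <- stats::spline(tt, py, n = n_dense)$y
  keep <- sqrt((sx - c0[1])^2 + (sy - c0[2])^2) <= r_end
  cbind(x = sx[keep], y = sy[keep])
}

## Minimum distance from every pixel to the sampled centerline, computed on
## local windows around each sample (Inf far from the vessel).
centerline_distance <- function(size, pts, reach) {
  d2 <- matrix(Inf, size, size)
  ir <- ceiling(reach)
  for (i in seq_len(nrow(pts))) {
    rr <- max(1L, as.integer(floor(pts[i, "y"])) - ir):
          min(size, as.integer(ceiling(pts[i, "y"])) + ir)
    cc <- max(1L, as.integer(floor(pts[i, "x"])) - ir):
          min(size, as.integer(ceiling(pts[i, "x"])) + ir)
    dd <- outer((rr - pts[i, "y"])^2, (cc - pts[i, "x"])^2, "+")
    d2[rr, cc] <- pmin(d2[rr, cc], dd)
  }
  sqrt(d2)
}

#' Generate a synthetic fundus phantom
#'
#' Renders a seeded synthetic fundus-like RGB image with known vessel ground
#' truth: a bright disc (the FOV) with a radial illumination falloff, dark
#' vessels with Gaussian cross-sections (profile s.d. `width/2`, so the
#' intensity drop at the nominal vessel edge is `contrast * exp(-1/2)`), and
#' additive Gaussian noise. The
#' truth mask marks pixels within half a width of a centerline; red and blue
#' channels are scaled copies of the green so channel extraction behaves as
#' on real fundus photographs. The caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `fundus_phantom`: list with `rgb` (H x W x 3),
#'   `truth` and `fov` (logical matrices), `vessels` (per-vessel list of
#'   `width`, `length` in px, and dense `centerline` (x, y) points), and
#'   `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec", call. = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$size
  c0 <- c((n + 1) / 2, (n + 1) / 2)            # (x, y) center
  cols <- matrix(rep(seq_len(n), each = n), n, n)   # x
  rows <- matrix(rep(seq_len(n), times = n), n, n)  # y
  rdist <- sqrt((cols - c0[1])^2 + (rows - c0[2])^2)
  fov <- rdist <= spec$fov_radius

  bg <- 0.62 - spec$bg_gradient * (rdist / spec$fov_radius)^2
  depth <- matrix(0, n, n)
  truth <- matrix(FALSE, n, n)
  vessels <- list()
  if (spec$n_vessels > 0) {
    for (v in seq_len(spec$n_vessels)) {
      w <- spec$width_range[1] +
        diff(spec$width_range) * stats::rbeta(1, 1.2, 3)
      r_end <- spec$fov_radius - w - 3
      pts <- phantom_centerline(c0, r_end, spec$jitter)
      sigma <- w / 2
      d <- centerline_distance(n, pts, reach = 1.5 * w + 1)
      depth <- pmax(depth, spec$contrast * exp(-d^2 / (2 * sigma^2)))
      truth <- truth | (d <= w / 2)
      seg_len <- sum(sqrt(rowSums(diff(pts)^2)))
      vessels[[v]] <- list(width = w, length = seg_len, centerline = pts)
    }
  }
  truth <- truth & fov

  green <- pmin(pmax(bg - depth, 0.05), 0.97)
  red <- clip01(green * 1.4 + 0.18)
  blue <- clip01(green * 0.35)
  outside <- 0.02
  rgb <- array(outside, c(n, n, 3))
  rgb[, , 1][fov] <- red[fov]
  rgb[, , 2][fov] <- green[fov]
  rgb[, , 3][fov] <- blue[fov]
  if (spec$noise_sd > 0)
    rgb <- rgb + stats::rnorm(length(rgb), 0, spec$noise_sd)
  rgb <- clip01(rgb)

  structure(list(rgb = rgb, truth = truth, fov = fov,
                 vessels = vessels, spec = spec),
            class = "fundus_phantom")
}

#' @export
print.fundus_phantom <- function(x, ...) {
  cat(sprintf("fundus_phantom: %dx%d px, %d vessel(s), %.1f%% of FOV is vessel (seed %d)\n",
              x$spec$size, x$spec$size, length(x$vessels),
              100 * sum(x$truth) / max(1, sum(x$fov)), x$spec$seed))
  invisible(x)
}

#' Write a phantom to a directory
#'
#' Writes `image.png`, `truth.png`, `fov.png` and `spec.yaml` (the generator
#' parameters) to `dir`, creating it if needed.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "fundus_phantom"))
    stop("phantom must be a fundus_phantom", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(phantom$rgb, file.path(dir, "image.png"))
  write_mask(phantom$truth, file.path(dir, "truth.png"))
  write_mask(phantom$fov, file.path(dir, "fov.png"))
  sp <- unclass(phantom$spec)
  yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  invisible(dir)
}
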