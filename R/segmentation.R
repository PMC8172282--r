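## Per-split Otsu statistics on the histogram of img restricted to region:
## one row per candidate split t = k/bins (class 0 = bins 1..k). Internal;
## otsu_threshold() picks the argmax of g.
otsu_stats <- function(img, region = NULL, bins = 256) {
  assert_gray(img)
  v <- if (is.null(region)) as.numeric(img) else img[as.logical(region)]
  if (length(v) == 0) stop("empty region", call. = FALSE)
  if (any(v < 0) || any(v > 1)) stop("intensities must lie in [0, 1]", call. = FALSE)
  q <- pmin(floor(v * bins), bins - 1)           # 0 .. bins-1
  counts <- tabulate(as.integer(q) + 1L, nbins = bins)
  if (sum(counts > 0) < 2)
    stop("constant image within region: no valid threshold", call. = FALSE)
  n <- length(v)
  p <- counts / n
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)[-bins]
  w1 <- 1 - w0
  cmu <- cumsum(p * mids)
  mu <- cmu[bins]
  mu0 <- ifelse(w0 > 0, cmu[-bins] / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu - cmu[-bins]) / w1, 0)
  g <- w0 * w1 * (mu0 - mu1)^2
  data.frame(t = seq_len(bins - 1) / bins, w0 = w0, w1 = w1,
             mu0 = mu0, mu1 = mu1, g = g)
}

#' Otsu threshold by between-class variance
#'
#' Exhaustively scans all bin boundaries of the intensity histogram
#' (restricted to `region` when given) and returns the threshold maximizing
#' the between-class variance `g = w0 * w1 * (mu0 - mu1)^2`, where `w0`, `w1`
#' are the class proportions and `mu0`, `mu1` the class mean gray levels.
#' Maximizing `g` is equivalent to minimizing the within-class variance; the
#' overall mean satisfies `mu = w0*mu0 + w1*mu1` at every candidate split.
#' Ties resolve to the smallest threshold.
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param region Optional logical matrix restricting the histogram (e.g. the
#'   field of view); `NULL` uses all pixels.
#' @param bins Number of histogram bins over \[0, 1\] (default 256).
#' @return Threshold in \[0, 1\] (a bin boundary `k/bins`). Pixels above it
#'   (strictly) are foreground.
#' @export
otsu_threshold <- function(img, region = NULL, bins = 256) {
  st <- otsu_stats(img, region, bins)
  valid <- st$w0 > 0 & st$w1 > 0
  g <- ifelse(valid, st$g, -Inf)
  st$t[which.max(g)]                 # which.max returns the first maximizer
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of [segment()] with their defaults:
#' CLAHE clip limit 0.01 (fraction of tile pixels) on an 8 x 8 tile grid with
#' 256 bins; vesselness scales 1 to 6 px in steps of 0.5 (vessel radii for
#' diameters 2--12 px); eigenvalue floor 1e-10; oriented-opening cleanup
#' enabled; Otsu on 256 bins.
#'
#' @param clip_limit,tile_grid,clahe_bins CLAHE parameters, see [clahe()].
#' @param s_min,s_max,s_step Scale sampling, see [scale_set()].
#' @param lambda_floor See [improved_response()].
#' @param noise_floor_q Quantile defining the noise-referenced response
#'   floor: raw responses at or below the `noise_floor_q` quantile of the
#'   response that pure white noise at the image's estimated noise level
#'   would produce are treated as noise and zeroed before normalization
#'   (default 0.99; set to 0 to disable). On noise-free images the floor is
#'   negligible; on noisy ones it keeps the Otsu stage from binarizing pure
#'   noise into spurious vessels.
#' @param morphology Apply [improved_open()] to the response map (default TRUE).
#' @param otsu_bins Histogram bins for [otsu_threshold()].
#' @param baseline Use the classic two-term vesselness
#'   ([traditional_vesselness()]) instead of the improved response; all other
#'   stages are unchanged.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(clip_limit = 0.01, tile_grid = c(8, 8),
                            clahe_bins = 256, s_min = 1, s_max = 6,
                            s_step = 0.5, lambda_floor = 1e-10,
                            noise_floor_q = 0.99, morphology = TRUE,
                            otsu_bins = 256, baseline = FALSE) {
  if (!(is.numeric(noise_floor_q) && length(noise_floor_q) == 1 &&
        noise_floor_q >= 0 && noise_floor_q < 1))
    stop("noise_floor_q must be in [0, 1)", call. = FALSE)
  cfg <- list(clip_limit = clip_limit, tile_grid = tile_grid,
              clahe_bins = clahe_bins, s_min = s_min, s_max = s_max,
              s_step = s_step, lambda_floor = lambda_floor,
              noise_floor_q = noise_floor_q,
              morphology = isTRUE(morphology), otsu_bins = otsu_bins,
              baseline = isTRUE(baseline))
  num <- c("clip_limit", "clahe_bins", "s_min", "s_max", "s_step",
           "lambda_floor", "otsu_bins")
  for (f in num)
    if (!(is.numeric(cfg[[f]]) && all(cfg[[f]] > 0)))
      stop("config field '", f, "' must be positive", call. = FALSE)
  scale_set(cfg$s_min, cfg$s_max, cfg$s_step)    # validates the scale range
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  cat(sprintf("  clahe: clip_limit %g, tiles %dx%d, %d bins\n",
              x$clip_limit, x$tile_grid[1], x$tile_grid[2], x$clahe_bins))
  cat(sprintf("  scales: %g..%g step %g px (%s response)\n", x$s_min, x$s_max,
              x$s_step, if (x$baseline) "classic" else "improved"))
  cat(sprintf("  morphology: %s; otsu bins: %d\n",
              if (x$morphology) "198-template opening" else "off", x$otsu_bins))
  invisible(x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Segment retinal vessels in a fundus image
#'
#' End-to-end pipeline: green channel extraction, CLAHE enhancement,
#' multiscale vesselness response, oriented-opening noise cleanup, Otsu
#' thresholding over the field of view, binarization (vessel iff response
#' strictly above the threshold) and FOV masking. Deterministic: identical
#' inputs give bit-identical masks.
#'
#' @param rgb H x W x 3 numeric array in \[0, 1\].
#' @param fov Optional logical FOV matrix; when `NULL` it is estimated with
#'   [fov_from_image()]. A supplied mask always wins over estimation.
#' @param config A [pipeline_config()].
#' @return An object of class `vessel_segmentation`: list with `mask`
#'   (logical matrix, TRUE = vessel, FALSE everywhere outside the FOV),
#'   `threshold` (chosen Otsu threshold), `response` (the cleaned response
#'   map fed to Otsu), `fov`, and `config`.
#' @export
segment <- function(rgb, fov = NULL, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  run_stage("input", assert_rgb(rgb))
  green <- run_stage("green", extract_green(rgb))
  if (is.null(fov)) fov <- run_stage("fov", fov_from_image(rgb))
  fov <- matrix(as.logical(fov), nrow(green), ncol(green))
  run_stage("fov", if (!any(fov)) stop("field of view is empty", call. = FALSE))
  enhanced <- run_stage("clahe",
    clahe(green, config$clip_limit, config$tile_grid, config$clahe_bins))
  scales <- scale_set(config$s_min, config$s_max, config$s_step)
  resp <- run_stage("vesselness",
    if (config$baseline) traditional_vesselness(enhanced, scales, fov,
                                                normalize = FALSE)
    else multiscale_response(enhanced, scales, fov, normalize = FALSE,
                             lambda_floor = config$lambda_floor))
  attr(resp, "best_scale") <- NULL
  if (!config$baseline && config$noise_floor_q > 0) {
    resp <- run_stage("noise floor", {
      sigma <- estimate_noise_sd(enhanced, fov)
      floor_level <- sigma * noise_response_quantile(
        scales, config$lambda_floor, config$noise_floor_q)
      resp[resp <= floor_level] <- 0
      resp
    })
  }
  resp <- run_stage("normalize", minmax_normalize(resp, fov))
  cleaned <- if (config$morphology)
    run_stage("morphology", improved_open(resp, build_template_bank()))
  else resp
  thr <- run_stage("otsu", otsu_threshold(cleaned, fov, config$otsu_bins))
  mask <- cleaned > thr & fov
  structure(list(mask = mask, threshold = thr, response = cleaned,
                 fov = fov, config = config),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("vessel_segmentation: %dx%d px, otsu threshold %.4f, %.1f%% of FOV marked vessel\n",
              nrow(x$mask), ncol(x$mask), x$threshold,
              100 * sum(x$mask) / max(1, sum(x$fov))))
  invisible(x)
}
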