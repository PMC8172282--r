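#' Oriented linear structuring element
#'
#' Builds a flat line structuring element of a given pixel length and
#' orientation, rasterized with a centered digital-differential-analyzer
#' (Bresenham-style) walk along the major axis. "Length" counts set pixels
#' along the rasterized line, matching the pixel-denominated vessel diameters
#' the bank emulates; for even lengths the extra pixel sits on the positive-x
#' side of the origin. Angles are measured counterclockwise from the +x
#' (column) axis; half-integer minor coordinates round toward +Inf.
#'
#' @param length Number of set pixels along the line, 2--12.
#' @param angle Orientation in degrees, in \[0, 180).
#' @return An object of class `structuring_element`: list with `length`,
#'   `angle`, `offsets` (length x 2 integer matrix of (row, col) offsets from
#'   the origin), `mask` (logical matrix with the origin at its center pixel)
#'   and `origin` (row, col of the origin within `mask`).
#' @examples
#' make_line_se(5, 0)    # horizontal 5-pixel run
#' make_line_se(5, 90)   # its transpose
#' @export
make_line_se <- function(length, angle) {
  if (!(length(length) == 1L && length == as.integer(length) &&
        length >= 2 && length <= 12))
    stop("length must be an integer in [2, 12]", call. = FALSE)
  if (!(length(angle) == 1L && is.finite(angle) && angle >= 0 && angle < 180))
    stop("angle must be in [0, 180) degrees", call. = FALSE)
  L <- as.integer(length)
  theta <- angle * pi / 180
  ux <- cos(theta)
  uy <- sin(theta)
  k <- seq.int(-((L - 1L) %/% 2L), length.out = L)   # extra pixel on + side
  rnd <- function(v) as.integer(floor(v + 0.5))
  if (abs(ux) >= abs(uy)) {          # x-major
    dc <- k
    dr <- rnd(k * uy / ux)
  } else {                           # y-major
    dr <- k
    dc <- rnd(k * ux / uy)
  }
  rr <- max(abs(dr))
  cr <- max(abs(dc))
  mask <- matrix(FALSE, 2L * rr + 1L, 2L * cr + 1L)
  mask[cbind(dr + rr + 1L, dc + cr + 1L)] <- TRUE
  structure(
    list(length = L, angle = angle,
         offsets = cbind(dr = as.integer(dr), dc = as.integer(dc)),
         mask = mask, origin = c(rr + 1L, cr + 1L)),
    class = "structuring_element"
  )
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring_element: length %d, angle %g deg\n", x$length, x$angle))
  cat(paste(apply(x$mask, 1, function(r) paste(ifelse(r, "#", "."), collapse = "")),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Bank of 198 oriented line templates
#'
#' All combinations of line lengths 2--12 px (the vessel diameter range, step
#' 1 px) and orientations 0--170 degrees in steps of 10, in deterministic
#' length-major order: 11 lengths x 18 angles = 198 structuring elements.
#'
#' @return An object of class `template_bank`: a list of 198
#'   [make_line_se()] elements with attributes `lengths` and `angles`.
#' @export
build_template_bank <- function() {
  lengths <- 2:12
  angles <- seq(0, 170, by = 10)
  bank <- vector("list", length(lengths) * length(angles))
  i <- 0L
  for (L in lengths)
    for (a in angles) {
      i <- i + 1L
      bank[[i]] <- make_line_se(L, a)
    }
  structure(bank, lengths = lengths, angles = angles, class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("template_bank: %d linear structuring elements (lengths %s; angles %s deg)\n",
              length(x), paste(range(attr(x, "lengths")), collapse = "-"),
              paste(range(attr(x, "angles")), collapse = "-")))
  invisible(x)
}

#' Dump a template bank as plain text
#'
#' Writes one line per element, `length,angle,rows,cols,origin_r,origin_c,rle`,
#' where `rle` is the run-length encoding of the mask in row-major order, for
#' audit outside R.
#'
#' @param bank A [build_template_bank()] result.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
dump_template_bank <- function(bank, path) {
  lines <- vapply(bank, function(se) {
    r <- rle(as.integer(t(se$mask)))
    sprintf("%d,%g,%d,%d,%d,%d,%s", se$length, se$angle,
            nrow(se$mask), ncol(se$mask), se$origin[1], se$origin[2],
            paste(r$lengths, r$values, sep = "x", collapse = ";"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## Pad with a constant fill value (+Inf for erosion, -Inf for dilation):
## out-of-image samples never win the min/max, so windows are effectively
## clipped to the image domain. This domain-restricted border rule is what
## makes the erosion/dilation pair a true adjunction on the finite image,
## and hence the opening exactly idempotent.
se_pad <- function(img, se, fill) {
  pr <- max(abs(se$offsets[, "dr"]))
  pc <- max(abs(se$offsets[, "dc"]))
  if (nrow(se$mask) > nrow(img) || ncol(se$mask) > ncol(img))
    stop("structuring element (", nrow(se$mask), "x", ncol(se$mask),
         ") larger than image (", nrow(img), "x", ncol(img), ")", call. = FALSE)
  p <- matrix(fill, nrow(img) + 2 * pr, ncol(img) + 2 * pc)
  p[(pr + 1):(pr + nrow(img)), (pc + 1):(pc + ncol(img))] <- img
  list(p = p, pr = pr, pc = pc)
}

min_max_over_offsets <- function(img, se, sign, fun, fill) {
  pp <- se_pad(img, se, fill)
  out <- NULL
  for (i in seq_len(nrow(se$offsets))) {
    dr <- sign * se$offsets[i, "dr"]
    dc <- sign * se$offsets[i, "dc"]
    shifted <- pp$p[(1 + pp$pr + dr):(nrow(img) + pp$pr + dr),
                    (1 + pp$pc + dc):(ncol(img) + pp$pc + dc), drop = FALSE]
    out <- if (is.null(out)) shifted else fun(out, shifted)
  }
  out
}

#' Flat grayscale erosion and dilation by a line element
#'
#' Windowed minimum (erosion, over the structuring-element support) and
#' maximum (dilation, over the reflected support). Windows are clipped to the
#' image domain at the borders (out-of-image samples are ignored), which
#' keeps erosion and dilation adjoint and the opening exactly idempotent.
#'
#' @param img Numeric matrix.
#' @param se A [make_line_se()] structuring element.
#' @return Numeric matrix of the same size.
#' @export
grayscale_erode <- function(img, se) {
  assert_gray(img)
  min_max_over_offsets(img, se, +1L, pmin, fill = Inf)
}

#' @rdname grayscale_erode
#' @export
grayscale_dilate <- function(img, se) {
  assert_gray(img)
  min_max_over_offsets(img, se, -1L, pmax, fill = -Inf)
}

#' Grayscale opening by a line element
#'
#' Erosion followed by dilation with the same flat element; removes bright
#' structures smaller than the element without enlarging the rest. Idempotent
#' and anti-extensive (the result never exceeds the input).
#'
#' @inheritParams grayscale_erode
#' @return Numeric matrix of the same size.
#' @export
grayscale_open <- function(img, se) {
  grayscale_dilate(grayscale_erode(img, se), se)
}

#' Opening maximized over the 198-template bank
#'
#' Applies the grayscale opening for every template in the bank and keeps, at
#' each pixel, the maximum over the 198 results. A bright curvilinear segment
#' survives whenever at least one template (length and orientation) fits
#' inside it, so vessels of any direction and caliber within the bank's range
#' are preserved while isolated bright noise is suppressed.
#'
#' @param img Numeric matrix (typically the vesselness response map).
#' @param bank A [build_template_bank()] result (or any non-empty list of
#'   structuring elements).
#' @return Numeric matrix of the same size.
#' @export
improved_open <- function(img, bank = build_template_bank()) {
  assert_gray(img)
  if (length(bank) == 0) stop("empty template bank", call. = FALSE)
  out <- NULL
  for (se in bank) {
    o <- grayscale_open(img, se)
    out <- if (is.null(out)) o else pmax(out, o)
  }
  out
}
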