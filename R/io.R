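## Raster I/O for fundus images and masks. PNG and TIFF go through the png
## and tiff packages; PPM/PGM (the plain netpbm formats some datasets use)
## are decoded here. 8-bit files are divided by 255, 16-bit by 65535: all
## internal math is floating point in [0, 1].

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected end of PNM file", call. = FALSE)
      if (ch == "#") {                       # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
        next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "'", call. = FALSE)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval < 256) as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE))
    else as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big"))
  } else {
    as.numeric(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  if (length(vals) != n) stop("truncated PNM file", call. = FALSE)
  vals <- vals / maxval
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(NA_real_, c(h, w, 3))
    for (ch in 1:3)
      a[, , ch] <- matrix(vals[seq(ch, n, by = 3)], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    ppm = ,
    pgm = ,
    pnm = read_ppm(path),
    stop("unsupported raster format '.", ext, "' (supported: png, tif/tiff, ppm/pgm)",
         call. = FALSE)
  )
  d <- dim(img)
  if (length(d) == 3 && d[3] == 4) img <- img[, , 1:3]       # drop alpha
  if (length(d) == 3 && d[3] == 2) img <- img[, , 1]          # gray + alpha
  img
}

#' Read a fundus image
#'
#' Loads an RGB raster (PNG, TIFF or PPM) as an H x W x 3 array in \[0, 1\].
#'
#' @param path Image file path.
#' @return Numeric H x W x 3 array.
#' @export
read_fundus <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) != 3)
    stop("'", path, "' is not an RGB image", call. = FALSE)
  img
}

#' Read a binary mask
#'
#' Loads a single-channel raster as a logical matrix; any value above half
#' range counts as foreground. Multi-channel files use the first channel.
#'
#' @param path Mask file path.
#' @return Logical H x W matrix.
#' @export
read_mask <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write a binary mask as 8-bit PNG
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a response map as 16-bit TIFF
#'
#' Stores a \[0, 1\] response map at 16-bit depth (value = round(f * 65535))
#' for inspection outside R.
#'
#' @param resp Numeric matrix in \[0, 1\].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_response <- function(resp, path) {
  resp <- clip01(matrix(as.numeric(resp), nrow(resp), ncol(resp)))
  tiff::writeTIFF(round(resp * 65535) / 65535, path, bits.per.sample = 16)
  invisible(path)
}
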