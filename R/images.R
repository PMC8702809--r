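#' Fundus image container
#'
#' Bundles an RGB fundus photograph with its optional field-of-view (FOV)
#' mask and optional manually segmented vessel ground truth.
#'
#' @param pixels numeric array `height x width x 3` (red, green, blue),
#'   integer levels in `[0, 255]`.
#' @param fov_mask optional binary matrix of the same height/width;
#'   1 marks pixels inside the eyeball.
#' @param truth optional binary matrix of the same height/width; 1 marks
#'   vessel pixels.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, fov_mask = NULL, truth = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop_retseg("pixels must be a height x width x 3 array", "retseg_channel_error")
  if (any(pixels < 0 | pixels > 255))
    stop_retseg("channel values must lie in [0, 255]", "retseg_range_error")
  for (nm in c("fov_mask", "truth")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!identical(dim(m), d[1:2]))
        stop_retseg(sprintf("%s dimensions must match pixels", nm), "retseg_shape_error")
      if (!is_binary(m))
        stop_retseg(sprintf("%s must be binary", nm), "retseg_range_error")
    }
  }
  structure(list(pixels = pixels, fov_mask = fov_mask, truth = truth),
            class = "fundus_image")
}

#' Single-channel intensity image
#'
#' A 2-D intensity image that records which value convention it uses:
#' discrete gray levels `0..L-1` or normalized intensities in `[0, 1]`.
#'
#' @param values numeric matrix.
#' @param convention `"integer"` (levels `0..L-1`) or `"normalized"` (`[0,1]`).
#' @param L number of gray levels for the integer convention (default 256).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(values, convention = c("integer", "normalized"), L = 256L) {
  convention <- match.arg(convention)
  if (!is.matrix(values)) stop_retseg("values must be a matrix", "retseg_shape_error")
  if (convention == "integer") {
    if (any(values < 0 | values > L - 1))
      stop_retseg("integer-convention values must lie in [0, L-1]", "retseg_range_error")
  } else if (any(values < 0 | values > 1)) {
    stop_retseg("normalized values must lie in [0, 1]", "retseg_range_error")
  }
  structure(list(values = values, convention = convention, L = as.integer(L)),
            class = "gray_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %d x %d, mask: %s, truth: %s>\n", d[1], d[2],
              if (is.null(x$fov_mask)) "none" else "yes",
              if (is.null(x$truth)) "none" else "yes"))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %s convention, L = %d>\n",
              nrow(x$values), ncol(x$values), x$convention, x$L))
  invisible(x)
}

# ---- raster readers/writers ------------------------------------------------

# read a raster file into a numeric array scaled to integer levels 0..255;
# grayscale files come back as a matrix, color files as H x W x 3
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    ppm = , pgm = read_ppm(path),
    gif = stop_retseg("GIF input is not supported; convert to PNG/TIFF/PPM",
                      "retseg_format_error"),
    stop_retseg(sprintf("unsupported raster format '%s'", ext), "retseg_format_error")
  )
  if (ext %in% c("png", "tif", "tiff")) a <- round_half_up(a * 255)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  a
}

#' Read a fundus image and companions from disk
#'
#' Supported formats: PNG, TIFF and PPM/PGM. Masks and truths are binarized
#' at half intensity.
#'
#' @param path image file.
#' @param mask_path,truth_path optional companion rasters.
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path, mask_path = NULL, truth_path = NULL) {
  px <- read_raster(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  to_bin <- function(p) {
    if (is.null(p)) return(NULL)
    m <- read_raster(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    (m >= 128) + 0
  }
  fundus_image(px, fov_mask = to_bin(mask_path), truth = to_bin(truth_path))
}

#' Write an image as PNG
#'
#' @param x a matrix in `[0,1]` or `[0,255]`, a 3-channel array, or a
#'   [gray_image()].
#' @param path output file.
#' @export
write_png <- function(x, path) {
  if (inherits(x, "gray_image"))
    x <- if (x$convention == "integer") x$values / (x$L - 1) else x$values
  if (max(x) > 1) x <- x / 255
  png::writePNG(clamp(x, 0, 1), path)
}

# minimal netpbm reader: P2/P3 (ascii) and P5/P6 (binary), maxval <= 65535
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_retseg("not a supported PPM/PGM file", "retseg_format_error")
  toks <- integer(0)
  buf <- character(0)
  read_tokens <- function(n) {
    out <- integer(0)
    while (length(out) < n) {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0 || ch == "") stop_retseg("truncated PPM header", "retseg_format_error")
      if (ch == "#") { # comment to end of line
        repeat {
          c2 <- rawToChar(readBin(con, "raw", 1L))
          if (c2 %in% c("\n", "\r", "")) break
        }
        next
      }
      if (grepl("[0-9]", ch)) {
        num <- ch
        repeat {
          c2 <- rawToChar(readBin(con, "raw", 1L))
          if (grepl("[0-9]", c2)) num <- paste0(num, c2) else break
        }
        out <- c(out, as.integer(num))
      }
    }
    out
  }
  hdr <- read_tokens(3L)
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  npx <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(npx)]
  } else if (maxval < 256) {
    as.integer(readBin(con, "raw", npx))
  } else {
    readBin(con, "integer", npx, size = 2L, signed = FALSE, endian = "big")
  }
  vals <- round_half_up(vals / maxval * 255)
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3L))
    for (c in 1:3) a[, , c] <- matrix(vals[seq(c, npx, by = 3L)], h, w, byrow = TRUE)
    a
  }
}
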