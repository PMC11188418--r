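#' @name image-types
#' @title Image and mask conventions
#'
#' @description
#' The package represents images as plain base-R objects:
#'
#' * a *grayscale image* is a numeric or integer matrix indexed
#'   `[row, col]`, 1-based, origin at the top-left, with intensities in
#'   `[0, 255]`;
#' * a *color image* is an `h x w x 3` array on the same grid convention,
#'   channels ordered R, G, B;
#' * a *binary mask* is a matrix of the same shape as its partner image
#'   whose values are exactly 0 or 1 (nonzero = fruit / foreground).
#'
#' File I/O enforces 8-bit integers; the in-memory texture operations also
#' accept float-valued matrices so that scale-invariance properties can be
#' exercised without quantization.
#'
#' @keywords internal
NULL

.is_color <- function(img) is.array(img) && length(dim(img)) == 3L

.check_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg),
         call. = FALSE)
  invisible(img)
}

.check_mask <- function(mask, img, arg = "mask") {
  if (!is.matrix(mask) && !is.logical(mask))
    stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  d <- dim(img)[1:2]
  if (!identical(dim(mask), d))
    stop(sprintf("`%s` shape (%s) does not match image shape (%s)",
                 arg, paste(dim(mask), collapse = "x"),
                 paste(d, collapse = "x")), call. = FALSE)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0 and 1", arg), call. = FALSE)
  invisible(mask)
}

# decoded [0,1] array from png/EBImage -> 8-bit integers.
# 16-bit content is mapped to [0,255] by integer division of the 16-bit code.
.quantize_decoded <- function(x, bit_depth = 8L) {
  if (bit_depth > 8L) {
    storage.mode(x) <- "integer"
    x <- x %/% as.integer(2^(bit_depth - 8L))
  }
  storage.mode(x) <- "integer"
  x
}

#' Read a PNG or JPEG image
#'
#' Returns a color image (`h x w x 3` integer array) for 3-channel files and
#' a grayscale image (integer matrix) for single-channel files, values in
#' `[0, 255]`.  An alpha channel, if present, is dropped.  16-bit PNG input
#' is rescaled to `[0, 255]` by integer division.  JPEG decoding requires the
#' \pkg{EBImage} package.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An integer matrix (grayscale) or an `h x w x 3` integer array
#'   (color); see [image-types] for the grid convention.
#' @seealso [write_image()], [to_grayscale()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e)
                      stop(sprintf("cannot decode PNG '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
    info <- attr(raw, "info")
    depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    max_code <- 2^depth - 1
    x <- round(raw * max_code)
    x <- .quantize_decoded(x, depth)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package", call. = FALSE)
    raw <- tryCatch(EBImage::readImage(path),
                    error = function(e)
                      stop(sprintf("cannot decode JPEG '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
    dat <- EBImage::imageData(raw)
    # EBImage stores [x, y(, channel)]; transpose to [row, col(, channel)]
    if (length(dim(dat)) == 2L) {
      x <- t(dat)
    } else {
      x <- aperm(dat, c(2L, 1L, 3L))
    }
    x <- .quantize_decoded(round(x * 255))
  } else {
    stop(sprintf("unsupported image format '.%s' (PNG or JPEG expected)",
                 ext), call. = FALSE)
  }
  d <- dim(x)
  attributes(x) <- NULL
  if (length(d) == 2L) {
    dim(x) <- d
    return(x)
  }
  dim(x) <- d
  plane <- function(k) {
    p <- x[, , k]
    dim(p) <- d[1:2]
    p
  }
  if (d[3] <= 2L) return(plane(1L))        # gray, or gray + alpha
  y <- x[, , 1:3]
  dim(y) <- c(d[1:2], 3L)                  # drop alpha if RGBA
  y
}

#' Write an image to PNG or JPEG
#'
#' PNG output is lossless: `read_image(write_image(x, p))` reproduces `x`
#' bit for bit.  JPEG output (extension `.jpg`/`.jpeg`, requires
#' \pkg{EBImage}) is lossy and written at the given quality.
#'
#' @param img Grayscale matrix or `h x w x 3` color array, integer values in
#'   `[0, 255]`.
#' @param path Output path; the extension selects the format.
#' @param jpeg_quality JPEG quality in `[1, 100]`, default 95; ignored for
#'   PNG.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, jpeg_quality = 95L) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)),
         call. = FALSE)
  v <- as.vector(if (.is_color(img)) img else .check_gray(img))
  if (anyNA(v) || any(v < 0) || any(v > 255) || any(v != floor(v)))
    stop("image values must be integers in [0, 255]", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package", call. = FALSE)
    dat <- if (.is_color(img)) aperm(img, c(2L, 1L, 3L)) / 255 else t(img) / 255
    EBImage::writeImage(EBImage::Image(dat,
                                       colormode = if (.is_color(img)) "Color"
                                                   else "Grayscale"),
                        path, quality = as.numeric(jpeg_quality))
  } else {
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Nonzero pixels are foreground (fruit).  A color file is reduced by its
#' first channel.
#'
#' @param path Path to the mask PNG.
#' @return An integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (.is_color(m)) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  (m != 0L) + 0L
}

#' Convert a color image to grayscale
#'
#' ITU-R BT.601 luminance: `round(0.299 R + 0.587 G + 0.114 B)` with
#' round-half-away-from-zero, clamped to `[0, 255]`.
#'
#' @param img `h x w x 3` color array; a grayscale matrix is returned
#'   unchanged.
#' @return Integer grayscale matrix.
#' @export
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' to_grayscale(px)  # 76
to_grayscale <- function(img) {
  if (!.is_color(img)) {
    .check_gray(img)
    return(img)
  }
  y <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  y <- pmin(pmax(.round_half_up(y), 0), 255)
  dim(y) <- dim(img)[1:2]
  storage.mode(y) <- "integer"
  y
}

#' Pad a grayscale image by edge replication
#'
#' Adds `margin` rows/columns on every side, replicating the nearest edge
#' pixel.  Used as the default border policy of the encoders.
#'
#' @param img Grayscale matrix.
#' @param margin Non-negative integer pixel count.
#' @return A `(h + 2 margin) x (w + 2 margin)` matrix whose interior equals
#'   `img`.
#' @export
pad_replicate <- function(img, margin) {
  .check_gray(img)
  margin <- as.integer(margin)
  if (length(margin) != 1L || is.na(margin) || margin < 0L)
    stop("`margin` must be a single non-negative integer", call. = FALSE)
  if (margin == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep(1L, margin), seq_len(h), rep(h, margin))
  ci <- c(rep(1L, margin), seq_len(w), rep(w, margin))
  img[ri, ci, drop = FALSE]
}
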