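#' R-LBP encoding parameters
#'
#' Configuration of the R-LBP per-pixel encoder.
#'
#' @param threshold Relative-change threshold on the dispersion, a fraction
#'   in (0, 1).  Default 0.15: a direction's bit fires when adding the
#'   target pixel changes the ray's dispersion by more than 15%.  The
#'   comparison is strict (`>`).
#' @param ray_length Outward pixels per direction beyond the reference
#'   pixel, at least 1.  Default 2, so the reference ray holds 3 pixels and
#'   the augmented ray 4.
#' @param border_policy `"replicate_pad"` (default): the image is padded by
#'   `ray_length + 1` with replicated edges so every pixel gets a code;
#'   `"zero_border"`: pixels whose neighbourhood exits the image get code 0.
#' @param zero_cv_policy Bit emitted when the reference ray has zero
#'   dispersion but the augmented ray does not (the target pixel introduces
#'   all the variation, an unboundedly large relative change).  Default 1.
#' @return An object of class `rlbp_params`.
#' @export
#' @examples
#' rlbp_params()
#' rlbp_params(threshold = 0.2, border_policy = "zero_border")
rlbp_params <- function(threshold = 0.15, ray_length = 2L,
                        border_policy = c("replicate_pad", "zero_border"),
                        zero_cv_policy = 1L) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single number in (0, 1)", call. = FALSE)
  ray_length <- as.integer(ray_length)
  if (is.na(ray_length) || ray_length < 1L)
    stop("`ray_length` must be an integer >= 1", call. = FALSE)
  border_policy <- match.arg(border_policy)
  zero_cv_policy <- as.integer(zero_cv_policy)
  if (!zero_cv_policy %in% c(0L, 1L))
    stop("`zero_cv_policy` must be 0 or 1", call. = FALSE)
  structure(list(threshold = threshold, ray_length = ray_length,
                 border_policy = border_policy,
                 zero_cv_policy = zero_cv_policy),
            class = "rlbp_params")
}

#' @export
print.rlbp_params <- function(x, ...) {
  cat(sprintf(
    "R-LBP parameters: threshold %.2f, ray_length %d, border %s, zero-CV bit %d\n",
    x$threshold, x$ray_length, x$border_policy, x$zero_cv_policy))
  invisible(x)
}

#' Dispersion of an intensity array
#'
#' The coefficient-of-variation-like quantity compared by the R-LBP
#' encoder: the sum of squared deviations from the mean, divided by
#' `n * mean`, expressed as a percent.  (An index of dispersion rather than
#' the textbook standard-deviation-over-mean; see the methods vignette.)
#' Returns 0 for the all-zero list, the only way a non-negative list can
#' have mean 0.
#'
#' @param values Numeric vector, length at least 2, values non-negative.
#' @return Dispersion in percent.
#' @export
#' @examples
#' dispersion(c(10, 20, 30))  # 333.33...
dispersion <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  if (any(values < 0))
    stop("`values` must be non-negative", call. = FALSE)
  n <- length(values)
  m <- .seq_sum(values) / n
  if (m == 0) return(0)
  ssd <- 0
  for (x in values) ssd <- ssd + (x - m) * (x - m)
  (ssd / (n * m)) * 100
}

# resolve border handling for per-pixel ops: returns list(img, row, col)
# in padded coordinates, or NULL if the pixel cannot be encoded
.border_view <- function(img, pixel, params) {
  need <- params$ray_length + 1L
  h <- nrow(img); w <- ncol(img)
  r <- pixel[[1]]; cl <- pixel[[2]]
  if (r < 1L || r > h || cl < 1L || cl > w)
    stop("`pixel` is outside the image", call. = FALSE)
  if (params$border_policy == "replicate_pad") {
    list(img = pad_replicate(img, need), row = r + need, col = cl + need)
  } else if (r - need >= 1L && r + need <= h && cl - need >= 1L &&
             cl + need <= w) {
    list(img = img, row = r, col = cl)
  } else {
    NULL
  }
}

#' Reference and augmented ray arrays for one direction
#'
#' The two pixel arrays whose dispersions the R-LBP encoder compares for a
#' given direction: the reference ray `cva` holds the intensities at offsets
#' `1 d, 2 d, ..., (ray_length + 1) d` from the target pixel (the reference
#' pixel and its collinear outward continuation); the augmented ray `cvb`
#' is the same array with the target pixel's own intensity prepended.
#'
#' @param img Grayscale matrix.
#' @param pixel Target pixel as `c(row, col)`, 1-based.  The full ray must
#'   lie inside the image (no border handling here).
#' @param dir Direction id 1-8; see [directions()].
#' @param params An [rlbp_params()] object.
#' @return A list with numeric vectors `cva` (length `ray_length + 1`) and
#'   `cvb` (length `ray_length + 2`).
#' @export
direction_arrays <- function(img, pixel, dir, params = rlbp_params()) {
  .check_gray(img)
  dir <- as.integer(dir)
  if (is.na(dir) || dir < 1L || dir > 8L)
    stop("`dir` must be a direction id in 1..8", call. = FALSE)
  need <- params$ray_length + 1L
  r <- pixel[[1]]; cl <- pixel[[2]]
  dr <- .DIRECTIONS[dir, 1L]; dc <- .DIRECTIONS[dir, 2L]
  rr <- r + (1:need) * dr; cc <- cl + (1:need) * dc
  if (any(rr < 1L) || any(rr > nrow(img)) || any(cc < 1L) ||
      any(cc > ncol(img)) || r < 1L || r > nrow(img) || cl < 1L ||
      cl > ncol(img))
    stop("ray leaves the image; pad first or choose an interior pixel",
         call. = FALSE)
  cva <- img[cbind(rr, cc)]
  list(cva = as.numeric(cva), cvb = as.numeric(c(img[r, cl], cva)))
}

#' R-LBP code of a single pixel
#'
#' For each of the eight directions in clockwise numbering order, the bit is
#' 1 iff `|CVa - CVb| / CVa > threshold`, where `CVa` and `CVb` are the
#' [dispersion()] of the reference and augmented ray ([direction_arrays()]).
#' Degenerate rays: both dispersions zero gives bit 0; `CVa = 0` with
#' `CVb > 0` gives the bit set by `zero_cv_policy`.  Direction 1 is the most
#' significant bit of the resulting 8-bit code.
#'
#' @inheritParams direction_arrays
#' @return Integer code in `[0, 255]`, or 0 when the pixel cannot be
#'   encoded under the `zero_border` policy.
#' @export
encode_pixel <- function(img, pixel, params = rlbp_params()) {
  .check_gray(img)
  view <- .border_view(img, pixel, params)
  if (is.null(view)) return(0L)
  code <- 0L
  for (d in 1:8) {
    arrs <- direction_arrays(view$img, c(view$row, view$col), d, params)
    cva <- dispersion(arrs$cva)
    cvb <- dispersion(arrs$cvb)
    bit <- if (cva > 0) {
      as.integer(abs(cva - cvb) / cva > params$threshold)
    } else if (cvb > 0) {
      params$zero_cv_policy
    } else 0L
    code <- code + bit * bitwShiftL(1L, 8L - d)
  }
  code
}

#' R-LBP transform of a grayscale image
#'
#' Applies [encode_pixel()] to every pixel (compiled core).  Under the
#' default `replicate_pad` border policy the image is padded by
#' `ray_length + 1` replicated edge pixels before encoding, so every output
#' pixel carries a code; under `zero_border`, pixels whose neighbourhood
#' exits the image get code 0.
#'
#' @param img Grayscale matrix (integer or float-valued).
#' @param params An [rlbp_params()] object.
#' @return Integer matrix of 8-bit codes, same shape as `img`.
#' @seealso [lbp_transform()] for the classic baseline, [compose_scene()]
#'   for masked composition.
#' @export
#' @examples
#' img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
#' rlbp_transform(img)
rlbp_transform <- function(img, params = rlbp_params()) {
  .check_gray(img)
  need <- params$ray_length + 1L
  if (params$border_policy == "replicate_pad") {
    padded <- pad_replicate(img, need)
    codes <- .rlbp_core(padded * 1.0, params$threshold, params$ray_length,
                        params$zero_cv_policy)
    codes[(need + 1):(need + nrow(img)), (need + 1):(need + ncol(img)),
          drop = FALSE]
  } else {
    .rlbp_core(img * 1.0, params$threshold, params$ray_length,
               params$zero_cv_policy)
  }
}

#' Classic LBP transform
#'
#' The standard 3x3 local binary pattern used as the comparison baseline:
#' for the 8 clockwise neighbours, the bit is 1 iff the neighbour is greater
#' than or equal to the center.  Bit order and border policy (replicate pad
#' by 1) match [rlbp_transform()], so differences between the two arms are
#' attributable to the encoding alone.
#'
#' @param img Grayscale matrix.
#' @return Integer matrix of 8-bit codes, same shape as `img`.  A constant
#'   image maps to all 255 (ties count as 1).
#' @export
lbp_transform <- function(img) {
  .check_gray(img)
  padded <- pad_replicate(img, 1L)
  codes <- .lbp_core(padded * 1.0)
  codes[2:(1 + nrow(img)), 2:(1 + ncol(img)), drop = FALSE]
}
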