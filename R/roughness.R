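#' Mean absolute deviation of an intensity ray
#'
#' The per-direction deviation statistic of the peel-roughness metric:
#' `sum(|x_i - mean(x)|) / N` for the `N` pixels sampled along one
#' direction.
#'
#' @param values Numeric vector of intensities, length at least 2.
#' @return The mean absolute deviation, in intensity units.
#' @export
#' @examples
#' directional_deviation(c(10, 20, 30))  # 20/3
directional_deviation <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  m <- mean(values)
  mean(abs(values - m))
}

# bounding rectangle (1-based, inclusive) of a mask's nonzero pixels, or of
# the full image when mask is NULL
.bounding_rect <- function(img, mask = NULL) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (is.null(mask)) return(c(r0 = 1L, r1 = h, c0 = 1L, c1 = w))
  .check_mask(mask, img)
  rows <- which(apply(mask != 0, 1, any))
  cols <- which(apply(mask != 0, 2, any))
  if (length(rows) == 0L)
    stop("mask has no nonzero pixels", call. = FALSE)
  c(r0 = rows[1], r1 = rows[length(rows)],
    c0 = cols[1], c1 = cols[length(cols)])
}

#' Nine sampling regions of a bounding rectangle
#'
#' Divides the sides of the bounding rectangle (of the mask's nonzero pixels
#' if a mask is given, else the whole image) into four equal parts; the nine
#' interior grid intersection points are the region centers.  Each region's
#' window is the quarter-size box (`ceiling(H/4) x ceiling(W/4)`) centered
#' on its point, clipped to the rectangle.  Centers at non-integer division
#' points are placed at `round(H k / 4)`, `k = 1..3` (half away from zero),
#' in the rectangle's local coordinates.
#'
#' @param img Grayscale matrix.
#' @param mask Optional 0/1 matrix; its nonzero bounding rectangle is
#'   sampled.  Both rectangle sides must be at least 12 pixels.
#' @return A list of 9 regions (row-major over the 3 x 3 center grid), each
#'   a list with `center = c(row, col)` and `window = c(r0, r1, c0, c1)`,
#'   1-based inclusive image coordinates.
#' @export
#' @examples
#' regs <- sampling_regions(matrix(0L, 40, 40))
#' regs[[1]]$center  # rows/cols 11 (0-based: 10)
sampling_regions <- function(img, mask = NULL) {
  .check_gray(img)
  rect <- .bounding_rect(img, mask)
  H <- rect["r1"] - rect["r0"] + 1L
  W <- rect["c1"] - rect["c0"] + 1L
  if (H < 12L || W < 12L)
    stop(sprintf(
      "bounding rectangle is %dx%d; both sides must be >= 12 pixels", H, W),
      call. = FALSE)
  wh <- as.integer(ceiling(H / 4)); ww <- as.integer(ceiling(W / 4))
  rc <- .round_half_up(H * (1:3) / 4)   # 0-based local rows of the centers
  cc <- .round_half_up(W * (1:3) / 4)
  regions <- vector("list", 9L)
  k <- 0L
  for (pr in rc) {
    for (pc in cc) {
      r0 <- max(0, pr - wh %/% 2L); r1 <- min(H - 1L, pr - wh %/% 2L + wh - 1L)
      c0 <- max(0, pc - ww %/% 2L); c1 <- min(W - 1L, pc - ww %/% 2L + ww - 1L)
      if (r1 - r0 + 1L < 3L || c1 - c0 + 1L < 3L ||
          pr <= r0 || pr >= r1 || pc <= c0 || pc >= c1)
        stop("sampling-region window too small for directional rays",
             call. = FALSE)
      k <- k + 1L
      regions[[k]] <- list(
        center = c(row = unname(rect["r0"] + pr), col = unname(rect["c0"] + pc)),
        window = c(r0 = unname(rect["r0"] + r0), r1 = unname(rect["r0"] + r1),
                   c0 = unname(rect["c0"] + c0), c1 = unname(rect["c0"] + c1))
      )
    }
  }
  regions
}

#' Directional pixel rays of a sampling region
#'
#' For each of the eight [directions()], the half-ray of pixels starting at
#' the region center (included) and stepping by the direction offset until
#' leaving the region window.
#'
#' @param region One element of [sampling_regions()].
#' @param img Grayscale matrix the region belongs to.
#' @return A list of 8 numeric vectors, each of length at least 2.
#' @export
region_rays <- function(region, img) {
  .check_gray(img)
  w <- region$window
  rays <- vector("list", 8L)
  for (d in 1:8) {
    dr <- .DIRECTIONS[d, 1L]; dc <- .DIRECTIONS[d, 2L]
    r <- region$center[["row"]]; cl <- region$center[["col"]]
    vals <- numeric(0)
    while (r >= w[["r0"]] && r <= w[["r1"]] &&
           cl >= w[["c0"]] && cl <= w[["c1"]]) {
      vals <- c(vals, img[r, cl])
      r <- r + dr; cl <- cl + dc
    }
    if (length(vals) < 2L)
      stop("region window too small: a directional ray has fewer than 2 pixels",
           call. = FALSE)
    rays[[d]] <- vals
  }
  rays
}

#' Roughness of one sampling region
#'
#' Mean of the eight [directional_deviation()] values over the region's
#' rays.
#'
#' @inheritParams region_rays
#' @return Scalar region roughness, intensity units.
#' @export
region_roughness <- function(region, img) {
  mean(vapply(region_rays(region, img), directional_deviation, numeric(1)))
}

#' Peel roughness of an image
#'
#' The surface-roughness statistic used to separate fruit ripeness stages:
#' the bounding rectangle (of the mask's nonzero pixels if given, else the
#' whole image) is sampled at nine regions ([sampling_regions()]); in each,
#' the mean absolute intensity deviation is computed along eight directional
#' rays and averaged; the overall roughness is the mean over the nine
#' regions.  Smooth surfaces score near 0; high-amplitude fine texture
#' scores high.
#'
#' @inheritParams sampling_regions
#' @return A `roughness_report`: list with `per_region_di` (9 x 8 matrix of
#'   directional deviations), `per_region_pi` (9 region means), `overall`
#'   (scalar), and `regions`.
#' @export
#' @examples
#' img <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
#' peel_roughness(img)$overall
peel_roughness <- function(img, mask = NULL) {
  regions <- sampling_regions(img, mask)
  di <- matrix(NA_real_, 9L, 8L,
               dimnames = list(paste0("region", 1:9), paste0("dir", 1:8)))
  for (k in 1:9) {
    di[k, ] <- vapply(region_rays(regions[[k]], img), directional_deviation,
                      numeric(1))
  }
  pi_vals <- rowMeans(di)
  structure(
    list(per_region_di = di,
         per_region_pi = unname(pi_vals),
         overall = mean(pi_vals),
         regions = regions),
    class = "roughness_report"
  )
}

#' @export
print.roughness_report <- function(x, ...) {
  cat("Peel roughness report\n")
  cat(sprintf("  overall roughness: %.4f\n", x$overall))
  cat("  per-region values:",
      paste(sprintf("%.2f", x$per_region_pi), collapse = " "), "\n")
  invisible(x)
}
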