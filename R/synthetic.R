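#' Synthetic fruit-scene specification
#'
#' Parameters of the seeded scene generator: a disc-shaped fruit with a
#' spatially correlated surface-texture field on a smoothly textured leafy
#' background.  The generator stands in for orchard photographs so that the
#' texture pipeline is testable offline; see the methods vignette for what
#' it does and does not emulate.
#'
#' @param height,width Frame size in pixels.
#' @param disc_center Fruit center `c(row, col)`, 1-based.
#' @param disc_radius Fruit radius in pixels; the disc must keep a margin of
#'   at least 6 pixels to every frame edge.
#' @param fruit_rgb Base peel color, RGB triple in `[0, 255]`.
#' @param noise_sigma Marginal standard deviation (intensity units) of the
#'   fruit surface-texture field.  Roughness decreases with ripeness, so
#'   riper stages use smaller values.
#' @param texture_scale Spatial correlation scale (Gaussian smoothing sigma,
#'   pixels) of the fruit surface field.  Default 8: peel relief spans
#'   several pixels in close-range imagery rather than flickering per pixel.
#' @param bg_rgb Base background color (leafy green by default).
#' @param bg_noise_sigma Marginal standard deviation of the background
#'   field.
#' @param bg_blur_sigma Spatial smoothing of the background field (pixels);
#'   larger than `texture_scale` would blur leaves away, smaller would make
#'   the background fruit-like.
#' @param seed Integer seed; identical specs generate bit-identical scenes.
#' @param fruit_stream Substream index (>= 1) for the fruit field, used by
#'   [generate_stage_series()] so the four stages share one background
#'   realization while drawing independent surface fields.
#' @return An object of class `scene_spec`.
#' @export
#' @examples
#' spec <- scene_spec(seed = 7)
#' sc <- generate_fruit_scene(spec)
#' dim(sc$image); mean(sc$mask)
scene_spec <- function(height = 256L, width = 256L,
                       disc_center = c(128L, 128L), disc_radius = 60L,
                       fruit_rgb = c(70L, 150L, 60L), noise_sigma = 30,
                       texture_scale = 8, bg_rgb = c(55L, 95L, 50L),
                       bg_noise_sigma = 18, bg_blur_sigma = 4,
                       seed = 7L, fruit_stream = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               disc_center = as.integer(disc_center),
               disc_radius = as.integer(disc_radius),
               fruit_rgb = as.numeric(fruit_rgb),
               noise_sigma = as.numeric(noise_sigma),
               texture_scale = as.numeric(texture_scale),
               bg_rgb = as.numeric(bg_rgb),
               bg_noise_sigma = as.numeric(bg_noise_sigma),
               bg_blur_sigma = as.numeric(bg_blur_sigma),
               seed = as.integer(seed),
               fruit_stream = as.integer(fruit_stream))
  class(spec) <- "scene_spec"
  .validate_scene_spec(spec)
  spec
}

.validate_scene_spec <- function(spec) {
  with(spec, {
    if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
    if (length(fruit_rgb) != 3L || length(bg_rgb) != 3L)
      stop("colors must be RGB triples", call. = FALSE)
    if (disc_center[1] - disc_radius < 7L ||
        disc_center[1] + disc_radius > height - 6L ||
        disc_center[2] - disc_radius < 7L ||
        disc_center[2] + disc_radius > width - 6L)
      stop("disc must fit inside the frame with a margin of at least 6 pixels",
           call. = FALSE)
    if (fruit_stream < 1L) stop("`fruit_stream` must be >= 1", call. = FALSE)
  })
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Scene spec: %dx%d frame, disc r=%d at (%d,%d), sigma=%.1f, seed=%d\n",
    x$height, x$width, x$disc_radius, x$disc_center[1], x$disc_center[2],
    x$noise_sigma, x$seed))
  invisible(x)
}

# substream seeding: distinct, collision-free seeds for background (k = 0)
# and the four stage fruit fields (k = 1..4), also disjoint across the
# consecutive series seeds used by generate_group_set
.substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 5 + k) %% 2147483647)
}

.gauss_kernel <- function(s) {
  r <- max(1L, as.integer(ceiling(3 * s)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * s^2))
  k / sum(k)
}

# separable Gaussian smoothing with replicated edges, as two band-matrix
# products (BLAS-backed; no per-row extraction loops)
.blur2d <- function(m, s) {
  if (s <= 0) return(m)
  k <- .gauss_kernel(s)
  r <- as.integer((length(k) - 1L) / 2L)
  h <- nrow(m); w <- ncol(m)
  p <- pad_replicate(m, r)
  band <- function(n) {
    B <- matrix(0, n, n + 2L * r)
    for (t in seq_along(k)) B[cbind(seq_len(n), seq_len(n) + t - 1L)] <- k[t]
    B
  }
  band(h) %*% p %*% t(band(w))
}

# seeded correlated Gaussian field with marginal sd = sigma
.noise_field <- function(seed, h, w, blur, sigma) {
  if (sigma == 0) return(matrix(0, h, w))
  set.seed(seed)
  f <- .blur2d(matrix(rnorm(h * w), h, w), blur)
  f / sd(as.vector(f)) * sigma
}

#' Generate a synthetic fruit scene
#'
#' Renders one scene from a [scene_spec()]: the mask is 1 exactly where
#' `(r - cr)^2 + (c - cc)^2 <= radius^2` (no anti-aliased fringe); fruit
#' pixels are `fruit_rgb` plus a single correlated noise field shared by all
#' three channels; background pixels are `bg_rgb` plus a smoothed field.
#' Values are computed in float, then rounded and clamped to `[0, 255]`
#' once.  Identical specs yield bit-identical scenes.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (`h x w x 3` integer array), `mask` (0/1
#'   integer matrix), and `spec`.
#' @export
generate_fruit_scene <- function(spec) {
  .validate_scene_spec(spec)
  h <- spec$height; w <- spec$width
  cr <- spec$disc_center[1]; cc <- spec$disc_center[2]
  mask <- outer(seq_len(h), seq_len(w),
                function(r, c) {
                  (r - cr)^2 + (c - cc)^2 <= spec$disc_radius^2
                }) + 0L
  bg_field <- .noise_field(.substream_seed(spec$seed, 0L), h, w,
                           spec$bg_blur_sigma, spec$bg_noise_sigma)
  fruit_field <- .noise_field(.substream_seed(spec$seed, spec$fruit_stream),
                              h, w, spec$texture_scale, spec$noise_sigma)
  img <- array(0L, c(h, w, 3L))
  sel <- mask == 1L
  for (ch in 1:3) {
    plane <- spec$bg_rgb[ch] + bg_field
    plane[sel] <- spec$fruit_rgb[ch] + fruit_field[sel]
    img[, , ch] <- pmin(pmax(.round_half_up(plane), 0), 255)
  }
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, spec = spec)
}

# stage defaults: surface-texture amplitudes decreasing with ripeness and
# peel colors interpolating green -> orange (A least ripe ... D ripest)
.STAGE_SIGMAS <- c(30, 20, 12, 5)
.STAGE_COLORS <- list(c(70, 150, 60), c(130, 160, 55),
                      c(200, 160, 45), c(245, 160, 40))

#' Generate a four-stage ripeness series
#'
#' Four scenes labeled A (least ripe) to D (ripest) sharing geometry, seed
#' and background realization, differing in the fruit surface-texture
#' amplitude (strictly decreasing, mirroring the smoothing of the peel as
#' epicuticular wax accumulates) and base peel color (green to orange).
#' Peel roughness of the grayscaled fruit crop decreases A to D under the
#' default amplitudes.
#'
#' @param base A [scene_spec()]; its `noise_sigma`, `fruit_rgb` and
#'   `fruit_stream` are overridden per stage.
#' @param sigmas Four strictly decreasing surface amplitudes, default
#'   `c(30, 20, 12, 5)`.
#' @param colors List of four RGB triples, default green through orange.
#' @return A `stage_series`: list with `scenes` (four scene lists as from
#'   [generate_fruit_scene()]), `labels` (`A`-`D`), `sigmas`, `colors`,
#'   `seed`.
#' @export
#' @examples
#' ser <- generate_stage_series(scene_spec(seed = 1))
#' sapply(ser$scenes, function(s) mean(s$image))
generate_stage_series <- function(base = scene_spec(),
                                  sigmas = .STAGE_SIGMAS,
                                  colors = .STAGE_COLORS) {
  if (length(sigmas) != 4L || any(diff(sigmas) >= 0))
    stop("`sigmas` must be four strictly decreasing values", call. = FALSE)
  if (length(colors) != 4L)
    stop("`colors` must list four RGB triples", call. = FALSE)
  scenes <- lapply(1:4, function(s) {
    spec <- base
    spec$noise_sigma <- as.numeric(sigmas[s])
    spec$fruit_rgb <- as.numeric(colors[[s]])
    spec$fruit_stream <- s
    generate_fruit_scene(spec)
  })
  structure(list(scenes = scenes, labels = c("A", "B", "C", "D"),
                 sigmas = as.numeric(sigmas), colors = colors,
                 seed = base$seed),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("Stage series (seed %d): sigmas %s\n", x$seed,
              paste(x$sigmas, collapse = " > ")))
  invisible(x)
}

#' Generate a set of independent stage-series groups
#'
#' `n_groups` series with seeds `base$seed + 0:(n_groups - 1)`; the unit of
#' the roughness-difference experiment (the study design uses 50 groups of
#' four stages, i.e. 200 scenes).
#'
#' @param n_groups Number of groups, at least 1.
#' @param base A [scene_spec()] providing geometry and the base seed.
#' @inheritParams generate_stage_series
#' @return List of `n_groups` [generate_stage_series()] results.
#' @export
generate_group_set <- function(n_groups, base = scene_spec(),
                               sigmas = .STAGE_SIGMAS,
                               colors = .STAGE_COLORS) {
  n_groups <- as.integer(n_groups)
  if (is.na(n_groups) || n_groups < 1L)
    stop("`n_groups` must be >= 1", call. = FALSE)
  lapply(seq_len(n_groups) - 1L, function(g) {
    spec <- base
    spec$seed <- base$seed + g
    generate_stage_series(spec, sigmas = sigmas, colors = colors)
  })
}
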