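#' Compose a texture-enhanced training image
#'
#' Builds the synthetic training image used to enrich detector training
#' sets: the fruit segment (mask = 1) is replaced by its R-LBP encoding
#' while the background (mask = 0) is reduced to grayscale.  The encoding at
#' fruit-border pixels reads neighbour intensities from the full grayscaled
#' image regardless of the mask (crop-free), so no spurious edges are
#' fabricated at the mask boundary.
#'
#' @param img Color image (`h x w x 3` array) or grayscale matrix.
#' @param mask 0/1 matrix of the same shape (nonzero = fruit).
#' @param params An [rlbp_params()] object.
#' @param provenance Optional list (e.g. source/mask paths) carried through
#'   to the result.
#' @return A `composed_scene`: list with `image` (grayscale matrix),
#'   `params`, and `provenance`.
#' @export
#' @examples
#' img <- array(sample(0:255, 48 * 48 * 3, replace = TRUE), c(48, 48, 3))
#' mask <- matrix(0L, 48, 48); mask[10:30, 10:30] <- 1L
#' sc <- compose_scene(img, mask)
#' dim(sc$image)
compose_scene <- function(img, mask, params = rlbp_params(),
                          provenance = NULL) {
  .check_mask(mask, img)
  g <- to_grayscale(img)
  out <- g
  if (any(mask != 0)) {
    codes <- rlbp_transform(g, params)
    sel <- mask != 0
    out[sel] <- codes[sel]
  }
  storage.mode(out) <- "integer"
  structure(list(image = out, params = params, provenance = provenance),
            class = "composed_scene")
}

#' @export
print.composed_scene <- function(x, ...) {
  cat(sprintf("Composed scene: %d x %d (R-LBP fruit on grayscale background)\n",
              nrow(x$image), ncol(x$image)))
  if (!is.null(x$provenance$source))
    cat("  source:", x$provenance$source, "\n")
  invisible(x)
}

# supported raster extensions for dataset scanning
.IMG_EXT <- c("png", "jpg", "jpeg")

.list_stems <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% .IMG_EXT]
  stats::setNames(files, tools::file_path_sans_ext(basename(files)))
}

#' Build a texture-enhanced training set
#'
#' Applies [compose_scene()] to every image in `images_dir` whose same-stem
#' mask exists in `masks_dir`, writing the result as PNG (`<stem>_rlbp.png`)
#' into `out_dir`.  Plain-text detection label files (`<stem>.txt`, one box
#' per line: integer class plus four normalized floats) found in
#' `labels_dir` are copied byte-identically (`<stem>_rlbp.txt`), since
#' composition never moves objects.  Images without a mask are skipped and
#' listed in the `skipped` attribute of the return value, not fatal.
#'
#' @param images_dir Directory of input PNG/JPEG images.
#' @param masks_dir Directory of same-stem mask PNGs (nonzero = fruit).
#' @param labels_dir Optional directory of same-stem `.txt` label files.
#' @param out_dir Output directory (created if missing).
#' @param params An [rlbp_params()] object.
#' @return Integer count of scenes written, with attribute `skipped` naming
#'   input stems that had no mask.
#' @export
build_training_set <- function(images_dir, masks_dir, labels_dir = NULL,
                               out_dir, params = rlbp_params()) {
  if (!dir.exists(images_dir))
    stop(sprintf("images directory not found: %s", images_dir), call. = FALSE)
  if (!dir.exists(masks_dir))
    stop(sprintf("masks directory not found: %s", masks_dir), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- .list_stems(images_dir)
  masks <- .list_stems(masks_dir)
  written <- 0L
  skipped <- character(0)
  for (stem in names(imgs)) {
    if (!stem %in% names(masks)) {
      skipped <- c(skipped, stem)
      next
    }
    img <- read_image(imgs[[stem]])
    mask <- read_mask(masks[[stem]])
    sc <- compose_scene(img, mask, params,
                        provenance = list(source = imgs[[stem]],
                                          mask = masks[[stem]]))
    write_image(sc$image, file.path(out_dir, paste0(stem, "_rlbp.png")))
    if (!is.null(labels_dir)) {
      lab <- file.path(labels_dir, paste0(stem, ".txt"))
      if (file.exists(lab))
        file.copy(lab, file.path(out_dir, paste0(stem, "_rlbp.txt")),
                  overwrite = TRUE)
    }
    written <- written + 1L
  }
  if (length(skipped))
    message(sprintf("skipped %d image(s) without masks: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  structure(written, skipped = skipped)
}
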