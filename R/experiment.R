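#' Preprocessing arms of the roughness-difference experiment
#'
#' @return Character vector of the three arm names: `"grayscale"` (no
#'   transform), `"lbp"`, `"rlbp"`.
#' @export
preprocess_methods <- function() c("grayscale", "lbp", "rlbp")

# transform one grayscale crop per arm
.apply_method <- function(crop, method, params) {
  switch(method,
         grayscale = crop,
         lbp = lbp_transform(crop),
         rlbp = rlbp_transform(crop, params),
         stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

.adjacent_mean_abs_diff <- function(values) mean(abs(diff(values)))

# grayscaled fruit crop (mask bounding rectangle) of one scene
.fruit_crop <- function(scene) {
  g <- to_grayscale(scene$image)
  rect <- .bounding_rect(g, scene$mask)
  g[rect[["r0"]]:rect[["r1"]], rect[["c0"]]:rect[["c1"]], drop = FALSE]
}

#' Average adjacent-stage roughness difference of one group
#'
#' Each stage's fruit crop (the bounding rectangle of its mask) is
#' grayscaled, transformed per `method` (the grayscale arm applies no
#' transform), and scored with [peel_roughness()]; the group's value is the
#' mean of the three absolute differences between consecutive-stage
#' roughness values, `mean(|P_A - P_B|, |P_B - P_C|, |P_C - P_D|)`.
#'
#' @param series A [generate_stage_series()] result (or any list with four
#'   `scenes`, each carrying `image` and `mask`).
#' @param method One of [preprocess_methods()].
#' @param params An [rlbp_params()] object (used by the code arms).
#' @return Scalar mean adjacent-stage roughness difference.
#' @export
group_difference <- function(series, method = preprocess_methods(),
                             params = rlbp_params()) {
  method <- match.arg(method)
  if (length(series$scenes) != 4L)
    stop("`series` must hold four ordered stages", call. = FALSE)
  p <- vapply(series$scenes, function(sc) {
    crop <- .fruit_crop(sc)
    peel_roughness(.apply_method(crop, method, params))$overall
  }, numeric(1))
  .adjacent_mean_abs_diff(p)
}

#' Summary statistics of per-group roughness differences
#'
#' Computes [group_difference()] for every group and summarizes the
#' distribution by median, quartiles and interquartile range.  Quartiles
#' use linear interpolation between the closest order statistics
#' ([stats::quantile()] type 7).
#'
#' @param groups List of stage series, e.g. from [generate_group_set()].
#' @inheritParams group_difference
#' @return A `distribution_stats`: list with `median`, `q1`, `q3`, `iqr`,
#'   `n`, `method`, and the per-group `values`.
#' @export
#' @examples
#' groups <- generate_group_set(3, scene_spec(seed = 1))
#' run_experiment1(groups, "grayscale")
run_experiment1 <- function(groups, method = preprocess_methods(),
                            params = rlbp_params()) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 1L)
    stop("`groups` must be a non-empty list of stage series", call. = FALSE)
  values <- vapply(groups, group_difference, numeric(1),
                   method = method, params = params)
  distribution_stats(values, method = method)
}

#' Construct distribution statistics from per-group values
#'
#' @param values Numeric vector of per-group averages.
#' @param method Optional label of the preprocessing arm.
#' @return A `distribution_stats` object; see [run_experiment1()].
#' @export
distribution_stats <- function(values, method = NA_character_) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
                 n = length(values), method = method, values = values),
            class = "distribution_stats")
}

#' @export
print.distribution_stats <- function(x, ...) {
  lab <- if (is.na(x$method)) "" else sprintf(" [%s]", x$method)
  cat(sprintf(
    "Roughness-difference distribution%s: n = %d\n  median %.2f, q1 %.2f, q3 %.2f, IQR %.2f\n",
    lab, x$n, x$median, x$q1, x$q3, x$iqr))
  invisible(x)
}
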