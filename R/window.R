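#' Percentile windowing of the breast region
#'
#' Standardizes raw intensities to \[0, 1\] inside the breast and inverts
#' polarity so dense (attenuating, low-signal) tissue is bright. The lower
#' bound is the minimum in-breast intensity (the densest pixel, mapped to 1);
#' the upper bound is the 75th percentile of the in-breast intensity
#' distribution. Pixels at or above the upper bound — the darkest 25% of the
#' breast after inversion, mostly the uncompressed breast edge — are set to 0
#' and flagged background, excluded from all texture statistics. Intermediate
#' intensities are mapped linearly from 1 down to 0. The quantile convention is
#' linear interpolation between order statistics (R type 7), so the map depends
#' only on the affine position of intensities: `a * img + b` (a > 0) windows
#' identically to `img`.
#'
#' @param img a [raw_mammogram()].
#' @param mask logical breast mask congruent with `img`.
#' @return An object of class `windowed_image` with elements `values` (matrix
#'   in \[0,1\]), `background` (logical matrix, `TRUE` = excluded),
#'   `lower_bound`, `upper_bound` (original-intensity scalars) and
#'   `pixel_spacing`.
#' @export
window_breast <- function(img, mask) {
  stopifnot(inherits(img, "raw_mammogram"))
  mask <- check_mask(mask, img$pixels)
  px <- img$pixels
  inside <- px[mask]
  lower <- min(inside)
  upper <- unname(quantile(inside, 0.75, type = 7))
  if (upper <= lower)
    stop("degenerate window: breast region has no intensity spread ",
         "(lower bound == upper bound)")
  v <- (upper - px) / (upper - lower)
  v <- pmin(pmax(v, 0), 1)
  background <- !mask | px >= upper
  v[background] <- 0
  structure(
    list(values = v, background = background,
         lower_bound = lower, upper_bound = upper,
         pixel_spacing = img$pixel_spacing),
    class = "windowed_image"
  )
}

#' @export
print.windowed_image <- function(x, ...) {
  cat(sprintf("<windowed_image> %d x %d, window [%g, %g], %.1f%% background\n",
              nrow(x$values), ncol(x$values), x$lower_bound, x$upper_bound,
              100 * mean(x$background)))
  invisible(x)
}
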