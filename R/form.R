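#' Form (shape) features of the breast region
#'
#' Area in mm^2, the diameter of a circle with the same area as the breast
#' region, the boundary perimeter (count of exposed pixel edges times the
#' pixel spacing — a taxicab perimeter, which overestimates smooth contours)
#' and circularity `4*pi*A / P^2`.
#'
#' @param mask logical breast mask.
#' @param pixel_spacing mm per pixel.
#' @return Named numeric vector.
#' @export
form_features <- function(mask, pixel_spacing) {
  stopifnot(is.logical(mask), is.matrix(mask), pixel_spacing > 0)
  n <- sum(mask)
  if (n == 0L) stop("empty mask has no form features")
  area <- n * pixel_spacing^2
  # exposed edges: neighbour transitions plus border-touching edges
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  edges <- sum(padded[-1, ] & !padded[-nrow(padded), ]) +
    sum(!padded[-1, ] & padded[-nrow(padded), ]) +
    sum(padded[, -1] & !padded[, -ncol(padded)]) +
    sum(!padded[, -1] & padded[, -ncol(padded)])
  perim <- edges * pixel_spacing
  c(area_mm2 = area,
    equivalent_diameter_mm = 2 * sqrt(area / pi),
    perimeter_mm = perim,
    circularity = 4 * pi * area / perim^2)
}
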