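#' Automatic breast segmentation for raw FFDM images
#'
#' Raw ("for processing") mammograms have a bright air background and a darker,
#' attenuating breast. The breast region is recovered as the largest connected
#' component of pixels *below* an automatically chosen global (Otsu) threshold,
#' with interior holes filled. The procedure is deterministic for a fixed
#' image. When a validated external mask exists, pass it downstream directly
#' instead of calling this.
#'
#' @param img a [raw_mammogram()].
#' @param connectivity 4 or 8 neighbourhood for the connected components.
#' @return A logical matrix (`TRUE` = inside breast).
#' @export
segment_breast <- function(img, connectivity = 8L) {
  stopifnot(inherits(img, "raw_mammogram"))
  px <- img$pixels
  if (diff(range(px)) == 0)
    stop("segmentation failure: image is constant, no separable foreground")
  thr <- otsu_threshold(px)
  fg <- px < thr
  if (!any(fg))
    stop("segmentation failure: no pixels below the global threshold")
  lab <- .label_components_cpp(matrix(as.integer(fg), nrow(fg)), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  mask <- fill_holes(mask)
  if (sum(mask) < 64L)
    stop("segmentation failure: candidate breast region smaller than 64 pixels")
  mask
}

#' Otsu's global threshold
#'
#' Maximises between-class variance over a 256-bin histogram of the intensity
#' range. Returns a threshold on the original intensity scale; foreground
#' (breast) is conventionally the class *below* the threshold in raw FFDM.
#'
#' @param x numeric matrix or vector of intensities.
#' @param nbins number of histogram bins.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (diff(r) == 0) stop("constant input has no threshold")
  b <- pmin(nbins, floor((x - r[1]) / diff(r) * nbins) + 1L)
  h <- tabulate(b, nbins)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- w0 * (1 - w0)
  sb <- (mu_t * w0 - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(sb)
  r[1] + k / nbins * diff(r)
}

# fill holes: background components not touching the image border become mask
fill_holes <- function(mask) {
  bg <- !mask
  lab <- .label_components_cpp(matrix(as.integer(bg), nrow(bg)), 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  dim(hole) <- dim(mask)
  mask | hole
}

#' Dice overlap between two masks
#' @param a,b logical matrices of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
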