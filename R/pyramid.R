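#' Bicubic resampling (Catmull-Rom / Keys kernel, a = -0.5)
#'
#' Separable cubic-convolution resampling with edge replication, the common
#' "bicubic interpolation" default. Output pixel centre `i` samples the input
#' at `u = (i - 0.5) * factor + 0.5` (the Matlab `imresize` grid convention);
#' no antialias prefilter is applied, so the operation is the direct evaluation
#' of the separable kernel at the sample points. The kernel weights sum to one
#' at every sample position (edge replication folds clipped taps back in), so
#' constants are reproduced to machine precision.
#'
#' @param x numeric matrix.
#' @param factor downsize factor (> 0; values < 1 upsample). Output dimensions
#'   are `ceiling(dim(x) / factor)`.
#' @return Resampled matrix.
#' @export
bicubic_resize <- function(x, factor) {
  stopifnot(is.matrix(x), is.numeric(factor), factor > 0)
  Wr <- cubic_weights(nrow(x), factor)
  Wc <- cubic_weights(ncol(x), factor)
  Wr %*% x %*% t(Wc)
}

keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * (t^3 - 5 * t^2 + 8 * t - 4), 0))
}

# n_out x n_in weight matrix for 1-D cubic convolution at scale `factor`
cubic_weights <- function(n_in, factor) {
  n_out <- as.integer(ceiling(n_in / factor))
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) * factor + 0.5
    base <- floor(u)
    for (k in -1:2) {
      j <- base + k
      w <- keys_kernel(u - j)
      jc <- min(n_in, max(1L, j)) # edge replication
      W[i, jc] <- W[i, jc] + w
    }
  }
  W
}

# nearest-neighbour source index for each output position
nn_index <- function(n_in, factor) {
  n_out <- as.integer(ceiling(n_in / factor))
  u <- (seq_len(n_out) - 0.5) * factor + 0.5
  pmin(n_in, pmax(1L, as.integer(floor(u + 0.5))))
}

#' Build a multi-resolution image pyramid
#'
#' Downsizes a windowed image by each requested integer factor using bicubic
#' interpolation of the value grid; resampled values are clipped back to
#' \[0, 1\]. The background mask is propagated by nearest neighbour and
#' re-binarized: a coarse pixel is background iff its nearest source pixel is
#' background, which keeps background zeros from bleeding into coarse texture
#' statistics while staying deterministic. Level 1 is the source image itself,
#' bit-identical.
#'
#' @param win a [window_breast()] result.
#' @param factors integer downsize factors, each in 1..128.
#' @return An object of class `image_pyramid`: a named list of levels keyed by
#'   factor, each a `windowed_image`.
#' @export
build_pyramid <- function(win, factors = c(1, 2, 4, 6, 8, 16, 32, 64)) {
  stopifnot(inherits(win, "windowed_image"))
  factors <- as.integer(sort(unique(factors)))
  if (any(factors < 1L) || any(factors > 128L))
    stop("downsize factors must be integers in 1..128")
  dmin <- min(dim(win$values))
  if (any(factors > dmin))
    stop("downsize factor ", max(factors), " exceeds the smallest image ",
         "dimension (", dmin, ")")
  levels <- lapply(factors, function(d) {
    if (d == 1L) return(win)
    v <- pmin(pmax(bicubic_resize(win$values, d), 0), 1)
    bg <- win$background[nn_index(nrow(win$values), d),
                         nn_index(ncol(win$values), d), drop = FALSE]
    v[bg] <- 0
    structure(list(values = v, background = bg,
                   lower_bound = win$lower_bound,
                   upper_bound = win$upper_bound,
                   pixel_spacing = win$pixel_spacing * d),
              class = "windowed_image")
  })
  names(levels) <- as.character(factors)
  structure(list(levels = levels, factors = factors), class = "image_pyramid")
}

#' @export
print.image_pyramid <- function(x, ...) {
  cat("<image_pyramid> factors:", paste(x$factors, collapse = ", "), "\n")
  invisible(x)
}
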