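#' Grey-level quantization
#'
#' Groups non-background windowed values into `n_grey` equal-width bins over
#' \[0, 1\]: `level = min(n_grey, floor(v * n_grey) + 1)`, so a value of
#' exactly 1 falls in the top bin. Background pixels are coded 0 and are
#' excluded from every co-occurrence, run and zone statistic.
#'
#' @param win a [window_breast()] result or one pyramid level.
#' @param n_grey number of grey levels (>= 2; the study default is 10).
#' @return An object of class `quantized_image` with integer matrix `levels`
#'   (0 = background) and `n_grey`.
#' @export
quantize <- function(win, n_grey = 10L) {
  stopifnot(inherits(win, "windowed_image"))
  n_grey <- as.integer(n_grey)
  if (n_grey < 2L) stop("n_grey must be at least 2")
  lev <- pmin(floor(win$values * n_grey) + 1L, n_grey)
  lev[win$background] <- 0L
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, n_grey = n_grey), class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %d x %d, Ng = %d, %d background px\n",
              nrow(x$levels), ncol(x$levels), x$n_grey, sum(x$levels == 0L)))
  invisible(x)
}
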