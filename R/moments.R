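#' Histogram moments of a windowed image
#'
#' First-order statistics over the non-background pixels of a windowed image:
#' mean, standard deviation (n-1 denominator; the "SD" feature of the
#' mammographic-texture literature), skewness (`m3 / m2^1.5`), excess
#' kurtosis (`m4 / m2^2 - 3`) and selected percentiles. On a constant region
#' the sd is 0 and skewness/kurtosis are undefined: they are returned as `NA`
#' and such flagged values are dropped (with a logged count) before feature
#' selection rather than raising an error.
#'
#' @param win a [window_breast()] result or pyramid level.
#' @param probs percentile probabilities to report.
#' @return Named numeric vector.
#' @export
histogram_moments <- function(win, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(win, "windowed_image"))
  v <- win$values[!win$background]
  if (length(v) < 2L)
    stop("histogram moments need at least 2 non-background pixels")
  m <- mean(v)
  s <- sd(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  pc <- quantile(v, probs, type = 7, names = FALSE)
  out <- c(mean = m, sd = s, skewness = skew, kurtosis = kurt, pc)
  names(out)[-(1:4)] <- paste0("p", round(100 * probs))
  out
}
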