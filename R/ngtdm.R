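#' Neighbourhood grey-tone difference matrix and features
#'
#' Builds the NGTDM over 3x3 neighbourhoods: for every non-background pixel
#' with a full 3x3 window inside the image, the average grey level `A` of its
#' non-background neighbours (centre excluded, renormalized over the
#' neighbours actually present) is compared with the pixel's own level `i`,
#' and `|i - A|` is accumulated into `s(i)`. Pixels whose neighbourhood is
#' entirely background are excluded. The Amadasun-King features follow:
#' coarseness measures the amount of local grey-level variation (large = flat,
#' coarse texture), contrast the spread among grey levels together with local
#' variation, plus busyness, complexity and strength.
#'
#' Degenerate cases: a constant image has zero summed differences and its
#' coarseness is capped at `1e12` (epsilon `1e-12` in the denominator);
#' contrast, busyness, complexity and strength are 0 when fewer than two grey
#' levels are present.
#'
#' @param q a [quantize()]d image.
#' @return `ngtdm()` returns a list with `s` (per-level summed differences),
#'   `n` (per-level pixel counts) and `n_grey`; `ngtdm_features()` returns the
#'   named feature vector.
#' @export
ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  L <- q$levels
  nr <- nrow(L); nc <- ncol(L)
  if (nr < 3L || nc < 3L)
    stop("NGTDM needs an image of at least 3x3 pixels")
  V <- matrix(as.numeric(L), nr, nc)
  M <- matrix(as.numeric(L > 0L), nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  S <- matrix(0, length(ri), length(ci))
  Cn <- matrix(0, length(ri), length(ci))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    S <- S + V[ri + dr, ci + dc, drop = FALSE]
    Cn <- Cn + M[ri + dr, ci + dc, drop = FALSE]
  }
  Li <- L[ri, ci, drop = FALSE]
  use <- Li > 0L & Cn > 0
  if (!any(use))
    stop("NGTDM: no interior non-background pixels with neighbours")
  A <- S[use] / Cn[use]
  lev <- Li[use]
  diffs <- abs(lev - A)
  s <- vapply(seq_len(q$n_grey), function(i) sum(diffs[lev == i]), numeric(1))
  n <- tabulate(lev, q$n_grey)
  list(s = s, n = n, n_grey = q$n_grey)
}

#' @rdname ngtdm
#' @param eps denominator guard for coarseness and strength.
#' @export
ngtdm_features <- function(q, eps = 1e-12) {
  t <- if (inherits(q, "quantized_image")) ngtdm(q) else q
  N <- sum(t$n)
  p <- t$n / N
  s <- t$s
  lv <- seq_len(t$n_grey)
  nz <- which(p > 0)
  ngp <- length(nz)
  coarseness <- min(1 / (eps + sum(p * s)), 1e12)
  if (ngp < 2L)
    return(c(coarseness = coarseness, contrast = 0, busyness = 0,
             complexity = 0, strength = 0))
  pi_ <- p[nz]; si <- s[nz]; li <- lv[nz]
  dij2 <- outer(li, li, `-`)^2
  contrast <- sum(outer(pi_, pi_) * dij2) / (ngp * (ngp - 1)) * sum(s) / N
  ip <- li * pi_
  busy_den <- sum(abs(outer(ip, ip, `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  psi <- pi_ * si
  complexity <- sum(abs(outer(li, li, `-`)) *
                      outer(psi, psi, `+`) / outer(pi_, pi_, `+`)) / N
  strength <- sum(outer(pi_, pi_, `+`) * dij2) / (eps + sum(s))
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
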