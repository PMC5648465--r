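#' Grey-level co-occurrence matrix
#'
#' Joint distribution of grey-level pairs at a fixed pixel offset. Pairs of
#' non-background pixels at the given distance are counted over the requested
#' directions, pooled, symmetrized (both orderings of every pair are counted)
#' and normalized to sum 1. Pairs involving a background pixel are skipped.
#'
#' @param q a [quantize()]d image.
#' @param distance offset length in pixels (>= 1).
#' @param directions subset of `c(0, 45, 90, 135)` degrees.
#' @return An object of class `glcm`: `p` (Ng x Ng probability matrix),
#'   `n_pairs` (ordered pair count), `distance`, `directions`,
#'   `symmetric = TRUE`.
#' @export
compute_glcm <- function(q, distance = 1L, directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(q, "quantized_image"))
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1")
  directions <- as.integer(directions)
  if (!all(directions %in% c(0L, 45L, 90L, 135L)) || length(directions) == 0L)
    stop("directions must be a non-empty subset of {0, 45, 90, 135}")
  L <- q$levels
  ng <- q$n_grey
  nr <- nrow(L); nc <- ncol(L)
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                  `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  counts <- matrix(0, ng, ng)
  for (d in as.character(directions)) {
    o <- offsets[[d]] * distance
    r1 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c1 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    if (length(r1) == 0L || length(c1) == 0L) next
    A <- L[r1, c1, drop = FALSE]
    B <- L[r1 + o[1], c1 + o[2], drop = FALSE]
    keep <- A > 0L & B > 0L
    if (!any(keep)) next
    idx <- (A[keep] - 1L) * ng + B[keep]
    tab <- tabulate(idx, ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts) # symmetrize: count both orderings
  total <- sum(counts)
  if (total == 0)
    stop("no valid co-occurrence pairs (image too small or fully background)")
  structure(list(p = counts / total, n_pairs = total, distance = distance,
                 directions = directions, symmetric = TRUE),
            class = "glcm")
}

#' GLCM sum average
#'
#' The Haralick sum-average statistic `SA = sum_k k * p_{x+y}(k)` for
#' `k = 2..2*Ng`, where `p_{x+y}(k) = sum_{i+j=k} p(i, j)` is the diagonal-sum
#' marginal of the co-occurrence matrix. At coarse image resolutions this
#' feature indexes how dispersed the radiopaque (dense) tissue is: mixing of
#' bright and mid grey levels at large effective pixel sizes shifts mass of
#' `p_{x+y}` upward. Bounds: `2 <= SA <= 2*Ng`.
#'
#' @param g a [compute_glcm()] result.
#' @return Scalar sum average.
#' @export
sum_average <- function(g) {
  stopifnot(inherits(g, "glcm"))
  ng <- nrow(g$p)
  k <- outer(seq_len(ng), seq_len(ng), `+`)
  sum(k * g$p)
}

#' Haralick feature suite from a GLCM
#'
#' Standard Haralick statistics: contrast, energy (angular second moment),
#' homogeneity (inverse difference moment), correlation, entropy (natural
#' log), dissimilarity, sum average, sum entropy and difference entropy.
#' Correlation is `NA` when either marginal is degenerate (constant image).
#'
#' @param g a [compute_glcm()] result.
#' @return Named numeric vector.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ng) * px)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  # symmetric GLCM: x and y marginals coincide
  corr <- if (sd_x > 0) sum((i - mu_x) * (j - mu_x) * p) / sd_x^2 else NA_real_
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  c(contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + (i - j)^2)),
    correlation = corr,
    entropy = ent(p),
    sum_average = sum((2:(2 * ng)) * psum),
    sum_entropy = ent(psum),
    difference_entropy = ent(pdiff))
}
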