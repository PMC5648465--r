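#' Grey-level size zone matrix and features
#'
#' Zones are 8-connected components of pixels sharing the same grey level;
#' background pixels belong to no zone. The matrix counts zones by (grey
#' level, zone size). Features follow the Thibault set: small/large-area
#' emphasis, grey-level and size-zone non-uniformity, zone percentage and
#' low/high grey-level zone emphases.
#'
#' @param q a [quantize()]d image.
#' @return `glszm_matrix()`: integer matrix (grey level x zone size);
#'   `glszm_features()`: named numeric vector.
#' @export
glszm_matrix <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  lab <- .label_components_cpp(q$levels, 8L)
  k <- attr(lab, "n_components")
  if (k == 0L) stop("size-zone matrix is empty (fully background image)")
  sizes <- tabulate(lab[lab > 0L], k)
  first <- match(seq_len(k), lab)
  levels_of <- q$levels[first]
  counts <- matrix(0, q$n_grey, max(sizes))
  for (z in seq_len(k))
    counts[levels_of[z], sizes[z]] <- counts[levels_of[z], sizes[z]] + 1
  counts
}

#' @rdname glszm_matrix
#' @export
glszm_features <- function(q) {
  P <- if (inherits(q, "quantized_image")) glszm_matrix(q) else q
  n_px <- if (inherits(q, "quantized_image")) sum(q$levels > 0L) else NA_real_
  nz <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  s <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  c(sae = sum(P / s^2) / nz,
    lae = sum(P * s^2) / nz,
    gln = sum(rowSums(P)^2) / nz,
    szn = sum(colSums(P)^2) / nz,
    zone_percentage = nz / n_px,
    lgze = sum(P / i^2) / nz,
    hgze = sum(P * i^2) / nz)
}
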