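#' Grey-level run-length matrix and features
#'
#' Counts maximal runs of identical grey level along the four principal
#' directions (0, 45, 90, 135 degrees); background pixels break runs and are
#' never counted. The four directional matrices are pooled (summed) into one
#' matrix before the features are computed. Features are the classical
#' Galloway set (short/long-run emphasis, grey-level and run-length
#' non-uniformity, run percentage) plus the Chu low/high grey-level run
#' emphases.
#'
#' @param q a [quantize()]d image.
#' @return `runlength_matrix()`: integer matrix (grey level x run length);
#'   `runlength_features()`: named numeric vector.
#' @export
runlength_matrix <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  L <- q$levels
  nr <- nrow(L); nc <- ncol(L)
  maxlen <- max(nr, nc)
  counts <- matrix(0, q$n_grey, maxlen)
  add_lines <- function(lines) {
    for (v in lines) {
      r <- rle(v)
      keep <- r$values > 0L
      if (any(keep)) {
        idx <- cbind(r$values[keep], r$lengths[keep])
        for (k in seq_len(nrow(idx)))
          counts[idx[k, 1], idx[k, 2]] <<- counts[idx[k, 1], idx[k, 2]] + 1
      }
    }
  }
  add_lines(split(L, row(L)))                      # 0 degrees
  add_lines(split(L, col(L)))                      # 90 degrees
  add_lines(split(L, row(L) + col(L)))             # 45 degrees (anti-diagonals)
  add_lines(split(L, row(L) - col(L)))             # 135 degrees (diagonals)
  counts
}

#' @rdname runlength_matrix
#' @export
runlength_features <- function(q) {
  P <- if (inherits(q, "quantized_image")) runlength_matrix(q) else q
  n_px <- if (inherits(q, "quantized_image")) sum(q$levels > 0L) else NA_real_
  nr_runs <- sum(P)
  if (nr_runs == 0) stop("run-length matrix is empty (fully background image)")
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  l <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  c(sre = sum(P / l^2) / nr_runs,
    lre = sum(P * l^2) / nr_runs,
    gln = sum(rowSums(P)^2) / nr_runs,
    rln = sum(colSums(P)^2) / nr_runs,
    run_percentage = nr_runs / (4 * n_px),
    lgre = sum(P / i^2) / nr_runs,
    hgre = sum(P * i^2) / nr_runs)
}
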