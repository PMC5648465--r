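#' Correlation screening of a feature table
#'
#' Iteratively removes features until no retained pair has absolute Pearson
#' correlation above `threshold`. At each step the most correlated offending
#' pair is considered and the survivor is chosen uniformly at random from the
#' two (the screening used before model fitting: within a correlated pair the
#' feature taken forward is randomly selected). Constant features (undefined
#' correlation) are dropped first with a logged reason, and subjects with any
#' missing feature value are dropped with a logged count. Deterministic for a
#' fixed seed.
#'
#' @param x numeric matrix or data frame of features (columns named); a
#'   leading `subject_id` column is ignored.
#' @param threshold absolute-correlation cutoff (default 0.95).
#' @param seed integer seed controlling the random survivor choices.
#' @return An object of class `screen_result`: `kept` (ordered names),
#'   `dropped` (data frame: `dropped`, `correlated_with`, `r`; screening
#'   reasons `"constant"` carry `NA` partners), `n_subjects_dropped`, `seed`.
#' @export
correlation_screen <- function(x, threshold = 0.95, seed = 1L) {
  if (is.data.frame(x)) {
    if ("subject_id" %in% names(x)) x$subject_id <- NULL
    x <- as.matrix(x)
  }
  stopifnot(is.numeric(x), !is.null(colnames(x)))
  if (nrow(x) < 2L) stop("screening needs at least 2 subjects")
  ok <- stats::complete.cases(x)
  n_drop_subj <- sum(!ok)
  if (n_drop_subj > 0) {
    message("correlation_screen: dropping ", n_drop_subj,
            " subject(s) with missing feature values")
    x <- x[ok, , drop = FALSE]
  }
  dropped <- data.frame(dropped = character(0), correlated_with = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    cst <- colnames(x)[sds == 0]
    dropped <- rbind(dropped, data.frame(dropped = cst,
                                         correlated_with = NA_character_,
                                         r = NA_real_))
    x <- x[, sds > 0, drop = FALSE]
  }
  with_seed(seed, {
    C <- abs(cor(x))
    diag(C) <- 0
    while (ncol(x) > 1L && max(C) > threshold) {
      idx <- which(C == max(C), arr.ind = TRUE)[1, ]
      pair <- sort(colnames(x)[idx])
      survivor <- sample(pair, 1L)
      loser <- setdiff(pair, survivor)
      dropped <- rbind(dropped, data.frame(dropped = loser,
                                           correlated_with = survivor,
                                           r = max(C)))
      keep <- colnames(x) != loser
      x <- x[, keep, drop = FALSE]
      C <- C[keep, keep, drop = FALSE]
    }
  })
  structure(list(kept = colnames(x), dropped = dropped,
                 n_subjects_dropped = n_drop_subj, seed = seed),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> kept %d features, dropped %d (seed %d)\n",
              length(x$kept), nrow(x$dropped), x$seed))
  invisible(x)
}
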