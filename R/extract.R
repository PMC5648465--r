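#' Extract the full texture-feature vector from one mammogram
#'
#' Runs the whole per-image pipeline: optional rescale to the reference
#' resolution (10.628 px/mm), breast segmentation (unless a mask is given),
#' percentile windowing, the bicubic multi-resolution pyramid, and at every
#' pyramid level the GLCM, NGTDM, run-length and size-zone feature families;
#' histogram moments at the original resolution and form features of the mask
#' complete the vector. Feature names encode family, statistic and downsize
#' factor, e.g. `glcm.sum_average@64`. The computation is deterministic:
#' identical inputs give bit-identical vectors.
#'
#' @param img a [raw_mammogram()].
#' @param mask optional logical breast mask; segmented automatically if `NULL`.
#' @param factors pyramid downsize factors.
#' @param n_grey grey levels for quantization (study default 10).
#' @param families texture families to compute per level.
#' @param rescale logical; rescale non-reference-resolution input first.
#' @return Named numeric vector with attribute `subject_id`.
#' @export
extract_features <- function(img, mask = NULL,
                             factors = c(1, 2, 4, 6, 8, 16, 32, 64),
                             n_grey = 10L,
                             families = c("glcm", "ngtdm", "rlm", "glszm"),
                             rescale = TRUE) {
  stopifnot(inherits(img, "raw_mammogram"))
  families <- match.arg(families, several.ok = TRUE)
  ref_spacing <- 1 / REFERENCE_PX_PER_MM
  if (rescale && abs(img$pixel_spacing - ref_spacing) / ref_spacing > 1e-3) {
    d <- ref_spacing / img$pixel_spacing
    px <- pmax(bicubic_resize(img$pixels, d), 0)
    if (!is.null(mask))
      mask <- mask[nn_index(nrow(img$pixels), d), nn_index(ncol(img$pixels), d),
                   drop = FALSE]
    img <- raw_mammogram(round(px), ref_spacing, img$side, img$view,
                         img$subject_id)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(what, ": ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(mask)) mask <- stage("segment", segment_breast(img))
  mask <- check_mask(mask, img$pixels)
  win <- stage("window", window_breast(img, mask))
  pyr <- stage("pyramid", build_pyramid(win, factors))
  out <- numeric(0)
  for (d in names(pyr$levels)) {
    lev <- pyr$levels[[d]]
    q <- stage(paste0("quantize@", d), quantize(lev, n_grey))
    fam <- numeric(0)
    if ("glcm" %in% families) {
      gf <- stage(paste0("glcm@", d), glcm_features(compute_glcm(q)))
      fam <- c(fam, stats::setNames(gf, paste0("glcm.", names(gf))))
    }
    if ("ngtdm" %in% families) {
      nf <- stage(paste0("ngtdm@", d), ngtdm_features(q))
      fam <- c(fam, stats::setNames(nf, paste0("ngtdm.", names(nf))))
    }
    if ("rlm" %in% families) {
      rf <- stage(paste0("rlm@", d), runlength_features(q))
      fam <- c(fam, stats::setNames(rf, paste0("rlm.", names(rf))))
    }
    if ("glszm" %in% families) {
      zf <- stage(paste0("glszm@", d), glszm_features(q))
      fam <- c(fam, stats::setNames(zf, paste0("glszm.", names(zf))))
    }
    names(fam) <- paste0(names(fam), "@", d)
    out <- c(out, fam)
  }
  hm <- stage("moments", histogram_moments(win))
  out <- c(out, stats::setNames(hm, paste0("hist.", names(hm), "@1")))
  ff <- stage("form", form_features(mask, img$pixel_spacing))
  out <- c(out, stats::setNames(ff, paste0("form.", names(ff))))
  attr(out, "subject_id") <- img$subject_id
  out
}

#' Assemble per-subject feature vectors into a wide table
#'
#' @param vectors list of [extract_features()] results (or any named numeric
#'   vectors with a `subject_id` attribute).
#' @return A data frame with a `subject_id` column followed by one column per
#'   feature; all vectors must share an identical name set.
#' @export
feature_table <- function(vectors) {
  stopifnot(length(vectors) > 0)
  nm <- names(vectors[[1]])
  for (v in vectors)
    if (!identical(names(v), nm))
      stop("feature name sets differ between subjects")
  ids <- vapply(seq_along(vectors), function(i) {
    id <- attr(vectors[[i]], "subject_id")
    if (is.null(id)) paste0("subject_", i) else id
  }, character(1))
  out <- as.data.frame(do.call(rbind, lapply(vectors, as.numeric)))
  names(out) <- nm
  cbind(subject_id = ids, out)
}
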