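#' Risk score models
#'
#' A risk score model is a weighted sum of z-scored features:
#' `score = sum_t w_t * (x_t - mu_t) / sigma_t`. The published three-feature
#' model combines the GLCM sum average computed on images downsized by factors
#' of 16, 32 and 64 (at the reference resolution of 10.628 px/mm), with
#' standardized weights 0.044, 0.036 and 0.066, feature means 0.0555, 0.0559
#' and 0.0566 and standard deviations 0.000238, 0.000430 and 0.000775. Those
#' constants are training-cohort statistics on the source study's feature
#' scale and are stored verbatim.
#'
#' @param terms data frame with columns `feature`, `weight`, `mean`, `sd`.
#' @param reference_resolution pixels per mm the model's constants assume.
#' @return An object of class `risk_score_model`.
#' @export
risk_score_model <- function(terms, reference_resolution = REFERENCE_PX_PER_MM) {
  stopifnot(is.data.frame(terms),
            all(c("feature", "weight", "mean", "sd") %in% names(terms)))
  if (anyDuplicated(terms$feature)) stop("duplicate feature names in model")
  if (any(terms$sd <= 0)) stop("every term must have sd > 0")
  structure(list(terms = terms[, c("feature", "weight", "mean", "sd")],
                 reference_resolution = reference_resolution),
            class = "risk_score_model")
}

#' @rdname risk_score_model
#' @export
published_model <- function() {
  risk_score_model(data.frame(
    feature = c("glcm.sum_average@16", "glcm.sum_average@32",
                "glcm.sum_average@64"),
    weight = c(0.044, 0.036, 0.066),
    mean = c(0.0555, 0.0559, 0.0566),
    sd = c(0.000238, 0.000430, 0.000775),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat(sprintf("<risk_score_model> %d terms @ %.3f px/mm\n",
              nrow(x$terms), x$reference_resolution))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Apply a risk score model to feature values
#'
#' @param model a [risk_score_model()].
#' @param features a named numeric vector (one subject), or a data frame /
#'   matrix with one column per feature (a `subject_id` column is carried
#'   through).
#' @param resolution pixels per mm of the images the features came from; the
#'   score is refused when it differs from the model's reference resolution
#'   (rescale the images first), because resolution-sensitive feature
#'   constants do not transfer.
#' @return Numeric score(s).
#' @export
risk_score <- function(model, features, resolution = model$reference_resolution) {
  stopifnot(inherits(model, "risk_score_model"))
  if (abs(resolution - model$reference_resolution) /
      model$reference_resolution > 1e-3)
    stop("features were computed at ", resolution, " px/mm but the model's ",
         "constants assume ", model$reference_resolution,
         " px/mm; rescale the images before extraction")
  tm <- model$terms
  if (is.numeric(features) && !is.matrix(features)) {
    missing <- setdiff(tm$feature, names(features))
    if (length(missing))
      stop("missing model feature(s): ", paste(missing, collapse = ", "))
    return(sum(tm$weight * (features[tm$feature] - tm$mean) / tm$sd))
  }
  df <- as.data.frame(features)
  missing <- setdiff(tm$feature, names(df))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  z <- sweep(sweep(as.matrix(df[, tm$feature, drop = FALSE]), 2, tm$mean),
             2, tm$sd, "/")
  as.numeric(z %*% tm$weight)
}

#' Relative contribution of one term's weight
#'
#' `100 * w_term / sum(w)`: the share of the score's standardized weight mass
#' carried by one feature (45% for the factor-64 sum average in the published
#' model).
#'
#' @param model a [risk_score_model()].
#' @param feature term name.
#' @return Percentage.
#' @export
weight_contribution <- function(model, feature) {
  stopifnot(inherits(model, "risk_score_model"))
  i <- match(feature, model$terms$feature)
  if (is.na(i)) stop("no such term in model: ", feature)
  100 * model$terms$weight[i] / sum(model$terms$weight)
}

#' Read / write risk score models as JSON
#'
#' Schema: `{"terms": [{"feature", "weight", "mean", "sd"}, ...],
#' "reference_resolution_px_per_mm": 10.628}`. Numbers are written at full
#' precision so models round-trip bit-exactly.
#'
#' @param model a [risk_score_model()].
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "risk_score_model"))
  jsonlite::write_json(
    list(terms = model$terms,
         reference_resolution_px_per_mm = model$reference_resolution),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_score_model(as.data.frame(j$terms),
                   reference_resolution = j$reference_resolution_px_per_mm)
}
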