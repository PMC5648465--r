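#' Generate a synthetic raw mammogram phantom
#'
#' Renders a semicircular "breast" against a bright air background with raw
#' FFDM polarity (attenuating tissue = low intensity): a fat background whose
#' intensity rises quadratically towards the breast edge (the thin,
#' uncompressed edge transmits more signal, so it windows to background), plus
#' dense tissue as low-intensity Gaussian blobs and additive Gaussian noise.
#' The `dispersion` parameter trades blob count against blob size at *fixed
#' total dense area*: high dispersion means many small scattered blobs, low
#' dispersion a few large compact ones. A pixel is "dense" (ground truth) when
#' its blob depth exceeds half the blob amplitude; blob widths are chosen so
#' the dense pixels cover `dense_fraction` of the breast. Blob centres are
#' rejection-sampled away from the breast boundary and from each other, so
#' dense area is conserved across dispersion values. Deterministic given the
#' seed. The phantom is deliberately minimal: it supports direction/contract
#' testing of the pipeline, not image realism.
#'
#' @param shape image dimensions (rows, cols).
#' @param breast_fraction target in-mask area fraction of the image.
#' @param dense_fraction target fraction of the breast covered by dense blobs.
#' @param dispersion blob count/size trade-off in (0, 1\].
#' @param noise_sd additive intensity noise (raw counts).
#' @param seed integer seed.
#' @param subject_id identifier stored in the image.
#' @return List with `image` (a [raw_mammogram()] at the reference
#'   resolution), `mask` (ground-truth breast mask) and `truth` (realized
#'   dense fraction, blob centres and half-max radius).
#' @export
generate_phantom <- function(shape = c(512L, 512L), breast_fraction = 0.35,
                             dense_fraction = 0.10, dispersion = 0.5,
                             noise_sd = 150, seed = 1L,
                             subject_id = sprintf("phantom_%d", seed)) {
  stopifnot(breast_fraction > 0, breast_fraction < 1,
            dense_fraction > 0, dense_fraction < 1,
            dispersion > 0, dispersion <= 1)
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2
  R <- sqrt(2 * breast_fraction * nr * nc / pi)
  if (R > min(nr / 2, nc))
    stop("breast_fraction too large for this image shape")
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist2 <- (rr - cy)^2 + (cc - 0.5)^2
  mask <- dist2 <= R^2
  mask_area <- sum(mask)
  n_blobs <- max(1L, round(50 * dispersion))
  area_per_blob <- dense_fraction * mask_area / n_blobs
  r_half <- sqrt(area_per_blob / pi)
  sigma <- r_half / sqrt(2 * log(2))
  # projection: an approximately isotropic dense region attenuates in
  # proportion to its thickness, which scales with its in-plane radius
  amp <- 100 * sigma
  margin <- 1.3 * r_half
  with_seed(derive_seed(seed, "phantom"), {
    centres <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(centres) < n_blobs) {
      attempts <- attempts + 1L
      if (attempts > 5000L)
        stop("infeasible dense_fraction/dispersion: cannot place ",
             n_blobs, " non-overlapping blobs in the breast")
      cand <- c(runif(1, cy - R, cy + R), runif(1, margin, R))
      rad <- sqrt((cand[1] - cy)^2 + cand[2]^2)
      if (rad > R - margin) next
      if (nrow(centres) > 0 &&
          min(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2)) <
            2.4 * r_half) next
      centres <- rbind(centres, cand)
    }
    depth <- matrix(0, nr, nc)
    half <- ceiling(4 * sigma)
    for (b in seq_len(n_blobs)) {
      r0 <- centres[b, 1]; c0 <- centres[b, 2]
      ri <- max(1L, floor(r0 - half)):min(nr, ceiling(r0 + half))
      ci <- max(1L, floor(c0 - half)):min(nc, ceiling(c0 + half))
      depth[ri, ci] <- depth[ri, ci] +
        amp * exp(-(outer((ri - r0)^2, (ci - c0)^2, `+`)) / (2 * sigma^2))
    }
    # compressed breast: near-uniform thickness in the interior, signal
    # rising sharply only in the thin uncompressed edge band
    base <- ifelse(mask, 9000 + 2500 * (dist2 / R^2)^4, 15500)
    px <- base - depth * mask + rnorm(nr * nc, 0, noise_sd)
    px <- round(pmin(pmax(px, 0), 16383))
  })
  # ground-truth dense pixels: within the half-max radius of some blob centre
  dmin2 <- matrix(Inf, nr, nc)
  for (b in seq_len(n_blobs))
    dmin2 <- pmin(dmin2, (rr - centres[b, 1])^2 + (cc - centres[b, 2])^2)
  dense <- mask & (dmin2 <= r_half^2)
  list(image = raw_mammogram(px, pixel_spacing = 1 / REFERENCE_PX_PER_MM,
                             subject_id = subject_id),
       mask = mask,
       truth = list(dense_fraction_realized = sum(dense) / mask_area,
                    dense_mask = dense, centres = centres,
                    r_half = r_half, n_blobs = n_blobs))
}

#' Generate a matched case-control cohort with known effects
#'
#' Emulates an approximately matched screening case-control design: each
#' matched set shares stratum-level matching variables (age, BMI, HRT use)
#' with small within-set jitter, contains `controls_per_case` controls and one
#' case, and carries predictor columns drawn as standard normals so that the
#' planted coefficients `beta` are standardized log odds ratios (per SD). The
#' case is sampled within each stratum with probability proportional to
#' `exp(x . beta)` — exactly the conditional-logistic likelihood — so
#' `clogit_fit` is consistent for `beta`. A stratum-level case subtype
#' (screen-detected with probability `subtype_mix`) supports interaction
#' analyses. Deterministic given the seed.
#'
#' @param n_strata number of matched sets.
#' @param controls_per_case controls per case (study design: approximately 3).
#' @param beta named vector of true standardized log odds ratios; names become
#'   predictor columns. Default 0.31 per SD (odds ratio 1.36, the scale of
#'   effect reported for mammographic density-type predictors).
#' @param subtype_mix probability a stratum's case is screen-detected.
#' @param seed integer seed.
#' @return A [matched_cohort()] with attribute `beta_true`.
#' @export
generate_cohort <- function(n_strata, controls_per_case = 3L,
                            beta = c(score = 0.31), subtype_mix = 0.5,
                            seed = 1L) {
  stopifnot(n_strata >= 1, controls_per_case >= 1, length(beta) >= 1,
            !is.null(names(beta)))
  reserved <- c("subject_id", "stratum", "case", "subtype", "age", "bmi",
                "pd", "hrt")
  if (any(names(beta) %in% reserved))
    stop("predictor names may not collide with cohort columns: ",
         paste(intersect(names(beta), reserved), collapse = ", "))
  m <- controls_per_case + 1L
  with_seed(derive_seed(seed, "cohort"), {
    age_s <- rnorm(n_strata, 60, 5)
    bmi_s <- rnorm(n_strata, 27, 4)
    hrt_s <- rbinom(n_strata, 1, 0.25)
    subtype_s <- ifelse(runif(n_strata) < subtype_mix,
                        "screen_detected", "interval")
    x <- matrix(rnorm(n_strata * m * length(beta)), ncol = length(beta),
                dimnames = list(NULL, names(beta)))
    eta <- as.numeric(x %*% beta)
    case <- integer(n_strata * m)
    for (s in seq_len(n_strata)) {
      idx <- ((s - 1L) * m + 1L):(s * m)
      w <- exp(eta[idx] - max(eta[idx]))
      case[idx[sample.int(m, 1L, prob = w)]] <- 1L
    }
    df <- data.frame(
      subject_id = sprintf("s%05d_%d", rep(seq_len(n_strata), each = m),
                           rep(seq_len(m), n_strata)),
      stratum = rep(seq_len(n_strata), each = m),
      case = case,
      subtype = rep(subtype_s, each = m),
      age = rep(age_s, each = m) + runif(n_strata * m, -1, 1),
      bmi = rep(bmi_s, each = m) + runif(n_strata * m, -0.5, 0.5),
      hrt = rep(hrt_s, each = m),
      pd = exp(rnorm(n_strata * m, log(7), 0.4)),
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(x))
  })
  out <- matched_cohort(df)
  attr(out, "beta_true") <- beta
  out
}

#' Generate a feature table with planted signal and correlation structure
#'
#' Standard-normal feature columns with optional equicorrelated blocks (for
#' screening tests) and `k_informative` columns carrying a standardized
#' log-odds `effect` on a binary outcome. Deterministic given the seed.
#'
#' @param n,p subjects and features.
#' @param k_informative number of informative columns (the first k).
#' @param effect standardized log odds ratio per informative column.
#' @param cor_blocks optional list of `list(cols =, r =)` specs; each block's
#'   columns are rebuilt with pairwise correlation `r`.
#' @param seed integer seed.
#' @return List with `x` (matrix, columns `f001`...), `y` (0/1),
#'   `informative` (column names).
#' @export
generate_feature_table <- function(n, p, k_informative = 0L, effect = 0,
                                   cor_blocks = NULL, seed = 1L) {
  stopifnot(k_informative <= p, n >= 2)
  with_seed(derive_seed(seed, "features"), {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
    for (b in cor_blocks) {
      z <- rnorm(n)
      for (j in b$cols)
        x[, j] <- sqrt(b$r) * z + sqrt(1 - b$r) * rnorm(n)
    }
    eta <- if (k_informative > 0)
      effect * rowSums(x[, seq_len(k_informative), drop = FALSE]) else rep(0, n)
    y <- rbinom(n, 1, plogis(eta))
  })
  list(x = x, y = y,
       informative = if (k_informative > 0)
         colnames(x)[seq_len(k_informative)] else character(0))
}
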