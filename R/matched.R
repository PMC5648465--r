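#' Matched case-control cohorts
#'
#' Validates a data frame as a matched cohort: one row per subject with at
#' least `subject_id`, `stratum` (matched-set identifier) and `case` (0/1)
#' columns; every stratum must contain exactly one case and at least one
#' control, and no subject may appear in two strata. An optional `subtype`
#' column (`"screen_detected"` / `"interval"`) describes the case of each
#' stratum.
#'
#' @param data data frame of subjects.
#' @return The data, classed `matched_cohort`.
#' @export
matched_cohort <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "stratum", "case") %in% names(data)))
  if (nrow(data) == 0L) stop("empty cohort")
  if (!all(data$case %in% c(0, 1))) stop("`case` must be 0/1")
  cases <- tapply(data$case, data$stratum, sum)
  if (any(cases != 1))
    stop("every stratum must contain exactly one case; offending strata: ",
         paste(head(names(cases)[cases != 1], 5), collapse = ", "))
  sizes <- table(data$stratum)
  if (any(sizes < 2)) stop("every stratum needs at least one control")
  if (anyDuplicated(data$subject_id))
    stop("a subject appears in more than one stratum")
  if ("subtype" %in% names(data) &&
      !all(data$subtype %in% c("screen_detected", "interval")))
    stop("subtype must be 'screen_detected' or 'interval'")
  class(data) <- c("matched_cohort", "data.frame")
  data
}

#' Conditional logistic regression on a matched cohort
#'
#' Maximises the conditional likelihood
#' `prod_s exp(x_case b) / sum_{j in s} exp(x_j b)` (one case per matched
#' set), which eliminates the per-stratum nuisance intercepts. Fitting is
#' delegated to `survival::clogit` (exact conditional likelihood). Predictors
#' that are constant within every stratum carry no information — their
#' coefficient is undefined — and are dropped with a message; strata
#' contribute `log(1/(m+1))` to the null log-likelihood regardless.
#'
#' @param cohort a [matched_cohort()].
#' @param predictors character vector of model terms (columns of the cohort;
#'   expressions such as `"log(pd)"` or interactions `"a:b"` are allowed).
#' @return An object of class `clogit_fit`: `beta`, `se`, `vcov`, `loglik`,
#'   `null_loglik`, `deviance_chi2`, `predictors`, `n_strata`, `cohort`.
#' @export
clogit_fit <- function(cohort, predictors) {
  cohort <- matched_cohort(as.data.frame(cohort))
  stopifnot(length(predictors) >= 1)
  plain <- predictors[predictors %in% names(cohort)]
  uninformative <- vapply(plain, function(v) {
    all(tapply(cohort[[v]], cohort$stratum,
               function(x) length(unique(x)) == 1L))
  }, logical(1))
  if (any(uninformative)) {
    message("dropping uninformative predictor(s) (constant within every ",
            "stratum): ", paste(plain[uninformative], collapse = ", "))
    predictors <- setdiff(predictors, plain[uninformative])
    if (length(predictors) == 0L)
      stop("no informative predictors remain")
  }
  # conditional logistic likelihood == stratified Cox exact partial
  # likelihood with unit times and the case as the event (clogit's trick)
  f <- as.formula(paste("survival::Surv(rep(1, nrow(cohort)), case) ~",
                        paste(predictors, collapse = " + "),
                        "+ survival::strata(stratum)"))
  fit <- survival::coxph(f, data = cohort, method = "exact")
  beta <- coef(fit)
  if (anyNA(beta))
    stop("inestimable coefficient(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  if (any(abs(beta) > 15))
    stop("within-stratum separation: coefficient diverges for ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "))
  structure(list(beta = beta, se = sqrt(diag(vcov(fit))), vcov = vcov(fit),
                 loglik = fit$loglik[2], null_loglik = fit$loglik[1],
                 deviance_chi2 = 2 * (fit$loglik[2] - fit$loglik[1]),
                 predictors = predictors,
                 n_strata = length(unique(cohort$stratum)),
                 cohort = cohort, fit = fit),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("<clogit_fit> %d strata, loglik %.3f (null %.3f), chi2 %.2f\n",
              x$n_strata, x$loglik, x$null_loglik, x$deviance_chi2))
  print(data.frame(beta = x$beta, se = x$se), digits = 4)
  invisible(x)
}

#' Standardized odds ratio per control-SD
#'
#' The change in odds for a one standard deviation (among controls) increase
#' of the predictor: `OR = exp(beta * sd_controls)`, with a Wald 95%
#' confidence interval on the same scale.
#'
#' @param fit a [clogit_fit()] that includes `predictor`.
#' @param predictor name of the fitted term.
#' @param level confidence level.
#' @return List with `or`, `ci` (length 2), `beta`, `se`, `sd_controls`.
#' @export
standardized_or <- function(fit, predictor, level = 0.95) {
  stopifnot(inherits(fit, "clogit_fit"))
  if (!predictor %in% names(fit$beta)) stop("predictor not in fit: ", predictor)
  vals <- eval(parse(text = predictor),
               fit$cohort[fit$cohort$case == 0, , drop = FALSE])
  sdc <- sd(vals)
  if (sdc == 0) stop("zero control variance for ", predictor)
  b <- fit$beta[[predictor]]
  se <- fit$se[[predictor]]
  zq <- qnorm(1 - (1 - level) / 2)
  list(or = exp(b * sdc),
       ci = exp((b + c(-1, 1) * zq * se) * sdc),
       beta = b, se = se, sd_controls = sdc)
}

#' Likelihood-ratio test between nested conditional logistic fits
#'
#' @param full,reduced [clogit_fit()]s on the same cohort/strata, with the
#'   reduced model's terms a subset of the full model's.
#' @return List with `delta_chi2`, `df`, `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "clogit_fit"), inherits(reduced, "clogit_fit"))
  if (!all(reduced$predictors %in% full$predictors))
    stop("models are not nested")
  if (full$n_strata != reduced$n_strata)
    stop("fits use different strata")
  d <- 2 * (full$loglik - reduced$loglik)
  df <- length(full$beta) - length(reduced$beta)
  p <- if (df > 0) pchisq(d, df, lower.tail = FALSE) else as.numeric(d <= 0)
  list(delta_chi2 = d, df = df, p = p)
}

#' Matched concordance index
#'
#' Within each matched set the case's score is compared with each of its m
#' controls: concordance is `(wins + 0.5 * ties) / m`, and the matched
#' concordance index mC averages this over matched sets (each set weighted
#' equally; `weights = "pairs"` instead weights by the number of case-control
#' comparisons, which matters only for variable m). 0.5 means no
#' discrimination; on 1:1 designs mC equals the ordinary pairwise concordance
#' between case and control scores.
#'
#' @param cohort a [matched_cohort()].
#' @param scores column name in the cohort, or a numeric vector aligned with
#'   its rows.
#' @param weights `"strata"` (default) or `"pairs"`.
#' @return mC in \[0, 1\].
#' @export
matched_concordance <- function(cohort, scores, weights = c("strata", "pairs")) {
  cohort <- matched_cohort(as.data.frame(cohort))
  weights <- match.arg(weights)
  s <- if (is.character(scores) && length(scores) == 1L) cohort[[scores]]
       else as.numeric(scores)
  if (length(s) != nrow(cohort) || anyNA(s))
    stop("every subject must have a finite score")
  won <- function(idx) {
    cs <- s[idx][cohort$case[idx] == 1]
    ct <- s[idx][cohort$case[idx] == 0]
    c(sum(cs > ct) + 0.5 * sum(cs == ct), length(ct))
  }
  per <- vapply(split(seq_len(nrow(cohort)), cohort$stratum), won, numeric(2))
  if (weights == "strata") mean(per[1, ] / per[2, ]) else sum(per[1, ]) / sum(per[2, ])
}

#' Stratified bootstrap confidence interval
#'
#' Resamples matched sets (not individual subjects) with replacement,
#' preserving the matched design, and returns the percentile interval of the
#' statistic over `B` resamples. Resamples on which the statistic is
#' undefined (`NA` or error) are redrawn and counted.
#'
#' @param cohort a [matched_cohort()].
#' @param statistic function taking a cohort and returning a scalar.
#' @param B number of bootstrap resamples (>= 200).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param level confidence level.
#' @return List with `ci`, `estimate`, `replicates`, `n_redrawn`.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 1000L, seed = 1L,
                         level = 0.95) {
  cohort <- matched_cohort(as.data.frame(cohort))
  if (B < 200L) stop("B must be at least 200")
  strata_ids <- unique(cohort$stratum)
  rows <- split(seq_len(nrow(cohort)), cohort$stratum)[as.character(strata_ids)]
  est <- statistic(cohort)
  reps <- numeric(B)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        pick <- sample(length(strata_ids), replace = TRUE)
        idx <- unlist(rows[pick], use.names = FALSE)
        boot <- cohort[idx, , drop = FALSE]
        boot$stratum <- rep(seq_along(pick), vapply(rows[pick], length, 1L))
        boot$subject_id <- seq_len(nrow(boot))
        val <- tryCatch(statistic(matched_cohort(boot)),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * B) stop("bootstrap statistic undefined on ",
                                       "nearly every resample")
      }
      reps[b] <- val
    }
  })
  if (n_redrawn > 0)
    message("bootstrap_ci: redrew ", n_redrawn, " degenerate resample(s)")
  alpha <- (1 - level) / 2
  list(ci = unname(quantile(reps, c(alpha, 1 - alpha), type = 7)),
       estimate = est, replicates = reps, n_redrawn = n_redrawn)
}

#' Screen-detected versus interval cancer interaction analysis
#'
#' Tests whether a predictor's effect differs between strata whose case was
#' screen-detected and strata whose case was an interval cancer (biologically
#' distinct phenotypes; masking by dense or dispersed tissue mainly affects
#' interval cancers). The subtype is a stratum-level case attribute applied to
#' the whole matched set; the model adds a predictor-by-subtype interaction
#' term, and subtype-specific standardized odds ratios are reported with the
#' likelihood-ratio test of the interaction.
#'
#' @param cohort a [matched_cohort()] with a `subtype` column.
#' @param predictor predictor column name.
#' @param adjust additional adjustment terms (default age and BMI).
#' @return List with `or_screen`, `or_interval` (each with Wald CI),
#'   `delta_chi2`, `df`, `p` and the underlying fits.
#' @export
interaction_test <- function(cohort, predictor, adjust = c("age", "bmi")) {
  cohort <- matched_cohort(as.data.frame(cohort))
  if (!"subtype" %in% names(cohort)) stop("cohort has no `subtype` column")
  case_sub <- tapply(cohort$subtype[cohort$case == 1],
                     cohort$stratum[cohort$case == 1], identity)
  if (length(unique(unlist(case_sub))) < 2L)
    stop("both case subtypes must be present for an interaction analysis")
  cohort$.interval <- as.numeric(cohort$subtype == "interval")
  adjust <- adjust[adjust %in% names(cohort)]
  full <- clogit_fit(cohort, c(predictor,
                               paste0(predictor, ":.interval"), adjust))
  reduced <- clogit_fit(cohort, c(predictor, adjust))
  sdc <- sd(cohort[[predictor]][cohort$case == 0])
  b_main <- full$beta[[predictor]]
  int_name <- grep(":", names(full$beta), value = TRUE)[1]
  b_int <- full$beta[[int_name]]
  v <- full$vcov
  se_main <- full$se[[predictor]]
  se_sum <- sqrt(v[predictor, predictor] + v[int_name, int_name] +
                   2 * v[predictor, int_name])
  zq <- qnorm(0.975)
  lrt <- lr_test(full, reduced)
  list(or_screen = exp(b_main * sdc),
       ci_screen = exp((b_main + c(-1, 1) * zq * se_main) * sdc),
       or_interval = exp((b_main + b_int) * sdc),
       ci_interval = exp((b_main + b_int + c(-1, 1) * zq * se_sum) * sdc),
       delta_chi2 = lrt$delta_chi2, df = lrt$df, p = lrt$p,
       full = full, reduced = reduced, sd_controls = sdc)
}
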