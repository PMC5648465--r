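make_cohort <- function(df) matched_cohort(df)

test_that("cohort validation enforces the matched design", {
  co <- generate_cohort(10, 3, beta = c(score = 0.3), seed = 1)
  expect_s3_class(co, "matched_cohort")
  expect_true(all(table(co$stratum) == 4))

  bad <- as.data.frame(co)
  bad$case[1:2] <- 1 # two cases in stratum 1
  expect_error(matched_cohort(bad), "exactly one case")
  dup <- as.data.frame(co)
  dup$subject_id[5] <- dup$subject_id[1]
  expect_error(matched_cohort(dup), "more than one stratum")
  expect_error(matched_cohort(as.data.frame(co)[co$case == 1, ]),
               "at least one control")
})

test_that("conditional logistic fits match the paired-difference oracle", {
  co <- generate_cohort(300, 1, beta = c(score = 0.5), seed = 7)
  f <- clogit_fit(co, "score")
  expect_equal(unname(f$beta), oracle_paired_clogit(co, "score"),
               tolerance = 1e-6)
  expect_gte(f$loglik, f$null_loglik)
  expect_gte(f$deviance_chi2, 0)
  # null log-likelihood of m+1-subject strata is -sum log(m+1)
  expect_equal(f$null_loglik, -300 * log(2), tolerance = 1e-10)
})

test_that("uninformative predictors are dropped and flagged", {
  co <- generate_cohort(50, 3, beta = c(score = 0.4), seed = 9)
  co$flat <- rep(5, nrow(co)) # constant everywhere
  expect_message(f <- clogit_fit(co, c("score", "flat")), "uninformative")
  expect_false("flat" %in% names(f$beta))
  expect_error(suppressMessages(clogit_fit(co, "flat")),
               "no informative predictors")
})

test_that("the conditional likelihood ignores stratum-constant shifts", {
  co <- generate_cohort(200, 3, beta = c(score = 0.4), seed = 13)
  f1 <- clogit_fit(co, "score")
  co2 <- co
  co2$score <- co2$score + 7 * co2$stratum # arbitrary stratum-level shift
  f2 <- clogit_fit(co2, "score")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("standardized ORs are exp(beta * control SD) with a Wald CI", {
  co <- generate_cohort(400, 3, beta = c(score = 0.31), seed = 5)
  f <- clogit_fit(co, c("score", "age", "bmi"))
  so <- standardized_or(f, "score")
  sdc <- sd(co$score[co$case == 0])
  expect_equal(so$or, exp(f$beta[["score"]] * sdc))
  expect_equal(so$ci[1], exp((f$beta[["score"]] - qnorm(0.975) *
                                f$se[["score"]]) * sdc))
  expect_true(so$ci[1] <= so$or && so$or <= so$ci[2])

  set.seed(99)
  co$zv <- ifelse(co$case == 1, rnorm(nrow(co), 3, 1), 3) # constant in controls
  fz <- clogit_fit(co, "zv")
  expect_error(standardized_or(fz, "zv"), "zero control variance")
})

test_that("likelihood-ratio tests compare nested fits", {
  co <- generate_cohort(200, 3, beta = c(score = 0.4, other = 0.2), seed = 2)
  full <- clogit_fit(co, c("score", "other"))
  red <- clogit_fit(co, "score")
  lr <- lr_test(full, red)
  expect_equal(lr$delta_chi2, 2 * (full$loglik - red$loglik))
  expect_equal(lr$df, 1)
  same <- lr_test(full, full)
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p, 1)
  other_only <- clogit_fit(co, "other")
  expect_error(lr_test(red, other_only), "not nested")
})

test_that("the matched concordance index honours its contracts", {
  co <- generate_cohort(50, 3, beta = c(score = 0.3), seed = 4)
  perfect <- ifelse(co$case == 1, 10, 1)
  expect_equal(matched_concordance(co, perfect), 1)
  expect_equal(matched_concordance(co, rep(2, nrow(co))), 0.5)

  # 1:1 design: equals ordinary pairwise case-vs-control concordance
  co1 <- generate_cohort(150, 1, beta = c(score = 0.5), seed = 6)
  manual <- mean(vapply(split(seq_len(nrow(co1)), co1$stratum), function(i) {
    cs <- co1$score[i][co1$case[i] == 1]
    ct <- co1$score[i][co1$case[i] == 0]
    (cs > ct) + 0.5 * (cs == ct)
  }, numeric(1)))
  expect_equal(matched_concordance(co1, "score"), manual)
  expect_error(matched_concordance(co, co$score[-1]), "score")
})

test_that("bootstrap CIs resample strata and respect degenerate cases", {
  co <- generate_cohort(60, 3, beta = c(score = 0.3), seed = 8)
  b_const <- bootstrap_ci(co, function(c) 0.42, B = 200, seed = 1)
  expect_equal(unname(b_const$ci), c(0.42, 0.42))

  perfect <- co
  perfect$score <- ifelse(perfect$case == 1, 10, 1)
  b_perf <- bootstrap_ci(perfect, function(c) matched_concordance(c, "score"),
                         B = 200, seed = 2)
  expect_equal(unname(b_perf$ci), c(1, 1))

  b1 <- bootstrap_ci(co, function(c) matched_concordance(c, "score"),
                     B = 200, seed = 3)
  b2 <- bootstrap_ci(co, function(c) matched_concordance(c, "score"),
                     B = 200, seed = 3)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(b1$ci[1] <= b1$estimate && b1$estimate <= b1$ci[2])
  expect_error(bootstrap_ci(co, function(c) 1, B = 50, seed = 1), "200")
})

test_that("interaction fits agree with subtype-restricted fits", {
  co <- generate_cohort(300, 3, beta = c(score = 0.5), seed = 10,
                        subtype_mix = 0.5)
  it <- interaction_test(co, "score", adjust = character(0))
  scr <- clogit_fit(co[co$subtype == "screen_detected", ], "score")
  itv <- clogit_fit(co[co$subtype == "interval", ], "score")
  expect_equal(unname(it$full$beta[["score"]]), unname(scr$beta[["score"]]),
               tolerance = 1e-6)
  int_name <- grep(":", names(it$full$beta), value = TRUE)
  expect_equal(it$full$beta[["score"]] + it$full$beta[[int_name]],
               unname(itv$beta[["score"]]), tolerance = 1e-6)
  expect_equal(it$df, 1)
  expect_true(it$p >= 0 && it$p <= 1)

  one <- co
  one$subtype <- "interval"
  expect_error(interaction_test(one, "score"), "both case subtypes")
})
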