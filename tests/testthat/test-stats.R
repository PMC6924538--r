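# Group-level statistics: effect sizes, test dispatch, post hocs, regression.

test_that("Hedges g is affine-invariant and consistent across interfaces", {
  expect_equal(hedges_g(3, 1, 10, 3, 1, 12), 0)
  g0 <- hedges_g(0.54, 0.41, 17, 0.20, 0.47, 20)
  expect_equal(hedges_g(0.54 + 5, 0.41, 17, 0.20 + 5, 0.47, 20), g0)
  k <- 3.7
  expect_equal(hedges_g(k * 0.54, k * 0.41, 17, k * 0.20, k * 0.47, 20), g0)
  expect_error(hedges_g(1, 0, 10, 2, 0, 10), "degenerate")
  expect_error(hedges_g(1, 1, 1, 2, 1, 10), "n >= 2")

  set.seed(301)
  x <- rnorm(15, 1); y <- rnorm(18)
  expect_equal(hedges_g_samples(x, y),
               hedges_g(mean(x), sd(x), 15, mean(y), sd(y), 18),
               tolerance = 1e-12)
})

test_that("two-group dispatch selects the branch Shapiro-Wilk indicates", {
  set.seed(302)
  x <- rnorm(20); y <- rnorm(20)
  stopifnot(shapiro.test(x)$p.value > 0.05, shapiro.test(y)$p.value > 0.05)
  cmp <- dispatch_two_group(x, y)
  expect_identical(cmp$test, "student_t")
  expect_true(is.finite(cmp$effect_size))

  # heavy-tailed samples at n = 200 fail normality almost surely
  nonpar <- replicate(100, {
    a <- rcauchy(200); b <- rnorm(200)
    dispatch_two_group(a, b)$test == "mann_whitney"
  })
  expect_gt(mean(nonpar), 0.95)

  # identical samples sit at the null centre of the rank test
  z <- c(rexp(10), 5:14)  # non-normal so the rank branch runs
  cmp <- dispatch_two_group(z, z)
  expect_identical(cmp$test, "mann_whitney")
  expect_equal(unname(cmp$statistic), length(z)^2 / 2)  # U at its null mean
  expect_gt(cmp$p, 0.9)

  expect_error(dispatch_two_group(1:2, 1:5), "n >= 3")
})

test_that("three-group omnibus is label-permutation invariant and finds a shifted group", {
  set.seed(303)
  s <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 1, 0.4))
  o1 <- omnibus_three_group(s)
  o2 <- omnibus_three_group(s[c(3, 1, 2)])
  expect_equal(unname(o1$statistic), unname(o2$statistic), tolerance = 1e-10)

  # with means 0, 0, 1 (sd 0.4) the omnibus and exactly the two contrasts
  # involving the shifted group should flag in most replicates
  hits <- replicate(60, {
    s <- list(a = rnorm(20, 0, 0.4), b = rnorm(20, 0, 0.4), c = rnorm(20, 1, 0.4))
    o <- omnibus_three_group(s)
    ph <- o$posthoc
    sig <- ph$p < 0.05
    involves_c <- ph$group1 == "c" | ph$group2 == "c"
    o$p < 0.05 && all(sig == involves_c)
  })
  expect_gt(mean(hits), 0.9)

  # non-normal groups go to Kruskal-Wallis with a Nemenyi table
  s <- list(a = rexp(25), b = rexp(25), c = rexp(25) + 2)
  o <- omnibus_three_group(s)
  expect_identical(o$test, "kruskal_wallis")
  expect_identical(attr(o$posthoc, "method"), "nemenyi")
  expect_identical(nrow(o$posthoc), 3L)
  expect_true(all(o$posthoc$p >= 0 & o$posthoc$p <= 1))

  expect_error(omnibus_three_group(list(rnorm(5), rnorm(5))), "3 groups")
})

test_that("Levene's test detects unequal spread and is zero for identical groups", {
  set.seed(304)
  x <- rnorm(20)
  o <- levene_variances(list(a = x, b = x))
  expect_equal(unname(o$statistic), 0, tolerance = 1e-10)

  rej <- replicate(300, {
    s <- list(a = rnorm(20, 0, 3), b = rnorm(20, 0, 1), c = rnorm(20, 0, 1))
    levene_variances(s)$p < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("severity regression reports r-squared, df and collinearity", {
  sev <- seq(1, 9, length.out = 17)
  imp <- 0.1 + 0.05 * sev
  fit <- suppressWarnings(severity_regression(imp, sev))  # perfect-fit warning
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$df, 15L)  # n - 2

  set.seed(305)
  imp <- rnorm(17); sev <- rnorm(17)
  fit <- severity_regression(imp, sev)
  expect_equal(fit$r_squared, cor(imp, sev)^2, tolerance = 1e-10)

  covs <- data.frame(c1 = rnorm(17), c2 = rnorm(17))
  fit <- severity_regression(imp, sev, covs)
  expect_identical(fit$df, 13L)
  expect_identical(fit$covariates, c("c1", "c2"))

  covs$c3 <- covs$c1 * 2  # exactly collinear
  expect_error(severity_regression(imp, sev, covs), "c3")

  # null case: mean r-squared is about 1/(n-1)
  r2 <- replicate(400, severity_regression(rnorm(17), rnorm(17))$r_squared)
  expect_lt(abs(mean(r2) - 1 / 16), 0.015)
})

test_that("the full analysis battery covers every configured contrast", {
  set.seed(306)
  fx <- make_fixtures(13)
  # build a larger synthetic cohort so every test has n >= 3 per group
  plan <- fx$plan
  specs <- list(lbd_vh = group_spec("lbd_vh", 8, 1.41, 0.23, 1.95, 0.16, sd_d = 0.3),
                lbd_nonvh = group_spec("lbd_nonvh", 8, 1.96, 0.14, 2.15, 0.13),
                control = group_spec("control", 8, 1.92, 0.16, 2.32, 0.12))
  cohort <- simulate_cohort(specs, plan, seed = 31)
  cohort <- attach_severity(cohort, target_r2 = 0.62, seed = 32)
  scores <- score_cohort(cohort$logs)
  report <- run_full_analysis(scores, cohort$metadata)

  expected <- c("omnibus_d_diff", "omnibus_pct_diff",
                paste0("planned_", c("d_diff", "fa_diff", "hit_diff", "c_diff",
                                     "d_before", "d_after", "f_before", "f_after")),
                "levene_d_before", "levene_d_after")
  expect_setequal(names(report$comparisons), expected)
  expect_s3_class(report$severity, "severity_fit")
  expect_true(all(vapply(report$comparisons, function(x) is.finite(x$p), TRUE)))

  # exclusion re-analysis drops the named participants
  excl <- run_full_analysis(scores, cohort$metadata,
                            exclude_ids = cohort$metadata$participant_id[1:2])
  expect_identical(excl$n, report$n - 2L)

  bad_meta <- cohort$metadata
  bad_meta$group[1] <- "mystery"
  expect_error(run_full_analysis(scores, bad_meta), "unknown group")

  # JSON serialization round-trips the comparison set
  js <- jsonlite::fromJSON(report_to_json(report))
  expect_setequal(names(js$comparisons), expected)
})
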