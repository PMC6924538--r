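# Group-level analysis: normality-dispatched tests, post hocs, Levene,
# Hedges g, and the hallucination-severity regression.

#' Hedges g from summary statistics
#'
#' Pooled-SD standardized mean difference with the small-sample correction
#' J = 1 - 3 / (4 (n1 + n2) - 9).
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @return Hedges g (positive when `m1 > m2`).
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
    stop("degenerate standard deviations", call. = FALSE)
  s_pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * (m1 - m2) / s_pooled
}

#' Hedges g from two samples
#'
#' @param x,y numeric samples.
#' @return Hedges g of `mean(x) - mean(y)`.
#' @export
hedges_g_samples <- function(x, y) {
  hedges_g(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

group_comparison <- function(measure, groups, test, statistic, p,
                             effect_size = NA_real_, posthoc = NULL,
                             normality_p = NULL) {
  structure(list(measure = measure, groups = groups, test = test,
                 statistic = unname(statistic), p = unname(p),
                 effect_size = unname(effect_size), posthoc = posthoc,
                 normality_p = normality_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g", x$measure, x$test,
              x$statistic, x$p))
  if (is.finite(x$effect_size)) cat(sprintf(", Hedges g = %.3f", x$effect_size))
  cat("\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc (", attr(x$posthoc, "method"), "):\n", sep = "")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Normality-dispatched two-group comparison
#'
#' Runs a Shapiro-Wilk test on each sample; when both pass at
#' `alpha_normality` the comparison uses an independent-samples t test
#' (equal-variance Student by default) with Hedges g, otherwise a
#' Mann-Whitney U test (exact when both groups have n <= 8, normal
#' approximation with continuity correction otherwise).
#'
#' @param x,y numeric samples, each with n >= 3.
#' @param measure label for the compared quantity.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @param var_equal use the pooled-variance Student t (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return A `"group_comparison"` recording the chosen branch.
#' @export
dispatch_two_group <- function(x, y, measure = "measure",
                               alpha_normality = 0.05, var_equal = TRUE) {
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs n >= 3", call. = FALSE)
  sw <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  if (all(sw > alpha_normality)) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    group_comparison(measure, c("x", "y"),
                     if (var_equal) "student_t" else "welch_t",
                     tt$statistic, tt$p.value,
                     effect_size = hedges_g_samples(x, y), normality_p = sw)
  } else {
    exact <- length(x) <= 8 && length(y) <= 8
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    group_comparison(measure, c("x", "y"), "mann_whitney",
                     wt$statistic, wt$p.value, normality_p = sw)
  }
}

# Nemenyi post hoc for Kruskal-Wallis: pairwise comparison of mean ranks via
# the studentized range distribution (no tie correction; intended for
# continuous scores).
nemenyi_posthoc <- function(values, groups) {
  k <- nlevels(groups)
  N <- length(values)
  rk <- rank(values)
  mean_ranks <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  combs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combs))) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt(N * (N + 1) / 12 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(mean_ranks[[g1]] - mean_ranks[[g2]]) / se * sqrt(2)
    out$statistic[i] <- q
    out$p[i] <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
  }
  attr(out, "method") <- "nemenyi"
  out
}

tukey_posthoc <- function(values, groups) {
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(group1 = vapply(pairs, `[`, "", 1),
                    group2 = vapply(pairs, `[`, "", 2),
                    statistic = tk[, "diff"], p = tk[, "p adj"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- "tukey"
  out
}

#' Normality-dispatched three-group omnibus test
#'
#' One-way ANOVA with Tukey HSD post hoc when every group passes Shapiro-Wilk
#' at `alpha_normality`; Kruskal-Wallis with a Nemenyi post hoc otherwise.
#'
#' @param samples named list of (at least) 3 numeric samples.
#' @param measure label for the compared quantity.
#' @param alpha_normality Shapiro-Wilk significance level.
#' @return A `"group_comparison"` with a `posthoc` pairwise table.
#' @export
omnibus_three_group <- function(samples, measure = "measure",
                                alpha_normality = 0.05) {
  if (length(samples) < 3) stop("need at least 3 groups", call. = FALSE)
  if (any(vapply(samples, length, 1L) < 3))
    stop("each group needs n >= 3", call. = FALSE)
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), vapply(samples, length, 1L)),
                   levels = names(samples))
  sw <- vapply(samples, function(s) stats::shapiro.test(s)$p.value, 1.0)
  if (all(sw > alpha_normality)) {
    fit <- stats::aov(values ~ groups)
    ss <- summary(fit)[[1]]
    group_comparison(measure, names(samples), "anova",
                     ss$`F value`[1], ss$`Pr(>F)`[1],
                     posthoc = tukey_posthoc(values, groups), normality_p = sw)
  } else {
    kw <- stats::kruskal.test(values, groups)
    group_comparison(measure, names(samples), "kruskal_wallis",
                     kw$statistic, kw$p.value,
                     posthoc = nemenyi_posthoc(values, groups), normality_p = sw)
  }
}

#' Levene's test of variance homogeneity
#'
#' Wraps [car::leveneTest()]; the default centres deviations on the group
#' means (the classical W statistic), with the Brown-Forsythe median variant
#' available.
#'
#' @param samples named list of numeric samples (>= 2 groups, each n >= 3).
#' @param measure label for the compared quantity.
#' @param center `"mean"` (default) or `"median"`.
#' @return A `"group_comparison"` with the W statistic and p value.
#' @export
levene_variances <- function(samples, measure = "measure",
                             center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(samples) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(samples, length, 1L) < 3))
    stop("each group needs n >= 3", call. = FALSE)
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), vapply(samples, length, 1L)),
                   levels = names(samples))
  lt <- car::leveneTest(values, groups, center = if (center == "mean") mean else stats::median)
  group_comparison(measure, names(samples), "levene",
                   lt$`F value`[1], lt$`Pr(>F)`[1])
}

#' Regression of performance improvement on hallucination severity
#'
#' Ordinary least squares of the Before-to-After improvement on severity plus
#' optional covariate columns. Reports the model R-squared, the severity
#' coefficient's t and p, and the residual degrees of freedom
#' df = n - (coefficients including intercept).
#'
#' @param improvement numeric response (e.g. per-participant d-prime change).
#' @param severity numeric severity score, same length.
#' @param covariates optional data frame of numeric covariate columns.
#' @return Object of class `"severity_fit"` with `r_squared`, `coefficients`,
#'   `df`, `t_severity`, `p_severity`, `covariates` and the underlying `lm`.
#' @export
severity_regression <- function(improvement, severity, covariates = NULL) {
  if (length(improvement) != length(severity))
    stop("improvement and severity lengths differ", call. = FALSE)
  dat <- data.frame(improvement = improvement, severity = severity)
  covs <- character(0)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    if (nrow(covariates) != length(improvement))
      stop("covariate rows must match observations", call. = FALSE)
    covs <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  fml <- stats::reformulate(c("severity", covs), response = "improvement")
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(r_squared = sm$r.squared,
                 coefficients = stats::coef(fit),
                 df = unname(fit$df.residual),
                 t_severity = sm$coefficients["severity", "t value"],
                 p_severity = sm$coefficients["severity", "Pr(>|t|)"],
                 covariates = covs, lm = fit),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("Severity regression: r^2 = %.3f, df = %d, t(severity) = %.3f, p = %.4g\n",
              x$r_squared, x$df, x$t_severity, x$p_severity))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Full group-level analysis battery
#'
#' Joins participant scores with metadata and reproduces the study's analysis
#' battery: three-group omnibus tests on d-prime and percentage-correct
#' improvement, planned two-group contrasts between patients with and without
#' hallucinations (improvement, false-alarm and hit-rate changes, Before and
#' After block values), Levene's test of Before/After d-prime variance across
#' the three groups (ceiling-effect check), and the severity regression
#' within the hallucinating group.
#'
#' @param scores participant-scores data frame from [score_cohort()].
#' @param metadata data frame with `participant_id`, `group` (one of
#'   `control`, `lbd_nonvh`, `lbd_vh`), optional `severity` and covariate
#'   columns.
#' @param alpha significance threshold recorded in the report (default 0.05).
#' @param alpha_normality Shapiro-Wilk level for test dispatch.
#' @param severity_covariates character vector of metadata columns to adjust
#'   the severity regression for (default none).
#' @param exclude_ids optional participant ids to drop for a sensitivity
#'   re-analysis (e.g. a diagnostic subgroup).
#' @return Object of class `"cohort_report"`: named list of
#'   `"group_comparison"` objects, the severity fit (when severity is
#'   available), group summary statistics and the configuration used.
#' @export
run_full_analysis <- function(scores, metadata, alpha = 0.05,
                              alpha_normality = 0.05,
                              severity_covariates = character(0),
                              exclude_ids = NULL) {
  known <- c("control", "lbd_nonvh", "lbd_vh")
  if (!all(metadata$group %in% known))
    stop(sprintf("unknown group labels: %s",
                 paste(setdiff(unique(metadata$group), known), collapse = ", ")),
         call. = FALSE)
  dat <- merge(scores, metadata, by = "participant_id")
  if (!is.null(exclude_ids)) dat <- dat[!dat$participant_id %in% exclude_ids, ]
  g <- function(grp, col) dat[dat$group == grp, col]
  three <- function(col) stats::setNames(lapply(known, g, col = col), known)

  comparisons <- list(
    omnibus_d_diff = omnibus_three_group(three("d_diff"), "d-prime improvement",
                                         alpha_normality),
    omnibus_pct_diff = omnibus_three_group(three("pct_diff"),
                                           "% correct improvement",
                                           alpha_normality))

  vh <- function(col) g("lbd_vh", col)
  nonvh <- function(col) g("lbd_nonvh", col)
  planned_cols <- c(d_diff = "d-prime improvement (VH vs non-VH)",
                    fa_diff = "false-alarm change (VH vs non-VH)",
                    hit_diff = "hit-rate change (VH vs non-VH)",
                    c_diff = "criterion change (VH vs non-VH)",
                    d_before = "Before d-prime (VH vs non-VH)",
                    d_after = "After d-prime (VH vs non-VH)",
                    f_before = "Before false alarms (VH vs non-VH)",
                    f_after = "After false alarms (VH vs non-VH)")
  for (col in names(planned_cols)) {
    comparisons[[paste0("planned_", col)]] <-
      dispatch_two_group(vh(col), nonvh(col), planned_cols[[col]],
                         alpha_normality)
  }
  comparisons$levene_d_before <- levene_variances(three("d_before"),
                                                  "Before d-prime variance")
  comparisons$levene_d_after <- levene_variances(three("d_after"),
                                                 "After d-prime variance")

  severity_fit <- NULL
  if ("severity" %in% names(metadata)) {
    vh_rows <- dat[dat$group == "lbd_vh" & !is.na(dat$severity), ]
    if (nrow(vh_rows) >= 3) {
      covs <- NULL
      if (length(severity_covariates))
        covs <- vh_rows[, severity_covariates, drop = FALSE]
      severity_fit <- severity_regression(vh_rows$d_diff, vh_rows$severity, covs)
    }
  }

  summaries <- do.call(rbind, lapply(known, function(grp) {
    rows <- dat[dat$group == grp, ]
    data.frame(group = grp, n = nrow(rows),
               d_before = mean(rows$d_before), d_after = mean(rows$d_after),
               d_diff = mean(rows$d_diff), d_diff_sd = stats::sd(rows$d_diff),
               fa_before = mean(rows$f_before), fa_after = mean(rows$f_after),
               fa_diff = mean(rows$fa_diff),
               pct_diff = mean(rows$pct_diff),
               stringsAsFactors = FALSE)
  }))

  structure(list(comparisons = comparisons, severity = severity_fit,
                 summaries = summaries, n = nrow(dat),
                 config = list(alpha = alpha, alpha_normality = alpha_normality,
                               severity_covariates = severity_covariates,
                               excluded = exclude_ids)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort analysis report (n = %d, alpha = %.2f)\n\nGroup summaries:\n",
              x$n, x$config$alpha))
  print(x$summaries, row.names = FALSE, digits = 3)
  cat("\nComparisons:\n")
  for (cmp in x$comparisons) print(cmp)
  if (!is.null(x$severity)) {
    cat("\n")
    print(x$severity)
  }
  invisible(x)
}

#' Serialize a cohort report to JSON
#'
#' @param report a `"cohort_report"`.
#' @param path optional output path; when omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  strip <- function(cmp) {
    out <- unclass(cmp)
    if (!is.null(out$posthoc)) {
      out$posthoc_method <- attr(out$posthoc, "method")
      out$posthoc <- as.data.frame(out$posthoc)
    }
    out
  }
  payload <- list(
    n = report$n,
    config = report$config,
    summaries = report$summaries,
    comparisons = lapply(report$comparisons, strip),
    severity = if (!is.null(report$severity)) {
      s <- unclass(report$severity)
      s$lm <- NULL
      s$coefficients <- as.list(s$coefficients)
      s
    })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
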