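# Synthetic SDT observers: Bernoulli yes/no responders whose hit and
# false-alarm probabilities are set (directly or via d-prime / criterion)
# per phase, used to exercise and calibrate the full pipeline without
# patient data. Responses are independent across trials: no learning within
# a phase and no session drift, the minimal model consistent with per-phase
# pooled scoring.

#' Invert d-prime and false-alarm rate to response probabilities
#'
#' Given a target sensitivity and false-alarm rate, returns the (h, f) pair
#' with f fixed and h = Phi(d' + z(f)), the inversion of d' = z(h) - z(f).
#'
#' @param dprime target discrimination sensitivity.
#' @param fa false-alarm rate in (0, 1).
#' @return Named numeric vector `c(h = , f = )`.
#' @export
probs_from_sdt <- function(dprime, fa) {
  if (any(fa <= 0) || any(fa >= 1)) stop("fa must lie in (0, 1)", call. = FALSE)
  h <- stats::pnorm(dprime + stats::qnorm(fa))
  if (any(h <= 0) || any(h >= 1))
    stop("implied hit rate falls outside (0, 1)", call. = FALSE)
  c(h = unname(h), f = unname(fa))
}

# (h, f) from d-prime and criterion: z(h) = d/2 - c, z(f) = -d/2 - c.
probs_from_dc <- function(dprime, crit) {
  c(h = unname(stats::pnorm(dprime / 2 - crit)),
    f = unname(stats::pnorm(-dprime / 2 - crit)))
}

#' Generative parameters of one synthetic observer
#'
#' @param h_before,f_before,h_after,f_after per-phase yes-response
#'   probabilities on test (h) and control (f) trials, strictly in (0, 1).
#' @param template_accuracy probability of a correct response on
#'   template-block trials (near ceiling; irrelevant to the analysis but
#'   exercises the log schema).
#' @param severity optional nonnegative hallucination-severity score.
#' @return Object of class `"observer_params"`.
#' @export
observer_params <- function(h_before, f_before, h_after, f_after,
                            template_accuracy = 0.98, severity = NA_real_) {
  p <- c(h_before, f_before, h_after, f_after)
  if (any(p <= 0) || any(p >= 1))
    stop("all response probabilities must lie strictly in (0, 1)", call. = FALSE)
  structure(list(h_before = h_before, f_before = f_before,
                 h_after = h_after, f_after = f_after,
                 template_accuracy = template_accuracy, severity = severity),
            class = "observer_params")
}

phase_rows <- function(pid, session, phase, ids, is_test, p_yes, presented_ms) {
  data.frame(participant_id = pid, session = session, phase = phase,
             stimulus_id = ids, is_test = is_test,
             presented_ms = presented_ms,
             response = stats::rbinom(length(ids), 1L, p_yes) == 1L,
             rt_ms = stats::rgamma(length(ids), shape = 4, scale = 250),
             stringsAsFactors = FALSE)
}

#' Simulate one observer's trial log
#'
#' Draws every Before/After two-tone response as an independent Bernoulli
#' with the phase- and class-appropriate probability from `params`;
#' template-block responses are correct with `template_accuracy`; practice
#' trials use the Before-phase probabilities. Reaction times are generated
#' (gamma-distributed) only to fill the schema and are never analysed.
#'
#' @param params an [observer_params()] object.
#' @param plan an [build_experiment()] plan.
#' @param participant_id id recorded in the log.
#' @param seed optional integer; when given the log is reproducible.
#' @return Trial-log data frame with the standard columns
#'   (`participant_id`, `session`, `phase`, `stimulus_id`, `is_test`,
#'   `presented_ms`, `response`, `rt_ms`).
#' @export
simulate_observer <- function(params, plan, participant_id = "obs1",
                              seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  two_tone_p <- function(ids, h, f) {
    is_test <- unname(plan$is_test[ids])
    list(is_test = is_test, p = ifelse(is_test, h, f))
  }
  blocks <- list()
  # practice session (session 0), scored with Before-phase parameters
  pr <- plan$practice
  tp <- two_tone_p(pr$before_ids, params$h_before, params$f_before)
  blocks[[1]] <- phase_rows(participant_id, 0L, "practice", pr$before_ids,
                            tp$is_test, tp$p, plan$presented_ms)
  tp <- two_tone_p(pr$after_ids, params$h_after, params$f_after)
  blocks[[2]] <- phase_rows(participant_id, 0L, "practice", pr$after_ids,
                            tp$is_test, tp$p, plan$presented_ms)
  k <- 3L
  for (s in seq_len(plan$n_sessions)) {
    sp <- plan$sessions[[s]]
    tp <- two_tone_p(sp$before_ids, params$h_before, params$f_before)
    blocks[[k]] <- phase_rows(participant_id, s, "before", sp$before_ids,
                              tp$is_test, tp$p, plan$presented_ms)
    # template trials: colour images; truth = whether the template contains
    # a person (fillers without a mapping are treated as person-free)
    tmpl_truth <- unname(plan$template_is_test[sp$template_ids])
    tmpl_truth[is.na(tmpl_truth)] <- FALSE
    p_corr <- params$template_accuracy
    resp_p <- ifelse(tmpl_truth, p_corr, 1 - p_corr)
    blocks[[k + 1L]] <- phase_rows(participant_id, s, "template",
                                   sp$template_ids, tmpl_truth, resp_p,
                                   plan$presented_ms)
    tp <- two_tone_p(sp$after_ids, params$h_after, params$f_after)
    blocks[[k + 2L]] <- phase_rows(participant_id, s, "after", sp$after_ids,
                                   tp$is_test, tp$p, plan$presented_ms)
    k <- k + 3L
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Specification of one synthetic group
#'
#' Describes a group on the (d-prime, false-alarm) scale per phase, with
#' optional between-observer heterogeneity as normal jitter on the
#' (d-prime, criterion) scale. The default jitter is zero: with 30 test and
#' 30 control Bernoulli trials per phase, trial-sampling noise alone already
#' produces observed-score spread of the order reported for real cohorts.
#'
#' @param label group label (`control`, `lbd_nonvh` or `lbd_vh`).
#' @param n number of observers (>= 2).
#' @param d_before,fa_before,d_after,fa_after group-level true d-prime and
#'   false-alarm rate per phase.
#' @param sd_d,sd_c between-observer SDs of d-prime and criterion jitter.
#' @return Object of class `"group_spec"`.
#' @export
group_spec <- function(label, n, d_before, fa_before, d_after, fa_after,
                       sd_d = 0, sd_c = 0) {
  if (n < 2) stop("group n must be >= 2", call. = FALSE)
  # validate that the central parameters invert cleanly
  probs_from_sdt(d_before, fa_before)
  probs_from_sdt(d_after, fa_after)
  structure(list(label = label, n = as.integer(n),
                 d_before = d_before, fa_before = fa_before,
                 d_after = d_after, fa_after = fa_after,
                 sd_d = sd_d, sd_c = sd_c),
            class = "group_spec")
}

#' Default cohort calibration
#'
#' Three [group_spec()]s reproducing the published group summaries:
#' hallucinating patients (n = 17, d-prime 1.41 to 1.95, false alarms 0.23
#' to 0.16), non-hallucinating patients (n = 20, 1.96 to 2.15, 0.14 to
#' 0.13) and controls (n = 20, 1.92 to 2.32). Control false-alarm rates are
#' unreported in the source summaries; the control spec fixes the criterion
#' at the hallucinator group's implied Before value (about 0.034) and
#' derives (h, f) from the control d-prime values — a documented convention,
#' not an observed quantity.
#'
#' @return Named list of three `"group_spec"` objects.
#' @export
default_cohort_spec <- function() {
  # criterion implied by VH Before (d' = 1.41, f = 0.23)
  vh_before <- probs_from_sdt(1.41, 0.23)
  c_ref <- unname(criterion(vh_before["h"], vh_before["f"]))
  ctrl_before <- probs_from_dc(1.92, c_ref)
  ctrl_after <- probs_from_dc(2.32, c_ref)
  list(
    lbd_vh = group_spec("lbd_vh", 17, 1.41, 0.23, 1.95, 0.16),
    lbd_nonvh = group_spec("lbd_nonvh", 20, 1.96, 0.14, 2.15, 0.13),
    control = group_spec("control", 20,
                         1.92, unname(ctrl_before["f"]),
                         2.32, unname(ctrl_after["f"])))
}

draw_observer_from_spec <- function(spec) {
  # jitter on the (d', c) scale, then convert to probabilities
  pb <- probs_from_sdt(spec$d_before, spec$fa_before)
  pa <- probs_from_sdt(spec$d_after, spec$fa_after)
  if (spec$sd_d > 0 || spec$sd_c > 0) {
    jd <- stats::rnorm(2, 0, spec$sd_d)
    jc <- stats::rnorm(2, 0, spec$sd_c)
    cb <- criterion(pb["h"], pb["f"]) + jc[1]
    ca <- criterion(pa["h"], pa["f"]) + jc[2]
    db <- max(spec$d_before + jd[1], 1e-3)
    da <- max(spec$d_after + jd[2], 1e-3)
    pb <- probs_from_dc(db, cb)
    pa <- probs_from_dc(da, ca)
    true_d <- c(before = db, after = da)
  } else {
    true_d <- c(before = spec$d_before, after = spec$d_after)
  }
  list(params = observer_params(pb[["h"]], pb[["f"]], pa[["h"]], pa[["f"]]),
       true_d = true_d)
}

#' Simulate a full cohort
#'
#' Draws each observer's generative parameters from its group's spec,
#' simulates a trial log per observer under the shared experiment plan, and
#' returns the logs with a metadata table. Fully reproducible from `seed`.
#'
#' @param specs list of [group_spec()]s (e.g. [default_cohort_spec()]).
#' @param plan an [build_experiment()] plan.
#' @param seed integer seed.
#' @param simulate_logs when `FALSE`, draw observer parameters and metadata
#'   only (cheap mode for parameter-recovery studies that do not need
#'   trial-level data).
#' @return Object of class `"cohort"`: list with `logs` (named list of
#'   trial-log data frames), `metadata` (participant_id, group, severity,
#'   true d-prime per phase) and the seed.
#' @export
simulate_cohort <- function(specs, plan, seed = 1L, simulate_logs = TRUE) {
  if (any(vapply(specs, function(s) s$n, 1L) < 1L))
    stop("every group needs n >= 1", call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  logs <- list()
  meta <- list()
  i <- 0L
  for (spec in specs) {
    for (j in seq_len(spec$n)) {
      i <- i + 1L
      pid <- sprintf("p%03d", i)
      drawn <- draw_observer_from_spec(spec)
      if (simulate_logs) logs[[pid]] <- simulate_observer(drawn$params, plan, pid)
      meta[[i]] <- data.frame(participant_id = pid, group = spec$label,
                              severity = NA_real_,
                              true_d_before = drawn$true_d[["before"]],
                              true_d_after = drawn$true_d[["after"]],
                              stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  structure(list(logs = logs, metadata = metadata, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf("Synthetic cohort: %d observers (%s), seed %d\n",
              nrow(x$metadata),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Attach a severity covariate linked to true improvement
#'
#' Gives each hallucinating observer a severity score correlated with their
#' true Before-to-After d-prime change: severity has the requested mean and
#' SD and population squared correlation `target_r2` with the true
#' improvement. Requires between-observer heterogeneity in the group spec
#' (`sd_d > 0`), since with identical true improvements no severity link can
#' produce a nonzero correlation.
#'
#' @param cohort a `"cohort"` object.
#' @param target_r2 requested population r-squared in (0, 1].
#' @param mean_severity,sd_severity marginal moments of the severity score
#'   (defaults 5.2 and 1.9, matching the reported severity scale).
#' @param group group label receiving severity (default `lbd_vh`).
#' @param seed integer seed for the noise draw.
#' @return The cohort with `metadata$severity` filled for the target group.
#' @export
attach_severity <- function(cohort, target_r2 = 0.62, mean_severity = 5.2,
                            sd_severity = 1.9, group = "lbd_vh", seed = 1L) {
  if (target_r2 <= 0 || target_r2 > 1)
    stop("target_r2 must lie in (0, 1]", call. = FALSE)
  rows <- cohort$metadata$group == group
  if (!any(rows)) stop(sprintf("no observers in group '%s'", group), call. = FALSE)
  d_true <- cohort$metadata$true_d_after[rows] - cohort$metadata$true_d_before[rows]
  sd_d <- stats::sd(d_true)
  if (!is.finite(sd_d) || sd_d == 0)
    stop("true improvements are constant; severity link infeasible (set sd_d > 0 in the group spec)",
         call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  r <- sqrt(target_r2)
  z <- (d_true - mean(d_true)) / sd_d
  # population-level link: corr(severity, true improvement) = r; the sample
  # correlation then varies around r, which is what recovery studies measure
  sev <- mean_severity +
    sd_severity * (r * z + sqrt(1 - r^2) * stats::rnorm(length(d_true)))
  cohort$metadata$severity[rows] <- sev
  cohort
}
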