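# Block-design construction: Before / Template / After sessions.
#
# Each session presents 10 two-tone images (5 test, 5 control) in random
# order (Before), then 20 colour images containing those 10 templates plus
# 10 fillers (Template), then the same 10 two-tone images reshuffled (After).
# The default experiment has 6 sessions, so 60 unique two-tone stimuli each
# seen twice (Before and After) and 120 distinct colour images, preceded by a
# practice session over easier stimuli with a 65%-correct gate.

TRIAL_LOG_COLUMNS <- c("participant_id", "session", "phase", "stimulus_id",
                       "is_test", "presented_ms", "response", "rt_ms")

#' Build an experiment plan
#'
#' Allocates stimuli to sessions (5 test + 5 control per session), draws the
#' within-block presentation orders from a seeded generator, and attaches a
#' practice session. All randomization is a pure function of
#' `(manifest, n_sessions, seed)`.
#'
#' @param manifest data frame with columns `stimulus_id`, `template_id`,
#'   `is_test` describing the available two-tone stimuli.
#' @param n_sessions number of experimental sessions (default 6).
#' @param seed integer seed controlling all allocation and ordering.
#' @param filler_pool optional character vector of colour-image ids used to
#'   pad each Template block to 20 images; autogenerated ids are used when
#'   omitted.
#' @param practice_manifest optional manifest of easier stimuli for the
#'   practice session; a synthetic 5+5 practice set is generated when omitted.
#' @param practice_threshold proportion-correct gate for the practice session
#'   (inclusive; default 0.65).
#' @param presented_ms nominal presentation duration recorded in trial logs.
#' @return Object of class `"experiment_plan"`.
#' @export
build_experiment <- function(manifest, n_sessions = 6L, seed = 1L,
                             filler_pool = NULL, practice_manifest = NULL,
                             practice_threshold = 0.65, presented_ms = 800L) {
  req <- c("stimulus_id", "template_id", "is_test")
  if (!all(req %in% names(manifest)))
    stop("manifest needs columns stimulus_id, template_id, is_test", call. = FALSE)
  n_sessions <- as.integer(n_sessions)
  test_ids <- as.character(manifest$stimulus_id[manifest$is_test])
  ctrl_ids <- as.character(manifest$stimulus_id[!manifest$is_test])
  need <- 5L * n_sessions
  if (length(test_ids) < need || length(ctrl_ids) < need)
    stop(sprintf("need at least %d test and %d control stimuli", need, need),
         call. = FALSE)
  template_of <- stats::setNames(as.character(manifest$template_id),
                                 as.character(manifest$stimulus_id))

  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  test_use <- sample(test_ids, need)
  ctrl_use <- sample(ctrl_ids, need)
  n_fill <- 10L * n_sessions
  if (is.null(filler_pool))
    filler_pool <- sprintf("filler_%03d", seq_len(n_fill))
  if (length(filler_pool) < n_fill)
    stop(sprintf("filler pool needs at least %d colour images", n_fill), call. = FALSE)
  fillers <- sample(as.character(filler_pool), n_fill)

  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    ids <- c(test_use[(s - 1L) * 5L + 1:5], ctrl_use[(s - 1L) * 5L + 1:5])
    before_ids <- sample(ids)
    after_ids <- sample(ids)
    templates <- c(unname(template_of[ids]), fillers[(s - 1L) * 10L + 1:10])
    sessions[[s]] <- list(before_ids = before_ids,
                          template_ids = sample(templates),
                          after_ids = after_ids)
  }

  if (is.null(practice_manifest)) {
    practice_manifest <- data.frame(
      stimulus_id = sprintf("practice_%02d", 1:10),
      template_id = sprintf("practice_tpl_%02d", 1:10),
      is_test = rep(c(TRUE, FALSE), each = 5))
  }
  p_ids <- as.character(practice_manifest$stimulus_id)
  p_test <- practice_manifest$is_test
  practice <- list(
    before_ids = sample(p_ids),
    template_ids = sample(c(as.character(practice_manifest$template_id),
                            sprintf("practice_filler_%02d", seq_along(p_ids)))),
    after_ids = sample(p_ids))

  is_test_map <- stats::setNames(c(manifest$is_test, p_test),
                                 c(as.character(manifest$stimulus_id), p_ids))
  template_truth <- stats::setNames(
    c(manifest$is_test, p_test),
    c(as.character(manifest$template_id),
      as.character(practice_manifest$template_id)))
  structure(list(sessions = sessions, practice = practice,
                 template_is_test = template_truth,
                 practice_threshold = practice_threshold,
                 n_sessions = n_sessions, seed = as.integer(seed),
                 presented_ms = as.integer(presented_ms),
                 is_test = is_test_map),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  n <- x$n_sessions
  cat(sprintf("Experiment plan: %d sessions + practice (seed %d)\n", n, x$seed))
  cat(sprintf("  %d two-tone stimuli, each presented Before and After (%d two-tone trials)\n",
              10L * n, 20L * n))
  cat(sprintf("  %d template-block colour images; practice gate >= %.0f%% correct\n",
              20L * n, 100 * x$practice_threshold))
  invisible(x)
}

#' Practice-session gate
#'
#' Returns `TRUE` when practice proportion correct meets or exceeds the
#' threshold (the gate is inclusive: 13/20 passes a 0.65 threshold).
#'
#' @param practice_log trial-log data frame of practice trials with `response`
#'   and `is_test` columns (correct = response equals is_test).
#' @param threshold proportion-correct cut-off (default 0.65).
#' @return Logical scalar.
#' @export
practice_gate <- function(practice_log, threshold = 0.65) {
  if (is.null(practice_log) || nrow(practice_log) == 0L)
    stop("empty practice log", call. = FALSE)
  correct <- practice_log$response == practice_log$is_test
  mean(correct) >= threshold
}

#' Validate a trial log against an experiment plan
#'
#' Checks that the log contains exactly the plan's trial slots: per-session
#' Before/After/Template counts, the 5+5 test/control balance of two-tone
#' blocks, agreement of presented stimulus ids with the plan, and absence of
#' missing responses. Violations are returned as data, not raised.
#'
#' @param log trial-log data frame (schema of [simulate_observer()]).
#' @param plan an `"experiment_plan"`.
#' @return Character vector of violation messages (empty when the log is
#'   consistent with the plan).
#' @export
validate_log <- function(log, plan) {
  v <- character(0)
  need_cols <- setdiff(TRIAL_LOG_COLUMNS, names(log))
  if (length(need_cols))
    return(sprintf("missing columns: %s", paste(need_cols, collapse = ", ")))
  if (anyNA(log$response)) v <- c(v, "missing responses present")
  for (s in seq_len(plan$n_sessions)) {
    sp <- plan$sessions[[s]]
    for (ph in c("before", "after", "template")) {
      ids <- switch(ph, before = sp$before_ids, after = sp$after_ids,
                    template = sp$template_ids)
      got <- log$stimulus_id[log$session == s & log$phase == ph]
      if (length(got) != length(ids)) {
        v <- c(v, sprintf("session %d %s: %d trials, expected %d",
                          s, ph, length(got), length(ids)))
        next
      }
      if (!identical(sort(as.character(got)), sort(as.character(ids))))
        v <- c(v, sprintf("session %d %s: stimulus ids differ from plan", s, ph))
      if (ph %in% c("before", "after")) {
        n_test <- sum(log$is_test[log$session == s & log$phase == ph])
        if (n_test != 5L)
          v <- c(v, sprintf("session %d %s: %d test / %d control, expected 5/5",
                            s, ph, n_test, length(got) - n_test))
      }
    }
  }
  v
}
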