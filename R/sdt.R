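# Signal-detection scoring of yes/no trial logs.
#
# d' = z(h) - z(f),  c = -(z(h) + z(f)) / 2,  z = probit.
# Hit and false-alarm rates are pooled over all sessions within a phase
# (30 test + 30 control per phase in the default 6-session design) and
# corrected away from {0, 1} before any probit use.

#' Probit (inverse standard normal CDF)
#'
#' Thin wrapper around [stats::qnorm()] with a strict open-interval domain,
#' used as the z(.) transform of signal-detection theory.
#'
#' @param p probability strictly inside (0, 1); vectorized.
#' @return Standard normal quantile(s).
#' @export
probit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probit requires 0 < p < 1", call. = FALSE)
  stats::qnorm(p)
}

#' Correct extreme response rates
#'
#' Adjusts proportions of `yes` counts so rates never sit on 0 or 1.
#' `"half_count"` replaces 0 with 1/(2N) and 1 with 1 - 1/(2N); `"loglinear"`
#' computes (count + 0.5) / (N + 1) for every rate.
#'
#' @param count number of yes responses.
#' @param n number of trials (per class).
#' @param correction `"half_count"` (default) or `"loglinear"`.
#' @return Corrected rate(s) strictly inside (0, 1).
#' @export
correct_rate <- function(count, n, correction = c("half_count", "loglinear")) {
  correction <- match.arg(correction)
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (correction == "loglinear") return((count + 0.5) / (n + 1))
  r <- count / n
  nn <- rep_len(n, length(r))
  lo <- r == 0
  hi <- r == 1
  r[lo] <- 1 / (2 * nn[lo])
  r[hi] <- 1 - 1 / (2 * nn[hi])
  r
}

#' Hit and false-alarm rates for one phase
#'
#' Computes h (yes on test trials) and f (yes on control trials) from a slice
#' of a participant's trial log containing a single two-tone phase, with the
#' configured extreme-rate correction applied before any probit use.
#'
#' @param trials trial-log slice (columns `is_test`, `response`) of one
#'   participant and one phase.
#' @param correction extreme-rate correction, see [correct_rate()].
#' @return List with `h`, `f`, `n_test`, `n_control`, `hits`, `fas`.
#' @export
rates <- function(trials, correction = "half_count") {
  n_test <- sum(trials$is_test)
  n_control <- sum(!trials$is_test)
  if (n_test == 0L || n_control == 0L)
    stop("need at least one test and one control trial", call. = FALSE)
  hits <- sum(trials$response[trials$is_test])
  fas <- sum(trials$response[!trials$is_test])
  list(h = correct_rate(hits, n_test, correction),
       f = correct_rate(fas, n_control, correction),
       n_test = n_test, n_control = n_control, hits = hits, fas = fas)
}

#' Discrimination sensitivity d-prime
#'
#' @param h hit rate in (0, 1).
#' @param f false-alarm rate in (0, 1).
#' @return z(h) - z(f).
#' @export
dprime <- function(h, f) probit(h) - probit(f)

#' Response criterion c
#'
#' @inheritParams dprime
#' @return -(z(h) + z(f)) / 2; positive values indicate a conservative bias
#'   against reporting a person.
#' @export
criterion <- function(h, f) -(probit(h) + probit(f)) / 2

block_scores <- function(participant_id, phase, r) {
  hits <- r$hits
  cr <- r$n_control - r$fas
  data.frame(participant_id = participant_id, phase = phase,
             n_test = r$n_test, n_control = r$n_control,
             h = r$h, f = r$f,
             dprime = dprime(r$h, r$f), criterion = criterion(r$h, r$f),
             pct_correct = 100 * (hits + cr) / (r$n_test + r$n_control),
             stringsAsFactors = FALSE)
}

#' Score one participant's trial log
#'
#' Pools all sessions' Before trials into one Before block and likewise After,
#' computes signal-detection metrics per block, and the After - Before
#' differences.
#'
#' @param log trial-log data frame for one participant.
#' @param correction extreme-rate correction, see [correct_rate()].
#' @return Object of class `"sdt_scores"`: list with `before` and `after`
#'   one-row data frames (h, f, d-prime, criterion, percentage correct) and
#'   `diff` (d_diff, pct_diff, fa_diff, hit_diff, c_diff), plus the
#'   correction used.
#' @export
score_participant <- function(log, correction = "half_count") {
  pid <- as.character(log$participant_id[1])
  before <- block_scores(pid, "before", rates(log[log$phase == "before", ], correction))
  after <- block_scores(pid, "after", rates(log[log$phase == "after", ], correction))
  diff <- data.frame(
    participant_id = pid,
    d_diff = after$dprime - before$dprime,
    pct_diff = after$pct_correct - before$pct_correct,
    fa_diff = after$f - before$f,
    hit_diff = after$h - before$h,
    c_diff = after$criterion - before$criterion,
    stringsAsFactors = FALSE)
  structure(list(before = before, after = after, diff = diff,
                 correction = correction),
            class = "sdt_scores")
}

#' @export
print.sdt_scores <- function(x, ...) {
  cat(sprintf("SDT scores for participant %s (%s correction)\n",
              x$before$participant_id, x$correction))
  for (ph in c("before", "after")) {
    b <- x[[ph]]
    cat(sprintf("  %-6s h=%.3f f=%.3f d'=%.3f c=%.3f %%correct=%.1f\n",
                ph, b$h, b$f, b$dprime, b$criterion, b$pct_correct))
  }
  d <- x$diff
  cat(sprintf("  diff   d'=%+.3f  %%=%+.1f  fa=%+.3f  hit=%+.3f  c=%+.3f\n",
              d$d_diff, d$pct_diff, d$fa_diff, d$hit_diff, d$c_diff))
  invisible(x)
}

#' Score a cohort of trial logs
#'
#' @param logs named list of per-participant trial logs, or one long data
#'   frame with a `participant_id` column.
#' @param correction extreme-rate correction, see [correct_rate()].
#' @return Data frame with one row per participant: before/after h, f,
#'   d-prime, criterion, percentage correct, and all differences.
#' @export
score_cohort <- function(logs, correction = "half_count") {
  if (is.data.frame(logs))
    logs <- split(logs, logs$participant_id)
  rows <- lapply(logs, function(log) {
    s <- score_participant(log, correction)
    data.frame(
      participant_id = s$before$participant_id,
      h_before = s$before$h, f_before = s$before$f,
      d_before = s$before$dprime, c_before = s$before$criterion,
      pct_before = s$before$pct_correct,
      h_after = s$after$h, f_after = s$after$f,
      d_after = s$after$dprime, c_after = s$after$criterion,
      pct_after = s$after$pct_correct,
      d_diff = s$diff$d_diff, pct_diff = s$diff$pct_diff,
      fa_diff = s$diff$fa_diff, hit_diff = s$diff$hit_diff,
      c_diff = s$diff$c_diff,
      correction = correction,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
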