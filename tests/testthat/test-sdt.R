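# Signal-detection scoring: probit, rates, d-prime, criterion.

test_that("probit matches a bisection oracle and is symmetric", {
  expect_identical(probit(0.5), 0)
  expect_equal(probit(0.975), oracle_probit(0.975), tolerance = 1e-9)
  expect_equal(probit(0.975), 1.959964, tolerance = 1e-6)
  for (p in c(0.1, 0.23, 0.749))
    expect_equal(probit(p), -probit(1 - p), tolerance = 1e-12)
  # round-trip through the normal CDF
  for (p in c(1e-6, 0.01, 0.37, 0.9, 1 - 1e-6))
    expect_lt(abs(pnorm(probit(p)) - p), 1e-10)
  expect_error(probit(0), "0 < p < 1")
  expect_error(probit(1), "0 < p < 1")
})

test_that("rates count yes responses and correct extremes", {
  log <- rbind(make_phase_log("p1", "before", 30, 22, 30, 7))
  r <- rates(log)
  expect_equal(r$h, 22 / 30, tolerance = 1e-12)  # 0.7333
  expect_equal(r$f, 7 / 30, tolerance = 1e-12)   # 0.2333

  perfect <- make_phase_log("p1", "before", 30, 30, 30, 0)
  r <- rates(perfect, "half_count")
  expect_equal(r$h, 1 - 1 / 60)
  expect_equal(r$f, 1 / 60)

  allno <- make_phase_log("p1", "before", 30, 0, 30, 0)
  r <- rates(allno, "half_count")
  expect_equal(r$h, 1 / 60)
  expect_equal(r$f, 1 / 60)

  r <- rates(perfect, "loglinear")
  expect_equal(r$h, 30.5 / 31)
  expect_equal(r$f, 0.5 / 31)

  only_test <- make_phase_log("p1", "before", 4, 2, 0, 0)[1:4, ]
  expect_error(rates(only_test), "control")
})

test_that("d-prime and criterion reproduce the defining equations", {
  expect_equal(dprime(0.42, 0.42), 0, tolerance = 1e-12)
  expect_lt(abs(dprime(0.7490, 0.23) - 1.410), 1e-3)
  expect_lt(abs(criterion(0.7490, 0.23) - 0.0338), 1e-3)
  expect_equal(dprime(0.8, 0.3), -dprime(0.3, 0.8), tolerance = 1e-12)
  expect_equal(criterion(0.5, 0.5), 0)
  expect_equal(criterion(0.77, 0.23), 0, tolerance = 1e-12)  # h = 1 - f
  # identity holds to 1e-12 against the raw probit arithmetic
  h <- 0.61; f <- 0.18
  expect_equal(dprime(h, f), qnorm(h) - qnorm(f), tolerance = 1e-12)
  expect_equal(criterion(h, f), -(qnorm(h) + qnorm(f)) / 2, tolerance = 1e-12)
})

test_that("d-prime is monotone in h and antitone in f on a grid", {
  hs <- seq(0.05, 0.95, by = 0.05)
  for (f in c(0.1, 0.3, 0.5, 0.7))
    expect_true(all(diff(dprime(hs, f)) > 0))
  for (h in c(0.2, 0.5, 0.8))
    expect_true(all(diff(dprime(h, hs)) < 0))
})

test_that("participant scoring matches hand arithmetic on a fixed 60-trial log", {
  log <- rbind(make_phase_log("p9", "before", 15, 10, 15, 6),
               make_phase_log("p9", "after", 15, 13, 15, 3))
  s <- score_participant(log)
  h_b <- 10 / 15; f_b <- 6 / 15; h_a <- 13 / 15; f_a <- 3 / 15
  expect_equal(s$before$h, h_b)
  expect_equal(s$before$f, f_b)
  expect_equal(s$before$dprime, qnorm(h_b) - qnorm(f_b))
  expect_equal(s$before$criterion, -(qnorm(h_b) + qnorm(f_b)) / 2)
  expect_equal(s$before$pct_correct, 100 * (10 + 9) / 30)
  expect_equal(s$diff$d_diff, (qnorm(h_a) - qnorm(f_a)) - (qnorm(h_b) - qnorm(f_b)))
  expect_equal(s$diff$fa_diff, f_a - f_b)
  expect_equal(s$diff$pct_diff, 100 * (13 + 12) / 30 - 100 * (10 + 9) / 30)

  # balanced-design identity: pct/100 = (h + 1 - f) / 2 on raw rates
  expect_equal(s$before$pct_correct / 100, (h_b + 1 - f_b) / 2, tolerance = 1e-12)

  # After block copied from Before -> all diffs exactly zero
  copy <- log
  copy$phase[31:60] <- "after"
  copy[31:60, c("is_test", "response")] <- log[1:30, c("is_test", "response")]
  s0 <- score_participant(copy)
  expect_identical(unname(unlist(s0$diff[-1])), rep(0, 5))
})

test_that("scoring a perfect block never produces infinities", {
  log <- rbind(make_phase_log("p2", "before", 30, 30, 30, 0),
               make_phase_log("p2", "after", 30, 30, 30, 0))
  s <- score_participant(log)
  expect_true(all(is.finite(unlist(s$before[-(1:2)]))))
  expect_true(all(is.finite(unlist(s$diff[-1]))))
})

test_that("estimated d-prime is consistent and nearly unbiased at the study's operating points", {
  # Monte-Carlo oracle: 1e5 simulated observers per operating point
  set.seed(202)
  bias_at <- function(d_true, f_true, n) {
    p <- probs_from_sdt(d_true, f_true)
    h_hat <- correct_rate(rbinom(1e5, n, p["h"]), n)
    f_hat <- correct_rate(rbinom(1e5, n, p["f"]), n)
    mean(dprime(h_hat, f_hat)) - d_true
  }
  # hallucinator-group operating points: bias under 0.08 at 30 trials/class
  for (op in list(c(0.5, 0.2), c(1.41, 0.23)))
    expect_lt(abs(bias_at(op[1], op[2], 30L)), 0.08)
  # the correction's bias grows with sensitivity but stays bounded at the
  # highest printed operating points
  for (op in list(c(1.95, 0.16), c(1.96, 0.14), c(2.32, 0.16)))
    expect_lt(abs(bias_at(op[1], op[2], 30L)), 0.12)
  # consistency: quadrupling the trial count shrinks the bias at the most
  # extreme (control After) operating point
  b30 <- bias_at(2.32, 0.16, 30L)
  b120 <- bias_at(2.32, 0.16, 120L)
  expect_lt(abs(b120), abs(b30) / 2)
})
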