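# Independent reference implementations used as oracles. These are written
# from first principles (dense loops, exhaustive scans, bisection) and stay
# independent of the code paths they check.

# Direct per-pixel bicubic interpolation from the Keys kernel definition
# (a = -0.5), pixel-centre alignment, clamped borders.
oracle_bicubic <- function(img, size) {
  keys <- function(x) {
    x <- abs(x)
    if (x <= 1) 1.5 * x^3 - 2.5 * x^2 + 1
    else if (x < 2) -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2
    else 0
  }
  out <- matrix(0, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    sy <- (i - 0.5) * nrow(img) / size - 0.5
    sx <- (j - 0.5) * ncol(img) / size - 0.5
    acc <- 0
    for (dy in -1:2) for (dx in -1:2) {
      ty <- floor(sy) + dy; tx <- floor(sx) + dx
      w <- keys(sy - ty) * keys(sx - tx)
      ty <- min(max(ty, 0), nrow(img) - 1) + 1
      tx <- min(max(tx, 0), ncol(img) - 1) + 1
      acc <- acc + w * img[ty, tx]
    }
    out[i, j] <- min(max(acc, 0), 255)
  }
  out
}

# Reflect padding by explicit index construction (edge-inclusive mirror).
oracle_pad <- function(m, r) {
  idx_r <- c(rev(seq_len(r)), seq_len(nrow(m)), seq(nrow(m), nrow(m) - r + 1))
  idx_c <- c(rev(seq_len(r)), seq_len(ncol(m)), seq(ncol(m), ncol(m) - r + 1))
  m[idx_r, idx_c, drop = FALSE]
}

# Brute-force grayscale opening: sliding-window min then max.
oracle_open <- function(img, k) {
  r <- (k - 1) / 2
  extremum <- function(m, f) {
    p <- oracle_pad(m, r)
    out <- m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      out[i, j] <- f(p[i:(i + 2 * r), j:(j + 2 * r)])
    out
  }
  extremum(extremum(img, min), max)
}

# Naive dense 2-D Gaussian convolution with reflect padding.
oracle_blur <- function(img, k, sigma) {
  r <- (k - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
  K <- outer(g, g)
  p <- oracle_pad(img, r)
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    out[i, j] <- sum(K * p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# Exhaustive Otsu: scan all 255 candidate thresholds, compute between-class
# variance directly from the pixel values.
oracle_otsu <- function(img) {
  v <- as.vector(pmin(pmax(round(img), 0), 255))
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_v) { best_v <- s; best_t <- t }
  }
  best_t
}

# Probit by bisection on the erf-based normal CDF.
oracle_probit <- function(p, tol = 1e-12) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small manifest for design tests.
make_manifest <- function(n_test, n_control = n_test) {
  data.frame(
    stimulus_id = c(sprintf("t%02d", seq_len(n_test)),
                    sprintf("c%02d", seq_len(n_control))),
    template_id = c(sprintf("tt%02d", seq_len(n_test)),
                    sprintf("tc%02d", seq_len(n_control))),
    is_test = rep(c(TRUE, FALSE), c(n_test, n_control)),
    stringsAsFactors = FALSE)
}

# Hand-rolled trial-log slice (one phase) from counts.
make_phase_log <- function(pid, phase, n_test, hits, n_control, fas) {
  data.frame(
    participant_id = pid, session = 1L, phase = phase,
    stimulus_id = sprintf("%s_s%02d", phase, seq_len(n_test + n_control)),
    is_test = rep(c(TRUE, FALSE), c(n_test, n_control)),
    presented_ms = 800L,
    response = c(rep(c(TRUE, FALSE), c(hits, n_test - hits)),
                 rep(c(TRUE, FALSE), c(fas, n_control - fas))),
    rt_ms = 1000, stringsAsFactors = FALSE)
}
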