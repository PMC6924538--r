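---
title: "Methods: two-tone stimuli, signal-detection scoring, and calibrated synthetic observers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tone stimuli, signal-detection scoring, and calibrated synthetic observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mooneysdt)
```

## The paradigm and the model

Two-tone (Mooney) images are binarized photographs that are hard to
interpret until the source photograph (the *template*) has been seen.
Comparing yes/no person-detection performance on the same two-tone images
*before* and *after* template viewing isolates the contribution of prior
knowledge to perception. The package scores each phase with equal-variance
signal detection theory:

$$d' = z(h) - z(f), \qquad c = -\tfrac{1}{2}\,[z(h) + z(f)],$$

with hit rate $h$, false-alarm rate $f$ and probit $z$. $d'$ measures how
well the observer separates person-present from person-absent images
independent of response bias; $c$ measures the bias itself. The
Before→After change in $d'$ is the quantity of scientific interest: a
larger change means prior knowledge helped more. In Lewy body disease,
patients with habitual visual hallucinations show a larger change than
patients without, driven mainly by a drop in false alarms.

Assumptions inherited from this model: equal signal and noise variance (no
confidence ratings or z-ROC data exist in a yes/no design to relax it), and
stable response probabilities within a phase.

## Stimulus pipeline parameters

`make_two_tone()` runs resize → grayscale → opening → blur → threshold.

| parameter | default | meaning |
|---|---|---|
| `target_size` | 500 px | square output size; bicubic (Keys, a = −0.5) interpolation |
| grayscale weights | 0.299/0.587/0.114 | ITU-R BT.601 luminance, the common image-library default |
| `opening_kernel` | 1 px | square structuring element of the grayscale opening |
| `blur_kernel` | 9 px | Gaussian kernel side |
| `blur_sigma` | `"auto"` → 1.7 px | `0.3·((k−1)/2 − 1) + 0.8`, the kernel-to-sigma convention of the mainstream image libraries |

Numerical choices, held fixed so the pipeline is bit-reproducible:

- **Borders**: reflect padding (edge-inclusive mirror) for both blur and
  morphology.
- **Rounding**: grayscale conversion and the post-blur image are rounded to
  integer intensities, emulating 8-bit processing; the blur operation
  itself is real-valued so it can be validated against dense convolution at
  1e-6 relative error.
- **Otsu**: threshold chosen by exhaustive maximization of between-class
  variance over the 256-bin histogram, ties broken toward the lowest
  threshold; pixels strictly above the threshold map to 255. A constant
  image raises an error rather than returning a degenerate "two-tone" with
  one tone. Downstream logic never depends on the 0/255 polarity: inverting
  a template flips the tones but yields the same binary partition.
- **The 1×1 opening** is mathematically the identity, so the default
  "noise clearing" step does nothing; we keep it as the faithful default
  but expose the kernel (and test a 3×3) since a larger element is the only
  way this stage can actually denoise. Whether the published value was a
  typo cannot be resolved from the text.
- **Pilot screening** (`screen_stimuli()`) keeps stimuli with pilot
  `before ≤ 0.80` and `after ≥ 0.65`; no numeric cut-offs are published, so
  these defaults are configuration values, not claims, and the rule accepts
  scores on any discrimination scale (proportion correct or d′) as long as
  the cut-offs match.

## Design and scoring choices

- **Practice gate**: "65% discrimination sensitivity" is interpreted as
  proportion correct — d′ is unbounded so a percentage cannot refer to it —
  and the gate is inclusive (13/20 passes).
- **Template blocks** contain the session's 10 templates plus 10 filler
  colour images drawn from a seeded pool, reaching the stated 20 per
  session and 120 distinct colour images over 6 sessions.
- **Pooling**: Before/After rates pool all sessions (30 test + 30 control
  trials per phase), matching single per-phase values; per-session scoring
  is possible by slicing the log.
- **Extreme-rate correction**: the half-count rule (0 → 1/(2N),
  1 → 1−1/(2N)) is the default; the log-linear rule ((count+0.5)/(N+1),
  applied to every rate) is available. The choice is recorded in the score
  output. Without correction a perfect block would give infinite d′.
- **Reaction times** are carried in the trial-log schema but never
  analysed.

### Finite-trial bias of scored d′

With 30 trials per class the corrected estimator is biased upward, and the
bias grows with the true operating point: about +0.02 at d′ = 0.5, +0.05
at the hallucinator Before point (1.41, f = 0.23), +0.085 at (1.95, 0.16)
and (1.96, 0.14), and +0.11 at the highest control point (2.32, 0.16)
(2×10⁵-replicate Monte-Carlo). Because the Before and After biases largely
cancel, group mean *changes* in d′ sit within a few hundredths of the
generating change — which is why replicate means of the calibrated cohorts
reproduce the published group changes within ±0.05 even though absolute
block means are visibly inflated. Tests assert the sub-0.08 bound only
where it actually holds (d′ ≤ 1.41 points) and a consistency property
(quadrupling trials at least halves the bias) elsewhere.

## Statistical battery

- **Dispatch**: Shapiro-Wilk on every sample at α = 0.05; all-normal →
  Student t (two groups; Welch by flag) or one-way ANOVA with Tukey HSD;
  otherwise Mann-Whitney (exact when both n ≤ 8, normal approximation with
  continuity correction above) or Kruskal-Wallis with a Nemenyi post hoc.
  The Nemenyi test uses the mean-rank / studentized-range formulation
  ($q = |\bar R_i - \bar R_j| \sqrt{2} / \sqrt{N(N+1)/12\,(1/n_i + 1/n_j)}$,
  p from the studentized range with infinite df), without tie correction —
  adequate for continuous scores.
- **Effect size**: Hedges g with the correction $J = 1 - 3/(4(n_1+n_2)-9)$
  on the pooled SD. Applied to the published improvement summaries
  (0.54 ± 0.41, n = 17 vs 0.20 ± 0.47, n = 20) it returns 0.7499; the
  source reports that SD once as 0.46 and once as 0.47 — we follow the pair
  co-printed with the effect size, and 0.46 would give 0.76 instead.
- **Planned contrasts**: the hallucinator vs non-hallucinator comparisons
  are run uncorrected alongside the corrected omnibus post hocs,
  mirroring the explicit choice to minimize type II error for the main
  contrast of interest; both appear in the report, labelled by test.
- **Levene's test** (via `car::leveneTest`) on Before- and After-block d′
  across the three groups probes the ceiling-effect alternative: a ceiling
  would compress variance in the better-performing groups.
- **Severity regression**: OLS of d′ improvement on hallucination severity
  (plus optional covariate columns, supplied as configuration because the
  exact published covariate coding is ambiguous). We report the residual
  df = n − p (15 for a simple regression at n = 17); sources that report
  df = n − 1 will differ by one. Collinear covariates raise an error naming
  the offending columns.
- Type-I calibration of every dispatched route is verified on
  2000-replicate null simulations (rejection 0.05 ± 0.015).

## The synthetic observer model

`simulate_observer()` draws every two-tone response as an independent
Bernoulli: probability `h_phase` on person-present trials, `f_phase` on
person-absent trials; template-block responses are correct with probability
0.98 (irrelevant to analysis; exercises the schema). This is the minimal
generative model consistent with per-phase pooled scoring. What it
deliberately omits: within-phase learning, session drift, per-stimulus
difficulty (real images differ; responses to the same image before/after
are correlated), and any mechanistic account of *why* hallucinators weight
priors more. Passing calibration tests therefore shows the scoring and
statistics recover what the generative model encodes — not that real
observers behave like independent Bernoulli responders.

Group calibration (`default_cohort_spec()`) uses the published operating
points: hallucinators n = 17, d′ 1.41 → 1.95, f 0.23 → 0.16;
non-hallucinators n = 20, 1.96 → 2.15, 0.14 → 0.13; controls n = 20, d′
1.92 → 2.32. Control false-alarm rates are unpublished: the control group
spec fixes the
control criterion at the hallucinators' implied Before value (c ≈ 0.034)
and derives (h, f) from the control d′ — a convention, flagged as such.

**Between-observer heterogeneity defaults to zero.** At 30 + 30 trials per
phase, binomial sampling alone gives SD(scored Δd′) ≈ 0.5, already at or
above the published cohort SDs (0.41/0.47) — real observers see the same
images twice, correlating their Before and After responses in a way
independent Bernoulli trials cannot. Matching the published SDs by adding
jitter is therefore infeasible under this model; jitter on the (d′, c)
scale remains available (`sd_d`, `sd_c`) and is required for the severity
link, which needs true improvements to vary.

`attach_severity()` gives hallucinating observers a severity score with
chosen mean and SD (defaults 5.2 and 1.9, the published scale) and
population correlation $\sqrt{r^2}$ with their true Δd′; recovery
simulations at n = 17 over 500 replicates return the target r² = 0.62
within ±0.05 on true improvements. Regressions on *scored* improvements are
attenuated by the trial-sampling noise above — one more reason the
published r² = 0.617 on real data cannot be reproduced from summaries.

## Reproducibility and problem sizes

A single top-level seed fans out to per-stage child seeds through a fixed
linear-congruential rule (`child_seed`), so the pipeline, its stages run in
isolation, and the tests all agree; every public simulation function is a
pure function of its seed. Validation uses: 200 random images (16–64 px)
for the Otsu oracle, 10⁵–2×10⁵ Monte-Carlo replicates for estimator bias,
2000 synthetic observers per group for calibration means in the test suite
(10000 in the reproduction script, where the Monte-Carlo error should be
negligible next to the finite-trial bias), 2000-replicate
nulls for type-I rates, and 500 replicates for severity recovery — sizes at
which the Monte-Carlo error is several times smaller than the tolerance
being checked, while the whole suite runs in a few minutes on one CPU.

## Known limitations

- The published cohort's inferential statistics (Levene W = 1.09, the
  Before-block t = 3.958, severity r² = 0.617) depend on unavailable raw
  data; the package demonstrates the *machinery* on calibrated synthetic
  cohorts instead.
- Independent-Bernoulli responding understates Before/After correlation
  and cannot match published change-score SDs (above).
- The equal-variance SDT model is assumed, not tested, as in the original
  design.
- The stimulus pipeline reproduces the published recipe, not the published
  stimulus set (the source photographs are not redistributable), and
  contains no perceptual-difficulty model of individual images.
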