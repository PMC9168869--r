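---
title: "Circadian HRV trend estimation and window discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian HRV trend estimation and window discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circhrv)
```

## The problem

Cardiac autonomic regulation fluctuates over the 24-hour cycle. Single
short-term heart-rate-variability (HRV) measurements are therefore noisy
proxies for a person's autonomic state: the time of day, the sleep schedule
and day-to-day variability all act as confounders. `circhrv` implements a
trend-based alternative designed for multi-day wearable photoplethysmography
recordings: all valid 5-minute segments from a recording period are
superimposed onto one standardized, wake-anchored day, a smooth circadian
trend is fitted per HRV metric, and groups of subjects are compared through
the medians of that trend in circadian windows. This turns many noisy
snapshots into one stable functional summary per subject, and lets
between-group differences be localized in circadian time.

## Pipeline and model

### Artifact handling

Wearable beat detection fails in two characteristic ways: a true beat is
split into two spurious short inter-beat intervals (IBIs), or two beats are
merged into one long interval. Both produce isolated IBIs far from the local
level. The detector flags beat $i$ when

$$|x_i - \mathrm{med}_i| > \max(c \cdot QD_i,\; f)$$

where $\mathrm{med}_i$ and $QD_i = (Q_3 - Q_1)/2$ are the median and
quartile deviation of the `window_beats`-wide neighborhood excluding beat
$i$. Defaults: `window_beats = 41`, `c = 3.32` (for Gaussian data
$3.32\,QD \approx 2.2\,\sigma$), and an absolute floor `f = 50` ms. The
floor matters: in low-variability stretches (sleep, SDNN below ~22 ms) the
quartile criterion alone would flag ~2.4% of clean beats; the floor makes
the false-flag rate collapse to well under 1% there while split/merge
deviations (hundreds of ms) remain far above threshold. All three
parameters are exposed because the appropriate robust cutoff is
device-dependent.

Flagged runs are removed and bridged by linear interpolation between the
flanking clean IBIs. The replacement count is the one whose summed duration
best matches the elapsed gap (measured from timestamps, so device-side
dropouts are honored), and the replacement values are rescaled to conserve
elapsed time exactly. Runs at a recording boundary have only one flank and
are dropped instead. Because interpolation fabricates data, segments with
more than four interpolated beats in a row are discarded outright — four
survives, five does not — as are segments with excessive movement (default
threshold: the subject's 90th percentile of wake-time mean segment
activity, configurable absolutely) or fewer than 100 beats.

### HRV metrics

Per 5-minute segment: SDNN (sample SD, $n-1$ denominator), RMSSD, pNN20,
pNN50 in the time domain; LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) band
powers from a Welch estimate (cubic-spline resampling of the tachogram at
4 Hz, mean removal, 120-s Hann segments, 50% overlap); and the Poincaré
dispersions computed through the standard estimator identities

$$SD1 = \frac{RMSSD}{\sqrt 2}, \qquad
  SD2 = \sqrt{\max\!\left(0,\; 2\,SDNN^2 - \tfrac{RMSSD^2}{2}\right)},$$

which satisfy $SD1^2 + SD2^2 = 2\,SDNN^2$ by construction — a conservation
law the test suite checks to $10^{-9}$ relative. We use the identities
rather than ellipse fitting because they are deterministic and make SD1/SD2
exactly reducible to time-domain quantities. Downstream trend and
discrimination stages default to SDNN, SD1 and SD2 percentages; the other
metrics are computed and exportable but are known to be more redundant or
artifact-prone on wrist-worn devices.

Raw metrics are converted to percentages of a normative reference keyed by
sex, age band and clock hour (`reference` table schema:
`sex, age_min, age_max, hour, metric, reference`). Lookup floors to the
containing band; no interpolation is attempted because such sources are
published banded. The package ships a *synthetic* normative generator
(`generate_normative_table()`) that defines the interface — positive,
smooth-in-hour, age-declining reference values — and deliberately does not
reconstruct any published table.

### The standardized day and the trend

Wake and sleep onsets (labeled per day) anchor the circadian coordinate:
the wake phase maps linearly onto $[0, 0.5)$ and the sleep phase onto
$[0.5, 1)$, regardless of their actual durations. Fixing each phase to half
the standardized day makes the ten analysis windows (five per phase, 20%
each) comparable across subjects with different schedules; it trades away
between-subject differences in absolute phase length, which is exactly what
a wake-anchored comparison wants. All recorded days are pooled
(superimposed) before fitting.

The trend is a 10th-degree polynomial least-squares fit of metric
percentage on position. Two numerical choices matter:

* **Basis.** A raw monomial basis of degree 10 on $[0,1]$ has condition
  number ~$10^7$; the fit uses an orthogonalized polynomial basis and is
  therefore exact (to machine precision) for any noiseless polynomial of
  degree ≤ 10 — a property the tests exploit as an oracle.
* **Margins.** The standardized day is periodic but a polynomial is not.
  Points within `margin_fraction` (default 0.15) of each boundary are
  replicated across it before fitting (end-of-sleep data copied before 0,
  start-of-wake data after 1), which suppresses the wild boundary behavior
  polynomials otherwise develop. For truly periodic signals the replication
  changes the interior fit by well under 1%. For non-periodic analytic
  checks (polynomial exactness, linear-trend medians) set
  `margin_fraction = 0`, since replication is then a model violation by
  design.

The ten window medians are medians of the *fitted trend* evaluated on a
1000-point midpoint grid per 0.1-wide bin — not medians of the raw points —
so sparse bins borrow strength from the whole fit. With fewer points than
the degree allows, the degree is reduced to $n - 2$; below 4 points the fit
refuses.

Segment midpoints (not starts) define both the standardized position and
the clock hour used for normative lookup; with 5-minute segments the
difference is at most 2.5 minutes, but the midpoint is the unbiased choice.

### Discrimination

`enumerate_windows()` lists all 30 contiguous within-phase bin ranges
(15 per phase); windows never span the wake/sleep boundary. For a grouping
(e.g. case vs control, or a clinical threshold such as EDSS ≥ 3, ARMSS > 4,
COMPASS-31 ≥ 17, FSMC ≥ 65 — the ARMSS rule is strict "greater than" where
sources disagree, and all thresholds are configurable), each subject
contributes the median of their trend over the window
(`search_single()`), or the difference of two window medians
(`search_delta()`, all 435 unordered pairs) under the hypothesis of an
adaptation deficit: a subject who fails to modulate HRV between two parts
of the circadian cycle has a small Δ regardless of their overall level.

Candidates are ranked by $|AUC - \tfrac12|$ — orientation-free, so a
protective and a deleterious window compete equally — with deterministic
(metric, phase, start, end) tie-breaking; reports show the
positive-class-oriented AUC. Every report row carries the full battery:
Mann-Whitney AUC with DeLong structural-components variance and normal 95%
CI clipped to $[0,1]$; two-sided Mann-Whitney-U p (exact for ≤ 8 untied
observations per group); the standardized mean difference
(case − comparison over pooled $n-1$ SD) with its asymptotic-variance CI;
and Benjamini-Hochberg adjustment with the family defined as one search
report (the natural unit here; no authority defines it more finely).
`confounder_screen()` tests the selected values against age
(Pearson/Spearman with Fisher-z CIs), gender and concomitant medication
(group comparison on the 0/1 split) at α = 0.05.

A caveat the package inherits from the design it implements: the best
window is selected *and then* tested, so its p-value is optimistic. The
ranked report makes the size of the search space explicit (90 single
selectors, 1305 Δ selectors over three metrics), and the BH adjustment runs
over that whole family, but a selection-corrected inference is deliberately
not claimed.

### Stability across day subsets

`stability_analysis()` refits the trend on every combination (or a seeded
sample of at most `max_combinations`, default 5000) of $k$ recorded days
and correlates the resulting ten-median vector with the full-data vector.
Rising, tight correlations at moderate $k$ are the evidence that a
recording period shorter than the full protocol already pins down the
trend; the test suite asserts the monotone property (median $r$ at
$k = 7$ exceeds $k = 2$; $r = 1$ exactly at $k =$ all days).

## The synthetic cohort generator

No public wearable-IBI cohort with labeled sleep, activity and clinical
grouping exists to validate against, so the generator is a first-class
module with analytically known ground truth.

**Beat level.** Within each 5-minute block the IBI process is a stationary
Gaussian AR(1) with mean $\mu(p)$, marginal SD $\sigma(p)$ and lag-1
autocorrelation $\rho(p)$ evaluated at the block's standardized position
$p$; the unit-variance innovation chain is continuous across blocks. AR(1)
is chosen not for physiological fidelity but because it gives closed-form
oracles for every downstream estimator:

$$SDNN = \sigma,\quad RMSSD = \sigma\sqrt{2(1-\rho)},\quad
  SD1 = \sigma\sqrt{1-\rho},\quad SD2 = \sigma\sqrt{1+\rho}.$$

Default profiles emulate a healthy pattern (mean IBI 780–1020 ms, SDNN
25–55 ms, ρ 0.25–0.65, all peaking during sleep; 16 h wake / 8 h sleep with
Gaussian day-to-day onset jitter, SD 20 min). Artifacts arrive as a Poisson
process (default 3/h) of beat splits and merges with positions recorded in
ground truth; both edits conserve elapsed time. Activity is near-zero
during sleep with a wake baseline plus Poisson bursts. These defaults are
fixed, documented study conditions; the real study's artifact prevalence
and activity distribution are unpublished, so they are realistic
placeholders, not estimates of any dataset.

**Segment level.** Cohort-scale studies (60 subjects × 14 days ×
288 segments/day ≈ 240k segments) do not need 90 million individual beats:
`generate_cohort(..., resolution = "segment")` draws each segment's SDNN
and RMSSD estimates directly from their AR(1) sampling distributions
(chi-square scale noise with $n_\text{beats}-1$ degrees of freedom) and
derives SD1/SD2 through the estimator identities. The beat-level path
remains the contract for preprocessing validation and end-to-end pipeline
runs; the segment-level path is the power-study engine. The two share the
same truth objects, schedules and effect machinery.

**Between-subject structure and effect injection.** Subjects carry a
truncated-normal HRV scale multiplier (CV 0.15, a realistic between-subject
spread for adult SDNN). A requested group effect
(`window`, `metric`, `smd`) multiplies the case group's $\sigma$ profile
(for SDNN%/SD2% targets) or shifts $\rho$ (for SD1%, via
$1-\rho' = (1+\delta)^2(1-\rho)$) inside the window. The multiplier
$\delta$ is solved by the delta method so that the population standardized
mean difference *of the fitted-trend window median* equals the target: the
noise-free modified profile is pushed through the actual degree-10 fit
(so the polynomial's smearing of a sharp window edge is part of the
calibration), and the case group's proportionally inflated SD enters the
pooled denominator, $d = \Delta K / (cv \cdot \sqrt{(K_0^2 + K_\delta^2)/2})$.
Non-targeted metrics co-move, as they would physiologically. Under a normal
between-subject law an SMD of $d$ implies a true AUC of
$\Phi(d/\sqrt 2)$ — the quantity the recovery tests check coverage against.

## What the tests do and do not show

The suite validates estimator definitions (hand-computed toys, brute-force
re-implementations of the artifact criterion, AUC pair counting, exhaustive
Mann-Whitney enumeration, an independent DeLong implementation in `pROC`),
conservation laws, closed-form AR(1) recovery at 2%, descriptive chi-square
p-values recomputed from published-style count tables, 93–97% empirical
DeLong coverage, and end-to-end recovery of an injected circadian effect
(best window overlapping the true window in ≥ 90% of 50 cohorts of 30 + 30
subjects × 14 days, with the DeLong CI covering the implied AUC of ~0.80 in
≥ 90%). Problem sizes — 50 recovery seeds, 1000 coverage cohorts,
60 stability combinations per subset size — are the package's chosen
defaults for a thorough desk-scale validation.

What passing does **not** show: that real wrist-PPG data meet the AR(1)
assumptions (real tachograms have respiratory and long-memory structure the
generator omits), that real artifact mixtures match split/merge at
Poisson rates, or that any specific clinical effect size is detectable in a
given cohort — the generator answers "does the pipeline recover what was
put in", not "what is in real data".

## Known limitations

* Naps and fragmented sleep are not modeled; each day must have one wake
  and one sleep interval, and segments outside labeled intervals are
  dropped.
* The frequency-domain estimator assumes enough beats for 4 Hz spline
  resampling; a Lomb-Scargle alternative is a candidate extension for very
  sparse segments.
* Boundary-spanning windows (across wake/sleep) are excluded from the
  search by design; the adaptation Δ between phases is the intended tool
  for cross-phase contrasts.
* Selection inference on the best window is reported as-is (see above).
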