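---
title: "Models and methods behind streamscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind streamscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamscore)
```

## The experimental paradigm

Listeners hear sequences of ABA– triplets: a low tone (A), a higher tone
(B), another A, then a 200-ms silence, repeating every 500 ms. With the B
tone 4 or 8 semitones above A, the sequence is initially heard as a single
galloping stream; over tens of seconds it tends to split into two isochronous
streams (the *build-up* of stream segregation). Two measures of streaming are
taken on the same stimuli:

* **subjective** — listeners continuously report "one stream" or
  "two streams";
* **objective** — listeners press a key when they detect a *deviant*
  triplet whose B tone is delayed by 50 ms. Temporal-shift detection is
  harder across streams than within one, so sensitivity falls as
  segregation increases.

Sequences contain 35, 37 or 39 triplets (17.5–19.5 s). Deviants can occur at
an early (6th triplet, 2.5 s), middle (17th from last, inclusive: 9/10/11 s)
or late (7th from last, inclusive: 14/15/16 s) position. In *switch* trials
the listener first labels noise bursts in the opposite ear ("approach" vs
"depart", one per second with rectangular ±250-ms jitter) and switches
attention to the tones at 12.5 s — the midpoint of the mean middle (10 s) and
late (15 s) deviant onsets. The factorial designs are: objective stage
2 Δf × 8 deviant configurations × 2 tasks × 3 lengths = 96 trials; subjective
stage 32 trials (all 37 triplets); dual-task stage 2 × 8 × 3 lengths = 48
trials.

A note on the middle-deviant index: counting "18th from last" inclusively
would put middle deviants at 8.5/9.5/10.5 s, which is inconsistent with the
stated onsets of 9/10/11 s and with a 12.5-s switch midpoint. We define the
middle deviant as the 17th-from-last triplet, which satisfies all three
constraints simultaneously.

## The synthetic listener

No behavioral data ship with the package, so every analysis is validated
against a generative listener whose parameters are known (planted) and can
be recovered. Perception is a two-state chain (integrated/segregated)
sampled once per 0.5-s triplet window. The integrated-to-segregated hazard
in the window at time $t$ is

$$ p_{I \to S}(t) = 1 - \exp\{-r_{\Delta f}\, e(t)\}, $$

where $e(t)$ is *effective time*: it accrues at 1 s/s while the tones are
attended, at $\rho$ s/s while they are not, and is multiplied by $\kappa$
at the moment attention switches to the tones. The reverse transition has a
constant per-window probability. This is the minimal mechanism that can
express the three competing accounts of automaticity:

* $\rho = 0$: no streaming without attention (build-up restarts at the
  switch);
* $\rho = 1,\ \kappa = 1$: fully automatic streaming (switch trials match
  attended trials in absolute time);
* intermediate $\kappa$: partial resetting — segregation resumes faster
  after a switch than at sequence start.

Defaults (per second of effective time): $r_4 = 0.002$, $r_8 = 0.005$,
chosen so that the attended proportion-segregated curve ends near 0.4 (4 st)
and 0.65 (8 st) after 18.5 s with segregation-to-integration hazard 0.02 per
window — intermediate streaming levels typical for these separations.
$\rho = 0.35$ and $\kappa = 0.5$ produce partial resetting. Percept reports
are emitted at the first attended window and at each attended state change,
after a lognormal motor delay (meanlog $\ln 0.6$ s, sdlog 0.35); percept
during unattended windows is simulated but never reported, since a
listener's experience before their first report is unknowable.

Deviant detection: each attended deviant is hit with probability
$\mathrm{logit}^{-1}(\beta_0 + b_s + \beta_{\Delta f}[\Delta f{=}8] +
\beta_{pos}\,pos + \beta_{seg}[segregated])$, defaults
$(2.5, -1.2, -0.9, -1.8)$ with subject intercepts $b_s \sim N(0, 0.5^2)$,
so hits become rarer at the wider separation, later positions, and during
segregated percepts. Press latency after the deviant's additional-silence
onset is lognormal with meanlog $\ln 0.55$ and sdlog 0.45; the 95th
percentile of that distribution is ≈1.15 s, which is what makes the
data-driven hit window land near 1.147 s. False alarms follow an
inhomogeneous Poisson process at 0.015/s while integrated and 0.006/s while
segregated — the segregated percept makes responding more conservative,
which is what the criterion contrast measures. Noise-burst labels are
correct with per-subject probability drawn from $N(0.925, 0.028^2)$ clipped
to $[0.86, 0.96]$, so that observed accuracies across a session stay within
the 82–98% range the paradigm reports while averaging 92–94%.

What the generator does *not* emulate: serial dependence between trials,
context effects of preceding sequences, learning or fatigue across blocks,
lapses, and any neural adaptation dynamics. Passing recovery tests therefore
shows the *analyses* are correct and well calibrated, not that this listener
is an adequate model of human data.

## Deviant-detection scoring

A press within 1.147 s of the start of a deviant's additional silence is a
hit; the window can also be recomputed from the data as the 95th percentile
(linear-interpolation percentile, quantile type 7) of deviant-locked
latencies pooled across conditions and subjects. Deviants are matched to
presses in time order and each press can satisfy at most one deviant; a
second press inside the same window is a false alarm. False alarms are
labeled early/middle/late by fixed section boundaries (the late section is
always the final 6 s; early and middle split the remainder equally — for
37 triplets: 6.25/12.5/18.5 s). The number of nonsignal "trials" for a
section is its duration divided by the hit window, minus one if the section
contains a deviant. Rates are pooled over all instances of a cell
(Δf × position × task); a pooled rate of exactly 0 or 1 has its numerator
adjusted by 0.5 before the z transform. Sensitivity and criterion are
$d' = z(H) - z(F)$ and $c = -(z(H) + z(F))/2$. With this scoring, a perfect
detector in an attend-condition early cell (24 sequences, 12 deviants)
reaches the ceiling $d' = z(11.5/12) - z(0.5/118.776) = 4.37 \approx 4.4$.

Two documented choices: in switch trials only post-switch sections and
deviants are scored (the listener is labeling noises before the switch and
cannot press); and percept-conditioned cells divide each section's
nonsignal time by the time actually spent in the conditioning percept, with
deviants occurring before any report excluded from percept-conditioned (but
not stimulus-conditioned) cells.

## Build-up curves

The reported percept is sampled at each triplet onset (a report at exactly
the onset counts as the new label). The proportion segregated at a time
point divides the number of trials labeled "two streams" by the number of
trials with any report so far, and is undefined where no trial has a report
yet — denominators are nondecreasing in time. Switch-aligned curves re-zero
time at 12.5 s. Group analyses that feed significance tests start 2 s after
alignment zero, where all subjects are defined; earlier points are computed
but flagged by their denominators. Phase durations between consecutive
alternations are natural-log transformed, and the final (censored) phase is
excluded — the convention we adopt since the handling of incomplete phases
is not otherwise constrained.

## The covert-attention model and the q scan

Could apparent build-up without attention be an artifact of listeners
covertly attending the tones early? Assume attention is on the tones with
fixed probability $q$ independently in each 0.5-s window. At the switch the
probability that attention has already been continuously on the tones for
exactly $k$ windows is geometric: $w_k = (1-q)q^k$ for $k < K$ and
$w_K = q^K$ with $K = 25$ pre-switch windows. The modeled switch curve at
post-switch time $t$ is $\sum_k w_k A(t + k/2)$ where $A$ is the attend
build-up curve read as a function of time-since-attending; $q = 0$
reproduces $A(t)$ (full reset), $q = 1$ reproduces $A(t + 12.5)$. Interior
undefined points of $A$ are linearly interpolated and values beyond its
support are clamped to the last defined value (the curve is near-asymptotic
there; linear extrapolation is available as an option).

The scan applies the mixture to *each subject's* attend curve, differences
the result against that subject's observed switch curve, and tests the
difference fields with the SPM cluster procedure on a grid of $q$ (default
step 0.001, matching the three-decimal precision at which such bounds are
reported). The returned set is the $q$ values with no significant cluster,
reported as intervals. The subject-level construction keeps the test
paired; testing group-mean curves instead would discard the within-subject
pairing that the t field requires.

## One-dimensional SPM

For $n$ subjects' difference fields the pointwise paired t statistic forms
a 1D field; smoothness is estimated from the variance of temporal gradients
of the unit-normalized residuals, $\mathrm{FWHM} = \sqrt{4\ln 2 / \lambda}$
(white noise on a unit grid gives ≈1.18). The corrected threshold is the
height at which the expected Euler characteristic of the thresholded
two-tailed t field — $2\,[P(T_{df} > u) + R\,\frac{\sqrt{4\ln 2}}{2\pi}
(1 + u^2/df)^{-(df-1)/2}]$ with $R$ = field length / FWHM resels — equals
$\alpha$. Cluster p-values use the standard extent approximation
($P(\text{extent} \ge k) = e^{-\beta k^2}$ in resel units). Inference is
two-tailed; infinite t values (zero variance with nonzero mean) are capped
at the 0.9999 t quantile for clustering, and all-zero points contribute
t = 0. Analysis is restricted to the largest contiguous window where every
subject is defined.

The distribution-free cross-check flips the signs of whole subject fields
and builds the null distribution of the maximum suprathreshold cluster mass.
Its default cluster-forming threshold is the pointwise two-tailed t
quantile, the convention for cluster-mass permutation tests; handing it the
RFT threshold instead makes the two methods' cluster boundaries coincide
exactly, which is how the method-concordance checks are run. On 5,000
simulated null fields (12 subjects, 101 points, FWHM 4) both methods'
family-wise error is measured at ≈0.04 at $\alpha = .05$.

## The logistic model ladder

Per-deviant hits and misses are modeled with a logistic regression
containing a normal random subject intercept. The marginal likelihood
integrates the intercept by fixed-order Gauss–Hermite quadrature (order 20,
non-adaptive; a refinement pass doubles the order if the estimated
between-subject SD exceeds 2 logits) and is maximized by BFGS with the
analytic gradient; standard errors come from the observed information
matrix. Doubling the order changes the converged log likelihood by under
$10^{-3}$ and every parameter by under $10^{-3}$ on default-size data,
so order 20 is comfortably sufficient for the likelihood-ratio decisions
the ladder makes. Complete separation is flagged as non-convergence.

Candidate fixed effects enter in a configurable order (Δf as an indicator
of 8 vs 4 semitones; position as numeric 0/1/2 — the single-df entries such
ladders report imply numeric coding; percept as an indicator of a
segregated report). An addition is retained only when the chi-squared test
on twice the log-likelihood gain (with the added df) has $p < .05$; the
percept decision is checked to be invariant to entry order. Pairwise
interactions of retained effects and independent (diagonal) random slopes
can be screened the same way; correlated slopes are not identifiable in a
screen of this size and the expected winning model has none. A sensitivity
flag re-runs the ladder on middle/late deviants only, since early deviants
almost always occur during integrated percepts and confound percept with
position.

Model quality is summarized by the adjusted count pseudo-$R^2$: predictions
are quantized at 0.5 (exactly 0.5 counts as a predicted miss, since only
values *greater* than 0.5 predict a hit), and the statistic is the gain in
correct predictions over the majority-class rule, as a fraction of what
that rule gets wrong. Fitted probabilities include the posterior-mode
subject intercepts, so the subject-only baseline already predicts better
than chance; negative values are possible and reported as-is.

## Validation problem sizes

The package's own checks run at these sizes, chosen to give decisive Monte
Carlo error while keeping a full run in minutes: scoring equivalence against
a brute-force matcher on 1,000 random press logs; SPM family-wise error on
5,000 simulated smooth null fields with a 1,000-flip permutation null where
clusters occur, and method concordance on 200 fields; q-scan recovery of a
planted $q^\ast = 0.95$ on 100 replicate 12-subject cohorts (scan step
0.005); and 100 planted plus 100 null ladder replicates (quadrature order
12 in the replicate loop). Generator-level properties (automaticity and
reset identities, Poisson false-alarm totals, latency calibration) use
1,000–4,000 simulated trials each.

## Known limitations

* The RFT cluster-extent p-value is an approximation that degrades for low
  smoothness and small extents; the sign-flip test is the authoritative
  fallback and can be selected wherever an SPM decision is made.
* The covert-attention scan reports a set of undistinguishable $q$ values,
  not an estimate with uncertainty; that is inherent to the exclusion-scan
  design.
* Percept-conditioned nonsignal counts attribute section time to percepts
  by the report trace, which inherits report latency; no latency
  deconvolution is attempted.
* The synthetic listener's independence assumptions (across trials and
  windows) make its data cleaner than human data; recovery rates measured
  here are upper bounds on what real data would support.
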