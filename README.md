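# streamscore

Analysis machinery for dual-measure auditory streaming experiments, for
auditory psychophysicists who collect **subjective percept reports**
("one stream" / "two streams") and an **objective deviant-detection task**
on the same ABA– triplet sequences.

Listeners hear triplets of a low tone (A) and a higher tone (B) every
500 ms; with Δf = 4 or 8 semitones between the tones the sequence starts as
a single galloping stream and tends to split into two streams over time
(build-up). Occasionally the B tone is delayed by 50 ms (a *deviant*);
detecting that shift is harder once the tones fall in separate streams, so
detection sensitivity and segregation reports are inversely related probes
of the same perceptual organization.

The package implements, end to end:

* **Stimulus schedules** — triplet timelines on the 0.5-s grid, deviants at
  early/middle/late positions (2.5, 9–11, 14–16 s), contralateral noise
  bursts ending at the 12.5-s attention switch, and the exact factorial
  designs (96 / 32 / 48 trials), plus optional audio rendering and WAV
  export.
* **Signal-detection scoring** — a 1.147-s hit window (or the 95th
  percentile of observed latencies), section-wise false-alarm labeling,
  duration-normalized nonsignal "trial" counts, 0.5-count correction at
  rates of 0 or 1, and
  `d' = z(H) − z(F)`, `c = −(z(H) + z(F))/2`, optionally conditioned on the
  concurrent percept.
* **Build-up curves** — proportion segregated on the triplet grid with
  responding-trial denominators, start- or switch-aligned, first-report
  statistics and log phase durations.
* **A covert-attention mixture model** — with probability *q* of attending
  the tones in each 0.5-s window, the switch-condition curve is modeled as
  the geometric-weighted mixture `Σ w_k A(t + k/2)`, `w_k = (1−q)q^k`,
  `w_K = q^K`; a grid scan returns the *q* values whose model is
  statistically indistinguishable from the observed curves.
* **1D statistical parametric mapping** — pointwise paired t fields,
  residual-based FWHM estimation, random-field-theory thresholds and
  cluster p-values, with a sign-flip permutation cluster-mass test as the
  distribution-free cross-check.
* **A logistic model ladder** — random-intercept logistic models of
  per-deviant hits fitted by Gauss–Hermite quadrature, chi-squared
  likelihood-ratio screening of Δf, position and percept (plus interactions
  and random slopes), and the adjusted count pseudo-R².
* **A synthetic listener** — a two-state hazard model of percept dynamics
  with effective-time accrual ρ while unattended and reset fraction κ at an
  attention switch, percept-dependent hit probabilities and false-alarm
  rates, lognormal latencies, and a noise-labeling channel, so every
  analysis can be validated against planted ground truth.

## Worked example

```r
library(streamscore)

cfg <- run_config(n_subjects = 12, q_step = 0.005)
e1  <- run_experiment1(cfg)

round(with(subset(e1$scores, task == "attend"),
           tapply(dprime, list(delta_f, position), mean)), 2)
#>   early late middle
#> 4  3.41 2.22   2.76
#> 8  2.58 1.22   1.76

e1$q_scan$delta_f_8
#> <q_scan rft> 201 q values, alpha = 0.05
#>   no significant model-data cluster for q in [0.855, 0.975]

e2 <- run_experiment2(cfg, exp1_scores = e1$scores)
e2$ladder
#> <model_ladder> n = 864, winning fixed effects: delta_f, position, percept
#>  step             term df_added    loglik      chi2            p accepted pseudo_r2
#>     0 subject (random)       NA -592.1002        NA           NA     TRUE 0.0511509
#>     1          delta_f        1 -562.3871  59.42619 1.269677e-14     TRUE 0.2097187
#>     2         position        1 -499.6511 125.47184 4.012437e-29     TRUE 0.3887468
#>     3          percept        1 -474.8679  49.56647 1.917635e-12     TRUE 0.4040921
```

Reading the numbers: mean attended d′ falls from the small to the large
frequency separation and from early to late deviants — detection worsens
exactly where segregation is stronger (the hit window recomputed from the
simulated latencies is 1.19 s, close to its 1.147-s default). The
covert-attention scan finds that only implausibly high per-window attention
probabilities (q ≳ 0.86) could make the covert-attention account mimic the
observed post-switch build-up of this simulated cohort — the signature used
to argue that some streaming is genuinely automatic. The model ladder
retains Δf, position **and** percept: the concurrent percept predicts
deviant detection beyond the stimulus parameters, and the mean criterion
difference (segregated − integrated) of +0.88 shows more conservative
responding during segregated phases.

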