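# mtwi: the multisensory temporal window of integration across tasks

`mtwi` is an R package for asking whether the brain's *temporal window of
integration* (TWI) — the range of audiovisual stimulus onset asynchronies
(SOAs) over which a sound and a flash are treated as one event — changes
with what the observer is trying to do. It implements, end to end, the
analysis of a two-task psychophysical design in which the same participants
complete:

* a **reaction-time (RT) task** — respond as fast as possible to the first
  stimulus of an audiovisual pair presented at SOAs of 0, ±20, 40, 60, 80,
  100, 120, 150, 200, 250, 300, 400 ms (negative = auditory first), plus
  auditory-only, visual-only and no-stimulus catch trials; and
* a **temporal-order-judgment (TOJ) task** — report which stimulus came
  first at the same SOAs.

A participant whose RTs show genuine multisensory integration at an SOA
where their order judgments are nonetheless accurate is *dissociating* the
two tasks: their window is wide when integration pays and narrow when
segregation pays — evidence that task demands recalibrate the TWI.

## The statistics at the core

**Race-model inequality (RT task).** For latency t from first-stimulus
onset, probability summation of independent channels bounds the
multisensory response probability:
`P_AV(t) ≤ P_A(t − δ_A) + P_V(t − δ_V)`, with onset delays
`δ_A = max(SOA, 0)`, `δ_V = max(−SOA, 0)`. Empirical CDFs use the
(i − 0.5)/n plotting-position convention with misses coded as infinite
latencies. The test statistic collapses four low percentiles,

```
D = Σ_{p ∈ {.10,.15,.20,.25}} [ Q_AV(p) − Q_bound(p) ] ,
```

with D < 0 indicating violation (integration). Significance comes from a
1000-iteration resampling null in which simulated multisensory samples are
minima of antithetically paired unisensory quantiles (percentile u with
1 − u: maximal negative dependence, the fastest race there is), with the
race bound re-estimated from unisensory resamples in each iteration.
Anticipatory guesses measured on catch trials are corrected by the
kill-the-twin procedure (conservative variant on observed data,
progressive on simulated data). Per participant, the RT-defined TWI is the
contiguous run of significantly violating SOAs around (or closest to)
simultaneity; the group-level summary is an exact 2^n sign-permutation
test on D per SOA.

**Bayesian psychometric function (TOJ task).** The probability of a
"visual first" response is a lapse-contaminated logistic,
`Ψ(x) = λ_A + (1 − λ_A − λ_V) F(x; μ, σ)`, fitted to per-SOA binomial
counts with priors Beta(2, 20) on both lapse rates, Normal(0, 200 ms) on
μ, and Gamma(shape 1.05, scale 1000 ms) on σ, by coordinate-wise slice
sampling (burn-in 100, thinning 10, 2000 retained draws). Thresholds for
above-chance performance (the 75%-correct points when lapse-free) are
extracted per draw; the TOJ-defined TWI spans the 5th percentile of the
auditory-side threshold draws to the 95th percentile of the visual-side
draws — deliberately the *widest* plausible window.

**Cross-task comparison.** A dissociation SOA is one with significant race
violation inside the RT window but lying outside the TOJ window; any
dissociation marks the participant *malleable*. Groups are compared with
pooled-variance t-tests on window widths and boundaries and a two-factor
(task × group) ANOVA on widths.

A synthetic-study generator (ex-Gaussian reaction times coupled by a
Gaussian copula, an optional coactivation gain near simultaneity,
anticipatory guesses and misses, binomial TOJ counts) provides complete
studies with known ground truth, so the whole pipeline is testable without
any data download.

## Worked example

```r
library(mtwi)

study <- make_study(synth_config_study(seed = 42))   # 11 participants, 5 malleable by construction
report <- run_study(study, study_config(seed = 7))
print(report)
#> <study_report> 11 participants (11 retained for TOJ), 5 malleable
#>   group RT TWI: [-100, +100] ms
#>   group TOJ thresholds: [-91, 99] ms
print(report$group$comparison)
#> <group_comparison> 5 malleable vs 6 non-malleable
#>   TOJ width: 60 (8) vs 385 (16) ms, t=-41.903, p=0.0000
#>   ANOVA width ~ task*group: F_task=94.83 (p=0.0000), F_int=1755.87 (p=0.0000)
```

The report says: all 11 synthetic observers were retained for the TOJ
analysis; exactly the five constructed narrow-window observers are
classified malleable; at the group level RTs show race-model violation for
SOAs from −100 to +100 ms (where the generator's coactivation gain acts),
while the group psychometric curve crosses its above-chance thresholds
near ∓90 ms; and the malleable group's TOJ-defined windows are
dramatically narrower than the others' (60 vs 385 ms), producing the large
task × group interaction that is the signature of task-driven
recalibration.

The staged analysis lives in `analysis/01_simulate_study.R` …
`04_compare_tasks.R`; each stage prints what it found and writes tables
under `results/`. Data from the original study (a MAT-container file) load
with `read_dataset_s1()` and run through the identical pipeline.

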