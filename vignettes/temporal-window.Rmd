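---
title: "Estimating and comparing the multisensory temporal window of integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing the multisensory temporal window of integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtwi)
```

The temporal window of integration (TWI) is the range of audiovisual
stimulus onset asynchronies (SOAs) over which an observer treats a sound
and a flash as one multisensory event. `mtwi` estimates the window twice
in the same observers — once from reaction-time (RT) facilitation and once
from temporal-order judgments (TOJ) — and asks whether the two estimates
dissociate, which is the signature of the window recalibrating to task
demands. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## The race-model test of the RT data

Under the race model, a multisensory response is the faster of two
unisensory processes, so multisensory facilitation cannot exceed
probability summation: for any latency `t` on the first-stimulus clock,

$$P_{AV}(t) \le P_A(t - \delta_A) + P_V(t - \delta_V), \qquad
\delta_A = \max(\mathrm{SOA}, 0),\; \delta_V = \max(-\mathrm{SOA}, 0),$$

with negative SOA meaning the auditory stimulus led. The onset delays
express the trailing stimulus on the clock that starts at the first
stimulus; the bound CDF is capped at 1 (the inequality is vacuous beyond
the cap).

Empirical CDFs are continuous piecewise-linear interpolants through the
plotting positions $(i - 0.5)/n$, where $n$ counts *all* trials including
misses; misses carry infinitely long latencies and load only the upper
tail. Quantiles invert this interpolant; probabilities below the first
position clamp to the minimum latency, and probabilities beyond the last
finite position are undefined (an SOA that cannot support the 25th
percentile is reported `untestable` and treated as non-significant).

The test statistic collapses four low percentiles into one number,
$D = \sum_{p} [Q_{AV}(p) - Q_{\mathrm{bound}}(p)]$ for
$p \in \{.10, .15, .20, .25\}$; negative D means violation. Testing only
low percentiles is where the race bound binds; collapsing avoids
accumulating type-I error over percentiles.

### The resampling null and its calibration

The null distribution of D is built by simulation: each of 1000 iterations
draws a multisensory sample of the observed size as minima of
antithetically paired unisensory quantiles (percentile $u$ in one modality
with $1-u$ in the other — maximal negative dependence, the fastest race
compatible with the marginals, hence a conservative yardstick), applies
the progressive kill-the-twin correction, and recomputes the statistic.
The one-sided p-value uses the add-one convention
$(\#\{D^* \le D\} + 1)/(n_{\mathrm{iter}} + 1)$.

Two design choices here departed from the most literal reading of the
procedure, and both are driven by calibration measurements made with the
package's own generator under the exact null (coactivation off, maximal
negative dependence):

* **The bound is re-estimated in every iteration** from with-replacement
  resamples of the two unisensory samples. If instead every $D^*$ is
  compared against the single observed bound, the simulated sample and the
  bound share the same empirical marginals, their estimation errors
  cancel, and the null distribution is far too narrow — we measured ~14%
  type-I error at a nominal 5% even with guess-free, miss-free data.
  Re-estimating the bound restores the missing variance component. The
  single-bound behaviour remains available via
  `race_test(regenerate_bound = FALSE)`.
* **The conservative kill-the-twin correction is applied to the observed
  audiovisual samples, not only the visual-only distribution.** The
  resampled null is twin-killed, so the observed multisensory sample must
  carry the matching correction; killing twins on one side only produced
  ~19% type-I error. This also matches how the original study's shared
  dataset describes its RT data (all of it corrected at source); for such
  data the pipeline skips the correction
  (`kill_twin_observed = FALSE`, wired automatically from the dataset
  metadata).

Kill-the-twin itself replaces, for each response observed on a catch
trial, one response of similar latency by an infinite latency.
"Similar" is nearest-neighbour matching with catch responses processed in
ascending order: the conservative variant (observed data) removes the
nearest latency at or below the catch response, falling back to the
overall nearest, which biases the correction toward removing fast
responses and so against declaring violation; the progressive variant
(simulated data) removes the overall nearest, ties going to the lower
latency.

Per participant, the RT-defined TWI is the contiguous run of
significantly violating SOAs containing simultaneity, or failing that the
run closest to it (ties resolved to the visual-leading side, where
violation is empirically more common); restricting to one run partly
compensates the 23 tests performed. The group-level summary is an exact
sign-permutation test on D across participants (all $2^n$ sign
assignments), reported per SOA and used only descriptively.

## The Bayesian psychometric model of the TOJ data

The probability of reporting "visual first" at SOA $x$ is a logistic
contaminated by lapses,
$\Psi(x) = \lambda_A + (1 - \lambda_A - \lambda_V)\, F(x; \mu, \sigma)$:
$\lambda_A$ is the error rate at large auditory-leading asynchronies,
$\lambda_V$ at large visual-leading ones, $\mu$ locates the point of
subjective simultaneity and $\sigma$ (ms) scales discriminability. The
likelihood is binomial per SOA; priors are Beta(2, 20) on each lapse rate
(mode 0.05 — lapses are small but rarely exactly zero), Normal(0, 200 ms)
on $\mu$, and Gamma on $\sigma$ in the shape–scale parameterization with
shape 1.05 and scale 1000 ms. That parameterization (rather than
shape–rate) is deliberate: it yields the nearly flat density with mode at
$(1.05 - 1) \times 1000 = 50$ ms that the prior is meant to be.

The posterior is explored by coordinate-wise univariate slice sampling
(stepping-out then shrinkage; initial width = the coordinate's prior SD;
initial values at the prior modes $\mu = 0, \sigma = 50,
\lambda = 0.05$; the joint lapse constraint $\lambda_A + \lambda_V < 1$
enforced by rejection inside the density). The schedule discards 100
burn-in iterations and keeps every 10th of the next 20 000, i.e. 2000
retained draws. The inner loop is compiled; an R-level implementation of
the same unnormalized posterior serves as an independent cross-check in
the tests.

Thresholds for above-chance performance solve
$\Psi(x) = (\lambda_A + 0.5)/2$ (auditory side) and
$(0.5 + 1 - \lambda_V)/2$ (visual side) in closed form via the logistic
inverse — the 25%/75% points when lapse-free. Computing them for every
posterior draw, the TOJ-defined TWI runs from the 5th percentile of the
auditory-side draws to the 95th percentile of the visual-side draws
(linear-interpolation order statistics): deliberately the *widest*
plausible window, so that later dissociation claims are conservative.
A participant whose boundary estimate falls outside the tested ±400 ms
range never reached threshold performance on that side and is excluded,
with the failing side recorded. The group curve evaluates the
psychometric function at the across-participant mean of per-participant
posterior medians; like the group race test it is illustrative only.

## Comparing the windows

A dissociation SOA shows significant race violation, lies inside the
RT-defined window, and falls strictly outside the TOJ-defined window;
participants with any dissociation SOA are *malleable*. Because the RT
window errs narrow (conservative race test) and the TOJ window errs wide
(5th/95th percentiles), a dissociation is a robust indication, and the
reverse pattern (no violation, poor order judgment) is never counted —
absence of evidence for violation is not evidence of absence. TOJ
accuracy at a dissociation SOA is the proportion of correct order reports
(`visual_first/n` at positive SOAs, its complement at negative ones).

Group statistics follow the study's conventions: pooled-variance
two-sample t-tests on window widths and boundaries, and a two-factor
between-subjects ANOVA on widths with factors task (RT/TOJ) and group
(malleable/not). The unbalanced design makes the sums-of-squares type
matter: Type II is the default (`car::Anova`), with the type exposed as an
argument; the interaction F — the quantity of interest — is the same
under either choice.

## The synthetic-data generator

The generator emulates the study design so every stage can be exercised
with known ground truth: 60 trials per condition over the 23-SOA grid,
unisensory reaction times from ex-Gaussian distributions (auditory mean
~250 ms, visual ~290 ms — auditory simple RTs are typically faster), the
two unisensory draws within a multisensory trial coupled by a Gaussian
copula with correlation $\rho$, misses at rate 0.007 and anticipatory
guesses at rate 0.0394 per trial (the study's observed averages).

Two generator choices deserve emphasis:

* **Coactivation** is a constant gain (default 50 ms) subtracted from the
  race minimum, but only at SOAs within `gamma_soa_window` (100 ms) of
  simultaneity. A gain applied at every SOA would violate the race bound
  even at ±400 ms — at long asynchronies the bound's low percentiles are
  just the leading stimulus's quantiles — making the RT-defined window
  degenerate; confining the gain reproduces the empirical finding that
  facilitation is confined to near-simultaneity. The generator is a
  deliberately simple descriptive stand-in; the analysis fits no
  generative RT model.
* **Guesses occur in every condition, not only on catch trials.** A
  prepared guess at a uniform 100–1000 ms latency preempts the
  stimulus-driven response when earlier; on catch trials it is the only
  possible response. This is precisely why catch trials estimate the
  guessing process: the kill-the-twin correction and the twin-killed
  resampling null both presuppose that stimulus conditions carry the
  contamination the catch condition measures. A generator with guess-free
  stimulus conditions would make the corrected test anticonservative by
  construction.

`synth_config_study()` is the study-conditions configuration used by the
analysis scripts and the acceptance script: 11 participants, five with
narrow true TOJ windows (true $\sigma = 20$ ms) and six with wide ones
($\sigma = 150$ ms), all with the 50 ms near-simultaneity gain. The five
narrow-window observers are malleable by construction — their TOJ windows
(≈ ±50 ms after the conservative 5th/95th widening) exclude SOAs at which
their RTs violate the race bound (up to ±100 ms) — while the wide windows
(≈ ±200 ms) cover the violating range. The sigmas are chosen for clear
separation between the constructed classes relative to the posterior
spread of the thresholds at 60 trials per SOA; the locations are jittered
by a few ms as real observers' are.

What passing on such data shows — and does not. The generator matches the
analysis's structural assumptions (binomial TOJ counts from a logistic
curve, exchangeable trials, stationary guessing). Real data bring
non-stationarity, sequential effects, fatigue, and psychometric shapes
that are not exactly logistic; the tests validate the machinery and its
calibration, not those scientific assumptions.

## Numerical choices and limitations

* Quantile/CDF conventions: plotting positions $(i-0.5)/n$; linear
  interpolation; ties collapsed to the largest position; the bound's
  crossing time solved exactly on the merged grid of shifted latencies.
* Resampling sample sizes always match the observed multisensory trial
  count, so D and D* carry the same estimation noise.
* p-values can never be exactly zero (add-one convention); per-SOA race
  results within two Monte-Carlo standard errors of $\alpha$ are flagged
  `borderline` in the report, since their significance can flip between
  seeds at 1000 iterations.
* Reproducibility: one master seed per analysis; every stochastic stage
  (per participant, per SOA, per fit) derives a fixed substream from it,
  so reports are byte-identical across runs with the same seed.
* The ex-Gaussian quantile function inverts the CDF by safeguarded Newton
  iteration (bisection fallback), accurate to ~1e-9 in probability.
* Problem sizes in the test suite (e.g. 200 null participants for the
  calibration study, 20 recovery fits, 10 end-to-end study seeds) are
  chosen to keep Monte-Carlo error comfortably below the tolerances being
  asserted while the whole suite stays conveniently runnable on a laptop.
* At SOAs far outside the facilitation range, the observed multisensory
  sample, the race bound and the resampled null all collapse onto the
  leading stimulus's distribution, so the test loses its conservative
  margin there and runs at its nominal level; and because every SOA of a
  participant shares the same unisensory samples, false violations at
  such SOAs are correlated across SOAs and can occasionally form
  contiguous runs. The contiguity rule and the `borderline` flags
  mitigate but do not eliminate this; single-participant windows with
  boundaries beyond the facilitation range deserve scrutiny.
* Known limitations: the race analysis addresses only the inequality test
  (no capacity coefficients, no coactivation-model fitting); the
  psychometric model fits only the logistic link; the kill-the-twin
  correction is an approximation whose residual error grows with the
  guess rate; and group-level summaries are descriptive, as inference is
  per participant throughout.
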