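---
title: "Collinearity diagnostics and bias simulation for rapid-event fMRI designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collinearity diagnostics and bias simulation for rapid-event fMRI designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Task fMRI analyses model the BOLD time series of a voxel as a general linear
model, $Y = X\beta + \epsilon$.  When a task presents several trial
components in rapid succession with no rest in between — as the Monetary
Incentive Delay (MID) task does, with Cue, Fixation, Probe and Feedback
abutting inside every trial — the haemodynamically convolved regressors for
those components overlap heavily.  Faced with that collinearity,
practitioners commonly (a) reparameterise (e.g. orthogonalise) regressors,
(b) drop temporal-derivative regressors, (c) merge adjacent events, (d)
replace duration-matched boxcars with onset impulses, or (e) omit whole
components.  Some of these moves only *hide* the collinearity; others
genuinely reduce it but bias the remaining estimates through unmodelled
signal.  `midvif` packages the tools needed to tell these situations apart
and to quantify the resulting bias by simulation.

## Efficiency, tVIF and cVIF

For a contrast vector $c$ over the model parameters,
$\mathrm{Var}(c\hat\beta) = \sigma^2 \, c (X'X)^{-1} c'$, and we define
`efficiency` $= 1/(c (X'X)^{-1} c')$.  Efficiency ranks designs (doubling it
halves the contrast variance) but carries no absolute benchmark.

The traditional variance inflation factor of column $j$,
$$\mathrm{tVIF}_j = \frac{\mathrm{Var}(\hat\beta_j \mid \text{full model})}
                        {\mathrm{Var}(\hat\beta_j \mid \text{intercept} + X_j)},$$
supplies the benchmark (1 = no inflation; 5 and 20 are the package's working
flags) but only for single coefficients, and it is blind to condition-signal
overlap that has been moved out of the pairwise column correlations by a
reparameterisation.

The contrast-based VIF extends the same full-vs-reduced construction to any
estimable contrast.  Writing $c$ for the weights on the task columns, the
*effective regressor* of the contrast is
$$x_c = X_{\text{task}}\, c' (c c')^{-1},$$
the unique signal whose coefficient equals $c\beta$ once the rest of the
task space ($Z = X_{\text{task}} N$, $N$ a basis of the null space of $c$)
is added back.  Then
$$\mathrm{cVIF}(c) = \frac{\mathrm{Var}(c\hat\beta \mid \text{full design})}
                         {\mathrm{Var}(\text{coef. of } x_c \mid \text{intercept} + x_c)} .$$
For an elementary contrast (a single $+1$), $x_c$ *is* the column and cVIF
reduces exactly to tVIF.  Nuisance columns (drift, motion) stay in the full
model — they inflate the numerator when they overlap the contrast — but are
never part of the best-case reduced model.

### Parameterisation and what "invariance" means here

Two design choices deserve explanation because the design space was
genuinely open:

* **Condition basis.**  cVIF expects the task columns to be condition
  regressors (condition vs baseline).  Under any *scaled-orthogonal*
  recoding of the conditions — e.g. replacing correlated regressors $A, B$
  by $A+B$ and $A-B$, which makes the columns orthogonal and drives every
  tVIF to 1 — the cVIF of the correspondingly mapped contrast is exactly
  unchanged, because the effective regressor $x_c$ and the null-space
  signals $Z$ are reconstructed identically.  This is the property that
  makes cVIF informative where tVIF is misleading: the recoding "fixes" the
  tVIFs without changing the true variance of any estimable quantity, and
  cVIF reports that nothing improved.  Under *serial* (Gram–Schmidt)
  orthogonalisation the transformation is not orthogonal; the
  meaning-preserving contrast then targets the same estimable function
  (same numerator) but its effective regressor changes norm, so exact
  invariance is not claimed — and indeed no non-degenerate diagnostic
  computed from $(X, c)$ alone can be invariant under *all* invertible
  reparameterisations.  The package therefore documents, and tests, the
  orthogonal-recoding family.
* **Reduced model.**  The best-case model is `intercept + x_c`, mirroring
  the tVIF reduced model.  A condition-number guard (`kappa > 1e10`)
  separates genuinely singular designs (duplicated columns, empty event
  cells) from floating-point noise.

## The MID schedule emulator

`generate_mid_schedule()` emulates the multi-site developmental MID
protocol: two runs of 50 trials (10 per cue type: Large/Small Win, Neutral,
Small/Large Loss) in uniformly random order, components abutting with no
inter-trial interval.  Per-trial component durations are drawn uniformly on
the protocol ranges — Cue 1.781–2.039 s, Fixation 1.500–3.666 s, Probe
0.172–0.497 s, Feedback 1.473–1.789 s with feedback = 1.950 s − probe —
and trial outcomes are i.i.d. Hit / Too Slow / Too Soon with probabilities
0.57 / 0.36 / 0.07.  Outcome-conditional shifts reproduce the documented
behavioural structure (in expectation: Hit probes +30 ms, Hit fixations
+112 ms, Miss response times +89 ms — midpoints of the reported 26–33,
63–160 and 78–100 ms ranges), applied half up / half down and clipped to
the legal ranges.  Too Soon trials carry a recorded RT only with
probability 0.5, reflecting how the stimulus software logs extra presses.

Choices worth knowing about:

* **i.i.d. outcomes instead of the behavioural staircase.**  The simulation
  only needs the marginal timing structure; `staircase_probe_duration()`
  implements the 60%-accuracy-targeting staircase (adjusting every third
  trial on the last six trials' accuracy) for users who want behaviourally
  coupled schedules.
* **Guaranteed non-empty cells.**  Each schedule is redrawn (probability
  ~1e-5) until every cue type has at least one Hit and one Miss, so the ten
  feedback regressors can never be empty and the saturated design is always
  full rank.
* **Run length** is the last feedback offset rounded up to whole 0.8 s
  scans; a single intercept spans the concatenated runs in
  simulation-style designs, while real-data-style designs can request
  per-run cosine drift blocks instead.
* **What the emulator does not reproduce:** real subjects' empirical trial
  orders, scanner-specific timing corrections, autocorrelated noise, and
  the staircase-induced serial dependence of probe durations.  Tests
  passing on emulated schedules therefore validate the *method*, not any
  particular cohort's data.

Two model builders mirror the specifications under study.  The
**cue-feedback model** uses onset impulses for 5 cue and 10 feedback
(cue × Hit/Miss) regressors, each paired with its temporal derivative — 30
task columns; Fixation, Probe and RT remain unmodelled.  The **saturated
model** gives every component a duration-matched boxcar: 5 Cue + 5 Fixation
+ 3 Probe (Win/Loss/Neutral) + 1 RT (probe onset, RT as duration) + 10
Feedback = 24 columns.  Adding derivatives to the saturated model
(`"saturated_derivs"`, 49 parameters with the intercept) drives half its
parameters past the cVIF-20 flag on emulated schedules — the reason the
saturated specification omits them.

## Regressor construction

Regressors are built at microtime resolution `dt / oversampling`
(default 0.8 s / 50 = 16 ms, fine enough that the ~30 ms behavioural
effects survive discretisation; halving the microtime step changes
regressor values by well under 1% RMS).  Boxcars occupy the half-open
interval $[$onset, onset+duration$)$; impulses carry unit mass at the
onset bin, the limiting boxcar of unit time-integral, so impulse and
boxcar amplitudes stay commensurate.  The canonical HRF is the familiar
two-gamma shape (peak delay 6 s, undershoot delay 16 s, dispersions 1,
peak:undershoot 6:1), normalised to unit sum over its samples — the
convention the true-amplitude calibration below assumes.  The temporal
derivative is the un-normalised forward finite difference of that kernel;
only its column space matters.  Convolution runs in the frequency domain
per run, and runs are concatenated along time.

## The bias / error / power simulation

Truth is always generated from the saturated design: per subject,
$Y = X_{\text{sat}}\beta + \epsilon$, $\epsilon \sim N(0, \sigma_w^2)$,
with every saturated amplitude drawn per subject as
$N(\mu, \sigma_b^2)$, $\sigma_w = 1$, $\sigma_b = 1.5$.  The built-in
scenarios set $\mu$ nonzero for one component at a time — Cue(Win) 0.22,
Fixation(Win) 0.22, Probe(Win) 0.85, RT 0.35, Feedback (Large Win Hit and
Miss) 0.25 — values calibrated so that group-level detection power at 500
subjects is roughly 80%.  Both models are then fitted by OLS to the same
data and seven standard contrasts are tested across subjects with a
two-sided one-sample t at $\alpha = 0.05$.

For a first-level contrast the total (mixed-effects) variance is
$$\sigma^2_{\text{mfx}} = c (X'X)^{-1} c' \, \sigma_w^2 + c c' \, \sigma_b^2,$$
and `mixed_variance()` reports the ratio
$\sqrt{\sigma^2_{\text{mfx}}}/\sqrt{c(X'X)^{-1}c'\sigma_w^2}$; on emulated
designs the condition-difference contrasts fall in the 2.5–4 range, the
regime where between-subject variance dominates.

Summaries follow the display conventions of the study this emulates: cells
whose contrast touches a parameter with nonzero true mean are *signal*
cells (their rejection rate is power); for null cells the rejection rate is
a type I error rate, flagged as inflated by an exact binomial test against
$\alpha$; bias is displayed as the average group t of (estimate − truth),
with $|t| > 1.96$ on average the significance convention.  Independent
noise is not a realistic fMRI assumption, but it leaves the bias structure
untouched and keeps the first-level fit an honest OLS.

Problem sizes: subject schedules are generated once per study and reused
across datasets, as the original timings were.  The package's own
validation runs the full grid at 40 subjects × 300–1000 datasets (the bias
and error-rate properties do not depend on the subject count) and the
power check at the full 500 subjects × 200 datasets.

## Group-level inference

`cluster_permutation_test()` implements one-sample cluster-extent
inference that respects multi-site acquisition.  Subject maps are
thresholded at a two-sided cluster-forming threshold ($|t| > 3.1$ by
default); suprathreshold voxels are labelled by 6-connectivity (face
adjacency only — edge- or corner-touching voxels are distinct clusters),
positive and negative clusters separately.  The null distribution flips
the sign of all subjects within a scanner site jointly — $2^{S}$ patterns
for $S$ sites, fully enumerated up to `max_perms` (13 sites → 8192), else
sampled with the identity retained so $p \ge 1/\#\text{perms}$.  Positive
and negative maxima are pooled into a single max-cluster-size statistic
per permutation (one two-sided null, matching the single 95th-percentile
cutoff); clusters larger than the $1-\alpha$ null quantile are
significant.  Cohen's $d = t/\sqrt{n}$ is attached for display.  Runs are
pooled per subject beforehand with precision-weighted fixed effects
(`fixed_effects_combine()`).

Degenerate inputs are handled explicitly: zero-variance voxels with
nonzero mean produce a capped $\pm$max-double t with a warning; a missing
site label or a non-positive variance is an error.  Because cluster sizes
are integers, the test is conservative on barely-smooth data (ties at the
null quantile); its validation uses spatially smoothed null maps — the
regime cluster-extent inference is designed for — and checks the
family-wise rejection fraction over 200 replicate studies against the
binomial band of the nominal level.

## Known limitations

* cVIF values depend on the condition basis supplied; the package does not
  attempt to recover "the" condition basis from an arbitrary design.
* The emulator's uniform-with-offset duration model matches the reported
  ranges and Hit/Miss mean differences but not any higher moments of the
  real behavioural distributions.
* No AR(1) prewhitening, slice timing, motion regressors or HRF basis
  sets; these are outside the package's scope.
* The simulation's impulse-model estimates are on the impulse-regressor
  scale; bias comparisons across models are therefore made via t
  statistics, not raw amplitudes.
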