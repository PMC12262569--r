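# midvif

Collinearity diagnostics and bias simulation for rapid-event task-fMRI GLM
designs, built around the Monetary Incentive Delay (MID) task as run in
large multi-site developmental cohorts.

## The problem

In a task-fMRI general linear model `Y = Xβ + ε`, adjacent trial components
(Cue → Fixation → Probe → Feedback, with no rest in between) produce heavily
overlapping HRF-convolved regressors.  Researchers respond with model
"repairs" — orthogonalising regressors, dropping temporal derivatives,
replacing duration-matched boxcars with onset impulses, or omitting
components outright.  Some repairs only disguise the problem; others buy
lower variance at the price of biased contrast estimates from unmodelled
neural signal.  `midvif` provides:

* **Design diagnostics.**  Contrast efficiency `1/(c(X'X)⁻¹c')`, the
  traditional VIF (tVIF, per coefficient), and a **contrast-based VIF**
  (cVIF): the variance of `cβ̂` under the full design divided by its
  variance in a best-case model containing only an intercept and the
  contrast's effective regressor `x_c = X c'(cc')⁻¹`.  cVIF reduces to tVIF
  for elementary contrasts, and—unlike tVIF—is unchanged by orthogonal
  recodings of correlated condition regressors that drive every tVIF to 1
  without reducing any true variance.  Working flags at 5 (inspect) and 20
  (excessive).
* **An MID schedule emulator.**  Two runs × 50 trials (10 per cue type),
  components abutting, protocol timing ranges, a 57/36/7% Hit/Too-Slow/
  Too-Soon outcome mix, and outcome-conditional duration/RT differences,
  plus the 60%-accuracy probe-duration staircase.
* **Model builders.**  The impulse-based **cue-feedback** specification (30
  task regressors: 5 cue + 10 feedback, each with a temporal derivative)
  and the **saturated** specification (24 duration-matched boxcar
  regressors: 5 cue + 5 fixation + 3 probe + 1 response-time + 10
  feedback; 49 parameters if derivatives are added).
* **A simulation engine** for bias, type-I error and power: truth generated
  from the saturated design with per-subject amplitudes `N(μ, 1.5²)` and
  scan noise `N(0, 1)`, both models fitted by OLS, seven standard contrasts
  tested across subjects.
* **Group inference.**  Precision-weighted run pooling, voxelwise
  one-sample t maps, Cohen's `d = t/√n`, and a site-stratified sign-flip
  cluster-extent permutation test (two-sided `|t| > 3.1` cluster forming,
  6-connectivity, max-cluster-size null; 13 sites enumerate to 8192
  permutations).

## Worked example

```r
library(midvif)

sched <- generate_mid_schedule(seed = 42)       # 2 runs x 50 trials
d_sat <- mid_design(sched, "saturated")         # 24 task columns + intercept
cons  <- contrast_library(d_sat$column_names)
vif_report(d_sat, cons)
```

```
Contrast collinearity report (cVIF flags: >5 inspect, >20 excessive)
          contrast efficiency  cvif flag
1      Cue:LW-Neut     2.6769 2.856   ok
2      Cue:LL-Neut     2.6534 2.852   ok
3      Cue:LW-Base     2.2826 5.526   >5
4    FB:WHit-WMiss     4.0378 1.288   ok
5    FB:LHit-LMiss     4.9559 1.159   ok
6 FB:LWHit-NeutHit     0.8558 3.615   ok
7    FB:LWHit-Base     0.9982 5.252   >5

Per-column tVIF:
     Cue_LargeWin      Cue_SmallWin       Cue_Neutral     Cue_SmallLoss
            5.526             5.568             5.652             5.612
    ...               (24 task columns; RT lowest at 1.408)
```

Despite the absence of inter-trial intervals, the saturated model's
condition-difference contrasts (the ones the task is used for) show modest
inflation (cVIF 1.2–2.9); only the baseline-referenced feedback contrast
crosses the inspection threshold.  Adding temporal derivatives changes the
picture completely — which is why the saturated specification omits them:

```r
d_der <- mid_design(sched, "saturated_derivs")  # 49 parameters
cvif(d_der, contrast_library(d_der$column_names)[["Cue:LW-Neut"]])
#> [1] 249.8553
```

The simulation engine quantifies what the impulse-based cue-feedback model
pays for its simplicity.  With true signal on the (unmodelled) fixation
component, its feedback-vs-baseline contrast absorbs the leftover signal,
while the saturated model stays unbiased:

```r
scheds <- lapply(1:40, function(s) generate_mid_schedule(seed = 9000 + s))
res <- run_scenarios(sim_scenarios(c("null", "fixation_win")),
                     schedules = scheds,
                     config = sim_config(n_subjects = 40, n_datasets = 300,
                                         seed = 77))
subset(res, scenario == "fixation_win" & contrast == "FB:LWHit-Base")
```

```
     scenario       model      contrast true_value signal mean_estimate  bias_t rejection_rate inflated
 fixation_win cuefeedback FB:LWHit-Base          0  FALSE        0.3326  0.5370         0.0967     TRUE
 fixation_win   saturated FB:LWHit-Base          0  FALSE       -0.0237 -0.0846         0.0333    FALSE
```

`mean_estimate` is the average contrast estimate across datasets (true
value 0), `bias_t` the average group t-statistic of that bias, and
`rejection_rate` the fraction of datasets whose group test rejected at
α = 0.05 — inflated for the cue-feedback model, nominal for the saturated
one.

## Command line

A thin dispatcher over the same functions lives at `inst/cli/midvif.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "midvif.R", package = "midvif"))')" \
    mid-generate --subjects 4 --seed 7 --out events/
# likewise: diagnose --design design.tsv | simulate --scenario null | grouptest --maps dir --sites sites.tsv
```

Every output directory receives a provenance config (command, seed,
package version), and all tables are TSV with a `# seed=` header line.
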