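---
title: "Methods: models, estimators and design choices in statinddi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in statinddi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinddi)
```

## The scientific setting

Ritonavir, given as a low-dose booster with nirmatrelvir for 5 days,
irreversibly (mechanism-based) inactivates CYP3A4 in gut and liver. For a
CYP3A4-cleared statin such as atorvastatin this raises exposure within a
day or two of starting the course and the effect outlasts the course,
because recovery requires de-novo enzyme synthesis. The package analyses
the canonical paired design for quantifying this: a single 10-mg statin
dose at baseline and again on day 5 of ritonavir 100 mg twice daily, with
rich plasma sampling (0–49 h) on both occasions, and it simulates
multi-day dosing schemes to explore dose adjustment.

## Noncompartmental analysis

NCA is deliberately model-free; the only choices are conventions, all of
which are flags:

* **AUC method** — lin-up/log-down trapezoid by default: linear when the
  concentration rises or is flat, the exact exponential-segment integral
  $(C_1 - C_2)\,\Delta t/\ln(C_1/C_2)$ when it falls between two positive
  values, linear as fallback at zero endpoints. Pure linear is available
  via `method = "linear"`.
* **Terminal slope** — log-linear least squares over every contiguous
  terminal subset of at least 3 points strictly after
  $T_\mathrm{max}$, keeping the fit with the highest adjusted $R^2$; ties
  within $10^{-4}$ go to the subset with more points. A fixed window can
  be forced with `selection = "manual"`. $\lambda_z$ must be positive:
  flat or rising tails raise a no-terminal-phase error rather than
  returning a nonsensical half-life.
* **Extrapolated tail** — $AUC_\infty = AUC_\mathrm{last} +
  \hat{C}_\mathrm{last}/\lambda_z$ with the *regression-predicted* last
  concentration by default (`last_pred = FALSE` switches to the observed
  one). The predicted value is less sensitive to a noisy final sample.
* **Ties at the peak** — $T_\mathrm{max}$ takes the earliest time.
* **BLQ handling** (`apply_lloq`) — default zero-before/drop-after: a BLQ
  sample before the first quantifiable one becomes 0 (pre-dose), at or
  after it is excluded. `drop_all` and `half_lloq` implement the other
  common conventions. The source trial reports only that some profiles
  fell below the LLOQ; it does not document its BLQ rule, so this default
  is a convention, not a reproduction.

Derived measures use the standard identities $CL/F =
\mathrm{Dose}/AUC_\infty$ and $V_z/F = (CL/F)/\lambda_z$. Because the
geometric mean commutes with reciprocals and ratios, these identities also
connect the published summary-table entries to each other; the acceptance
tests exploit exactly that (e.g. a 10-mg dose over an AUC of 17.8
h·ng/mL gives 9363 mL/min, matching the printed 9353 mL/min within the
rounding of the printed AUC).

**Molar activity sums.** `total_inhibitory_activity()` implements the
stated definition — the potency-weighted sum of molar AUCs, in h·nmol/L —
with the atorvastatin family equipotent (weight 1) and N-desmethyl
rosuvastatin at 0.5. The published total-activity values (76.5 → 152,
printed as h·mmol/L) cannot be reconstructed from the published per-analyte
geometric means: per-subject sums do not commute with geometric means, and
the printed unit appears inconsistent with the ng/mL concentration scale
by about $10^6$. The operation therefore implements the definition and the
package makes no claim of reproducing those two numbers. Molar masses are
not printed in the source; the shipped analyte table uses standard
reference values (e.g. atorvastatin 558.64 g/mol, rosuvastatin 481.54
g/mol).

## Exposure-change statistics

For paired values the geometric mean ratio is the exponentiated mean of
paired log differences, with a $t_{n-1}$ confidence interval (90% by
bioequivalence convention) and a two-sided paired t-test. Incomplete pairs
are dropped listwise (mirroring per-parameter $n = 7$ entries in the
published tables); single-occasion geometric means use all available
values. If all paired log differences are identical the t statistic is
undefined and the result is flagged `degenerate` rather than given a
fabricated p-value. The ratio–ratio regression (statin AUC ratio vs
midazolam probe ratio) runs on log ratios by default since exposure ratios
are log-normal-ish; the raw scale is a flag.

## The semi-mechanistic interaction model

States: central and peripheral drug amounts plus gut and liver enzyme
pools $E \in (0, 1]$.

$$\frac{dE}{dt} = k_\mathrm{deg}(1 - E) - k_\mathrm{inact}\,R(t)\,E,
\qquad E(0) = 1$$

$R(t)$ is the ritonavir presence: a square wave covering 12 h per dose by
default (continuous coverage under BID dosing), or an exponentially
decaying one-compartment driver (`rito_driver = "onecomp"`). Each statin
dose at time $t_d$ enters the central compartment at a zero-order rate for
duration $D(t_d)$ carrying bioavailability $F(t_d)$:

$$F = \frac{F_\mathrm{rel}}{\theta_F + (1-\theta_F)E_\mathrm{gut}},\qquad
D = D_0\,[1 + (\theta_D - 1)(1 - E_\mathrm{gut})]$$

This mapping is the simplest anchoring consistent with the reported
findings: $E = 1$ gives baseline kinetics, $E = 0$ gives the fitted
full-inhibition factors $1/\theta_F = 1/0.57 = 1.75$ and $\theta_D = 1.71$,
and elimination is unchanged ("no additional effect on elimination") —
clearance modulation through the liver pool is retained as a switch
(`use_cl_modulation`, with its own factor $\theta_{CL}$) precisely so that
model comparison can reject it, as the original analysis did. The exact
turnover equations of the original model live in its online supplement and
are not printed in the main text; the forms above are this package's
committed interpretation.

**Why closed forms instead of an ODE solver.** $F$, $D$ (and optionally
$CL$) are frozen at each dose time, so between doses the disposition
system is linear and time-invariant, and $R(t)$ is piecewise constant.
Both sub-models therefore have exact solutions: the enzyme pool is a chain
of exponential relaxations toward $k_\mathrm{deg}/(k_\mathrm{deg} +
k_\mathrm{inact}R)$, and the plasma model is the standard two-compartment
zero-order-input solution in the disposition eigenvalues $\alpha, \beta$,
superposed over doses. The package implements these closed forms (fast and
exact to machine precision), and the test suite cross-checks them against
an independent adaptive integrator (`deSolve::lsoda`, rtol $10^{-10}$) at
$10^{-6}$ relative tolerance, preserving the dual-route check an adaptive
solver would otherwise provide. The freezing of $F$ and $D$ at the dose
time is itself an assumption; it is accurate because absorption (1–2 h) is
fast relative to enzyme turnover ($1/k_\mathrm{deg} \approx 33$ h).

### Parameters, units and defaults

| parameter | meaning | default | basis |
|---|---|---|---|
| `cl_f_base` | apparent clearance CL/F, L/h | 561 | published baseline 9353 mL/min |
| `vc_f` | central volume Vc/F, L | 3500 | with Q, Vp: baseline Cmax ≈ 2.3 ng/mL |
| `q_f` | inter-compartmental clearance, L/h | 500 | shape of the distribution phase |
| `vp_f` | peripheral volume Vp/F, L | 2420 | fixes β = ln 2 / 9.07 h |
| `d0` | zero-order absorption duration, h | 1.25 | baseline median Tmax |
| `theta_f` | bioavailability denominator at full inhibition | 0.57 | fitted trial value |
| `theta_d` | absorption-duration factor at full inhibition | 1.71 | fitted trial value |
| `k_deg` | enzyme turnover rate, 1/h | 0.03 | ~23 h CYP3A turnover, literature convention |
| `k_inact` | inactivation scale while ritonavir present, 1/h | 0.3 | gut pool < 10% by 24 h of coverage |
| `iiv_omega` | log-normal SDs on F_rel, CL/F, Vc/F | 0.4 each | reproduces the published CI spread within ~2x |
| `sigma_prop` | proportional residual SD | 0.15 | typical bioanalytical + PK noise |

The four disposition parameters were committed once by matching the
published baseline geometric means (AUC via CL/F exactly; Cmax, Tmax and
t½ approximately) and are the virtual trial's definition of "truth", not
quantities re-tuned against any downstream check.

With these defaults the gut pool settles at $k_\mathrm{deg}/(k_\mathrm{deg}
+ k_\mathrm{inact}) \approx 0.09$ under continuous coverage, so the
model's day-5/baseline AUC ratio is ≈ 1.65 — close to, but below, the
full-inhibition ceiling of 1.75. The observed ~4.8-fold increase is *not*
reachable through this bioavailability-plus-duration mapping alone; how
the original fitted model reconciles the 1.75 factor with the observed
fold-change depends on its supplementary parameterisation, which the main
text does not print. `day5_exposure_ratio()` exposes this gap explicitly,
and the scenario acceptance check accordingly degrades to an ordering
bound (every-second-day dosing peaks higher than quarter dosing) rather
than asserting the published 4.8-fold peak.

## Estimation

Full FOCEI mixed-effects estimation (the original analysis used nlmixr2)
is out of scope. Two transparent substitutes are provided:

* `fit_pooled()` — naive-pooled Gaussian likelihood on log concentrations
  (proportional error ≡ additive on the log scale), residual variance
  profiled out, parameters log/logit-transformed to their domains,
  Nelder-Mead start + BFGS polish, numerical-Hessian standard errors. BLQ
  observations are excluded (M1 convention).
* `fit_two_stage()` — per-subject fits of $F_\mathrm{rel}$, CL/F, Vc/F
  with everything else pooled; population values are geometric means and
  the IIV estimate is the SD of per-subject log estimates.

For a design this rich (17 samples per occasion) the pooled estimator
recovers the occasion-contrast parameters $\theta_D$ and $\theta_F$ well
even under 40% IIV, because both occasions of every subject share the same
individual disposition deviations; the IIV instead inflates the apparent
residual and biases the *pooled disposition* parameters (a known property
of naive pooling — visible in the wide SEs on CL/F and Vp/F). The
acceptance experiment therefore targets the modulation factors: 20 seeded
trials, pooled refits, medians within ±15% of the generating 1.71 and
1.75. Model comparison uses $AIC = -2LL + 2(p + 1)$.

## The virtual trial generator

`generate_trial()` emulates the statistical structure the analysis
assumes: per-subject log-normal deviates on $F_\mathrm{rel}$, CL/F and
Vc/F; deterministic model curves per occasion; multiplicative log-normal
residual error ($C \cdot e^{\sigma z}$, the log-normal form of
proportional error, which cannot go negative); LLOQ censoring with BLQ
flags at 0.1 ng/mL (atorvastatin) or 0.05 ng/mL (rosuvastatin). The
generator is bit-reproducible given (config, seed), and per-subject draws
depend only on (seed, subject index).

Rosuvastatin is generated *empirically* (one-compartment, first-order
absorption; the ritonavir occasion multiplies $k_a$ by 9.2 and the
apparent volume by 0.62 with CL/F unchanged), because the original work
fits no mechanistic rosuvastatin model. This reproduces the paired
statistics that matter — AUC unchanged, Cmax roughly doubled, Tmax much
earlier — but deliberately not the observed terminal-half-life behaviour;
rosuvastatin checks are statistics-level only. The paradoxical
poor-function OATP1B1 carrier (exposure *fell* 55% under ritonavir) is
available as an injection (`inject_outlier()`), not as a genetics model:
`mode = "target_ratio"` rescales a subject's ritonavir occasion to a
chosen AUC ratio (default 0.45), `mode = "scale"` is a plain multiplier.

What passing tests on generated data do **not** show about real data: the
generator has no absorption-time variability, no within-day enzyme
fluctuation, no transporter component (the discussion of the original
trial attributes much of the atorvastatin effect to OATP inhibition), and
its IIV/residual magnitudes are assumptions (the original values are in
an unavailable supplement). Parameter-recovery results certify the
estimator against the generator's own truth, nothing more.

## Regimen simulation conventions

Clock conventions are commitments of this package (the source prints
none): statin once daily at hour 0 of each day; ritonavir at hours 0 and
12 of days 1–5; scenario day 1 is the first ritonavir day. A 10-day
full-dose run-in precedes the scenario (~26 terminal half-lives, residual
accumulation < $10^{-6}$, verified at run time by requiring < 1% AUC₂₄
drift across the last two run-in days). Daily Cmax/Cmin/AUC₂₄ are read
off a 0.1-h grid; ratios are against the last run-in day. "Subtherapeutic"
is AUC₂₄ below 50% of baseline — a configurable convention, since the
source uses the word without a number. The interruption scenario resumes
the full dose on day 8, two days after the course ends, matching the
published description; the every-second-day scenario doses days 1, 3, 5, 7
and daily thereafter. The mixed taper encodes the published scheme: full
day 1, half day 2, quarter days 3–6, half days 7–9, full from day 10.
`recommend_dose()` reproduces the published rule exactly: ≤ 10 mg
unchanged; 20 mg half; ≥ 40 mg quarter; reduced until 2 days after
ritonavir ends.

## Numerical and degenerate-input policy

* Closed-form model evaluation throughout; repeated disposition
  eigenvalues (a measure-zero configuration) are nudged by $10^{-9}$
  rather than special-cased.
* Predicted concentrations are floored at $10^{-12}$ ng/mL before taking
  logs in the likelihood; an exactly zero residual sum is floored to keep
  the profiled objective finite on noise-free data.
* All-BLQ profiles, empty datasets, non-positive doses, unmatched pairs,
  zero-variance regressors and single-subject two-stage requests raise
  typed errors rather than propagating NaN.
* Problem sizes used by the shipped checks — 20 recovery seeds, 200
  rosuvastatin cohorts, 1000 coverage nulls, 0.1-h simulation grids —
  were chosen as the smallest sizes at which the corresponding Monte-Carlo
  noise is comfortably below the tolerance being asserted.

## Known limitations

* The estimators are not FOCEI; pooled disposition estimates are biased
  under strong IIV (by design documented, and irrelevant to the
  occasion-contrast factors the package targets).
* The enzyme model has a single inactivation scale per pool and a binary
  presence function by default; no ritonavir accumulation kinetics.
* No transporter (OATP1B1) mechanism, no PBPK organ model, no
  pharmacodynamic (LDL) layer, and no rosuvastatin mechanistic model.
* Observed-data refits of the original trial are impossible — its raw
  concentrations are not deposited — so all estimation claims are
  parameter-recovery claims on synthetic data.
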