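---
title: "Modeling intravesical mitomycin-C chemotherapy for bladder cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intravesical mitomycin-C chemotherapy for bladder cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcdose)
```

## The model

Non-muscle-invasive bladder cancer (NMIBC) is routinely treated by
transurethral resection followed by intravesical instillation of the
chemotherapeutic mitomycin-C (MMC).  `mmcdose` implements a deliberately
compact description of that setting: three coupled ordinary differential
equations for the intravesical drug amount $M(t)$ [µM], the tumor cell
population $T(t)$ and an aggregate effector-cell population $E(t)$
(dendritic cells plus cytotoxic T lymphocytes),

$$
\begin{aligned}
\frac{dM}{dt} &= -\mu_1 M + m,\\
\frac{dT}{dt} &= -T\Big(\frac{p_1 M}{M + a} + p_2 E\Big)
                 + r T\Big(1 - \frac{T}{k}\Big),\\
\frac{dE}{dt} &= d_0 + \gamma\,\frac{p_1 T M}{M + a} - E\,(p_3 T + \mu_2).
\end{aligned}
$$

The drug obeys first-order washout $\mu_1$ against a constant instillation
rate $m$; weekly 2-hour instillations are idealized as a continuous
low-rate source, so $m$ carries units of µM/day and the full protocol dose
is recovered over the course length $\tau$.  The tumor grows
logistically toward a carrying capacity $k$ (interpreted as a no-cure
state), is killed by the drug through a saturating Michaelis–Menten term
with maximum rate $p_1$ and half-saturation $a$, and by effectors through
mass action at rate $p_2$.  Effectors are produced at a constant
homeostatic rate $d_0$, are recruited in proportion to drug-induced tumor
apoptosis (multiplier $\gamma$), and are lost to natural death ($\mu_2$)
and to deactivation by tumor contact ($p_3$).

The model is intentionally non-spatial and treats both cell populations
as homogeneous; regulatory T cells, cancer stem cells and pulsed
(non-continuous) instillation schedules are outside its scope.  One unit
subtlety is inherited from the source material: $\gamma$ is tabulated
with units of day$^{-1}$, which makes the activation term dimensionally a
rate times a flux rather than a pure cell flux.  The package carries
$\gamma$ as a plain numeric multiplier and evaluates the equation exactly
as written; no rescaling is attempted.

### Parameters

`mmc_params()` holds the eleven constants.  Point estimates are the
published ones (e.g. $\mu_1 = 21.05$/day from urinary pharmacokinetics,
giving a 47.4-minute half-life; $m = 6.561$ µM/day, the 40 mg/50 ml
protocol dose spread over $\tau = 365$ days; $d_0 = 1.032\times 10^5$
cells/day).  Five parameters are published only as biologically feasible
ranges; the package defaults to range midpoints and exposes the ranges
through `mmc_param_ranges()`:

| parameter | range | default (midpoint) |
|---|---|---|
| $r$ [1/day] | 0.01–0.045 | 0.0275 |
| $k$ [cells] | 0.9e8–1e9 | 5.45e8 |
| $p_1$ [1/day] | 0.12–0.2 | 0.16 |
| $p_2$ [1/(cells·day)] | 3.7e-6–5.5e-6 | 4.6e-6 |
| $p_3$ [1/(cells·day)] | 1.1e-6–1.59e-6 | 1.345e-6 |

Every default can be overridden programmatically or through YAML/JSON
configuration files (`read_params()`, `load_config()`).

## Equilibria and the cure criteria

Two quantities organize the whole analysis:

* $I_1 = p_2 d_0 / \mu_2$ — the net daily tumor-kill intensity of the
  immune system (`immune_intensity()`);
* $I_2 = p_1 (m/\mu_1) / (m/\mu_1 + a)$ — the net daily kill intensity of
  the drug at its residual equilibrium level $m/\mu_1$
  (`chemo_intensity()`); $I_2 < p_1$ for every $m$.

Without treatment the disease-free state is $(0, 0, d_0/\mu_2)$ with
Jacobian eigenvalues $(-\mu_1,\; r - I_1,\; -\mu_2)$: homeostasis is
locally stable iff $r < I_1$.  Under treatment the tumor-free state is
$(m/\mu_1, 0, d_0/\mu_2)$ with eigenvalues
$(-\mu_1,\; r - I_1 - I_2,\; -\mu_2)$: cure is locally stable iff
$r < I_1 + I_2$.  `disease_free_equilibria()` returns these closed forms;
`find_cancer_equilibria()` obtains interior equilibria by clearing
denominators of the nullcline condition, which leaves a quadratic in $T$
(hence at most two interior points), and evaluates their stability from
numeric Jacobian eigenvalues.  "Stable" always means strict negativity of
all real parts; an eigenvalue within rounding of zero is reported
non-stable with a `marginal` flag, since the linearization is
inconclusive there.

## Simulation and the initial-size threshold

`integrate_model()` uses the Dormand–Prince 5(4) adaptive Runge–Kutta
pair (deSolve's `"ode45"`), with the right-hand side compiled in C for
speed; the pure-R `mmc_rhs()` is retained as a reference implementation
and the two paths agree to solver tolerance.  Numerical choices worth
stating:

* relative tolerance `1e-8`; absolute tolerance is component-wise,
  `c(1e-12, 1e-6, 1e-6)` for $(M, T, E)$ — the drug lives on the 0.1–1 µM
  scale while the cell counts live on 1e4–1e9, and a cell-scale absolute
  tolerance applied to $M$ would leave an absolute error floor of order
  1e-7 µM, visible against the exact exponential solution of the drug
  equation;
* maximum internal step of 1 day, which keeps the interpolated (dense)
  output accurate between widely spaced steps once transients have died;
* up to 5e5 internal steps — washout rates up to twice the published
  value make some sampled systems moderately stiff.

Because the drug equation is linear and decoupled, $M(t)$ has the exact
solution $m/\mu_1 + (M_0 - m/\mu_1)e^{-\mu_1 t}$ (`drug_closed_form()`),
which the test-suite uses as a continuous accuracy oracle.

`classify_outcome()` calls a run a cure iff the final tumor count is
strictly below the cure threshold (default 1 cell; a tie counts as
persistence).  `find_initial_size_threshold()` locates the basin
boundary — the critical initial tumor count $T_0^*$ separating
elimination from persistence — by bisection on $\log_{10} T_0$ to a
default relative width of 1%, enough to resolve a threshold to three
significant figures.  The threshold-finder's default classification
horizon is 2000 days rather than the 400 days used for illustrative
trajectories: near the tumor-free state the slow eigenvalue is
$r - I_1 - I_2$, which for midpoint parameters gives decay on a 40-day
time scale, so a sub-basin trajectory started at a few million cells is
still at 1e2–1e4 cells on day 400 and needs the longer horizon to cross a
1-cell threshold.  The answer is an asymptotic (basin) property and is
insensitive to the horizon once decay completes.

With midpoint defaults the untreated threshold is ≈6.2×10⁶ cells
(≈16 mm diameter) and the treated one ≈1.65×10⁷ cells (≈24 mm): the
treated basin strictly contains the untreated one, and the treated
threshold coincides with the unstable interior equilibrium (a saddle),
as phase-plane reasoning predicts.  Threshold values move with the
within-range parameter choice — they are patient-condition-specific, not
universal constants.

## Tumor geometry and dose arithmetic

Tumor size enters clinical reasoning as a diameter, the model as a cell
count.  `cells_from_diameter()` uses a thin-disc geometry: a circular
patch of the urothelium three cell layers deep (cell length ≈10 µm) at
1e6 cells/mm³, so $\#\text{cells} = \pi (d/2)^2 \times 3\times10^{-2}
\times 10^6$.  Both depth and density are configurable.  The size classes
then map to 15 mm ↔ 5.3×10⁶ cells and 20.6 mm ↔ 1×10⁷ cells.  The
"large" class pair 6.62×10⁷ cells ↔ 26.5 mm is only consistent with the
formula if 26.5 mm is read as a radius; the API therefore exposes
explicit `cells_from_diameter()` / `cells_from_radius()` entry points
rather than guessing.

`dose_to_molar()`, `molar_to_rate()`, `rate_to_course_mg()` and
`half_life_minutes()` implement the unit chain 40 mg / 50 ml / 334 g/mol
→ 2,395 µM → 6.561 µM/day (over $\tau = 365$ days) → back to 40 mg, and
$t_{1/2} = \ln 2/\mu_1$.

## Personalized dose determination

Solving the cure criterion $r < I_1 + I_2(m)$ for $m$ yields a
patient-specific dose rule.  `eligibility_window()` and `dose_bound()`
ship two algebraic variants:

* **printed** (default): window $(I_1,\, I_1 + p_1/\mu_1)$ and bound
  $m^* = \mu_1 a (I_1 - r)/(r - I_1 - p_1/\mu_1)$ — the published form,
  and the one used for the cohort experiment;
* **rederived**: window $(I_1,\, I_1 + p_1)$ and bound with $p_1$ in
  place of $p_1/\mu_1$.  This is the exact algebraic boundary of the
  stability criterion: substituting $m^*$ back gives
  $I_1 + I_2(m^*) = r$ identically, and since $I_2$ increases with $m$,
  stability holds for instillation rates *above* this value — it is a
  lower bound on curative dosing, whereas the printed variant is framed
  as an upper bound.  Both interpretations are kept, clearly labelled,
  because they answer slightly different questions; the package does not
  silently pick one algebra over the other.

`recommend_dose()` wraps the rule into a classifier: growth rates outside
the window (or bounds below `min_mg`, default 1 mg — a value the source
material leaves unquantified) are `non_responder`; bounds above the
recommended maximum (default 40 mg, the standard protocol) are
`over_toxicity_capped`, with the cap reported as the usable dose;
everything else is `eligible`.

`cohort_experiment()` reproduces the virtual trial design: each of $n$
hypothetical patients receives ranged parameters drawn uniformly within
their feasible ranges (point estimates held fixed — the sampling law is a
package choice, as none is published), a growth rate drawn uniformly
inside the patient's own eligibility window (which enforces $I_1 < r$ by
construction), and a dose recommendation.  All draws flow through one
seeded generator, so the cohort is reproducible from `(seed, n)` alone.
At the published scale of 2,000 patients, almost all printed-variant
bounds exceed 40 mg, i.e. the recommended clinical range sits inside the
curative range for these parameter ranges.

## Global sensitivity

`run_sensitivity()` follows the standard LHS/PRCC design: Latin
hypercube samples (via the `lhs` package) of all eleven parameters over
half-to-double their baseline values, the model integrated to day 365
under treatment (the day at which the cumulative continuous dose equals
one protocol instillation), and partial rank correlation coefficients of
the final tumor count computed by explicit residualization: rank
everything, regress each parameter's ranks and the output's ranks on all
other parameters' ranks, and correlate the residuals.  P-values come from
the t-statistic on $n - 2 - (d-1)$ degrees of freedom, with significance
declared at $\alpha = 0.01$.  The test-suite cross-checks the
implementation against the inverse-correlation-matrix (precision-matrix)
formulation of partial correlation.

The initial burden for sensitivity runs defaults to the "medium" tumor
(1e7 cells) with homeostatic effectors `d0/mu2` recomputed per sampled
parameter set.  At $n = 1000$ the sign pattern is stable across seeds:
the anti-tumor sources and rates ($m$, $d_0$, $p_1$, $p_2$, $\gamma$)
correlate negatively with tumor burden, the pro-tumor ones ($r$, $p_3$,
$\mu_2$, $\mu_1$) positively, and $p_2$, $r$, $d_0$ dominate in
magnitude.  `uncertainty_sweep()` complements PRCC with a full-factorial
sweep, intended for the two weakly constrained constants $\mu_1$ and $a$;
tumor burden at the read-out never decreases as $a$ grows (weaker drug
kill).

## What the synthetic experiments do and do not show

All experiments in the package are *in silico*: parameter draws emulate
between-patient biological variability within literature-derived ranges,
not measured patients.  They exercise internal consistency of the model
— stability criteria versus simulated dynamics, dose algebra versus its
defining identities, sampling design versus its stratification
guarantees — and qualitative agreement with clinical observation (size
thresholds for cure, treatment enlarging the curable range).  Passing
them says nothing about predictive accuracy in real patients: growth
rates, immune kill rates and drug kill saturation are not currently
measurable in vivo, tumors are spatially structured, instillation is
pulsed rather than continuous, and immune regulation (Tregs, stem cells)
is absent from the model.  Reported basin thresholds are therefore
demonstrations of the method, not clinical cutoffs.

## Problem sizes

Default experiment sizes mirror the published designs: 1000 LHS samples
for PRCC, 2000 virtual patients, 400-day illustrative simulations,
day-365 sensitivity read-out.  Unit tests use smaller replicas (30–500)
of the same designs where the property under test does not depend on
scale; the acceptance-level checks run the full sizes.
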