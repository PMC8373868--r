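---
title: "A multiscale model of tumor-immune-EMT dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of tumor-immune-EMT dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasim)
```

## The model

`invasim` simulates the progression of a carcinoma from an in situ tumor to
invasive disease, coupling three scales:

1. **Tumor cells** are discrete agents. Each carries three boolean pathway
   mutations — proliferation ($\delta_P$), apoptosis ($\delta_A$), immune
   evasion ($\delta_{IE}$) — a continuous EMT score in $[0,1]$, a mesenchymal
   phenotype flag $\zeta$, and a cell-autonomous mutation probability.
   Populations are scaled: a tumor of order $10^9$ cells is represented at
   order $10^2$, and rate constants are scaled to match.
2. **Immune populations** — natural killer (NK) cells, cytotoxic T
   lymphocytes (CTLs), regulatory T cells (Tregs) — are continuous
   variables obeying linear ODEs, with recruitment of the adaptive
   compartments driven by immune-cleared mutant cells and (for Tregs)
   TGF-$\beta$.
3. **TGF-$\beta$** is an algebraic quantity,
   $\tau = \tau_{MUT} N_{MUT} + \tau_{Treg} N_{Treg}$, sourced by mutant
   tumor cells and, more strongly, by Tregs.

Each cell cycle (18 h) every tumor cell draws one fate from

$$\rho_P = p\,(1+\delta_P\Delta_P)(1-\zeta\Delta_{MGA})\frac{1}{1+N_C/K_0},
\qquad \rho_A = d_C\,(1-\delta_A\Delta_A),$$

$$\rho_{NK} = \delta_{MUT}\,
 \frac{N_{NK}}{N_C/K_1+N_{NK}}\,
 \frac{E_{NK}}{1+N_{Treg}/K_2}\,
 (1-\delta_{IE}\Delta_{IE})(1-\zeta\Delta_{MIE}),$$

with CTL clearance of the same form using $N_{CTL}$ and $E_{CTL}$, and
$\rho_R = 1 - (\rho_P+\rho_A+\rho_{NK}+\rho_{CTL})$ the probability of
resting in $G_0$. $\delta_{MUT}$ is 1 for any mutated cell and
`delta_MUT_baseline` (default 0) otherwise: mutated cells are immunogenic.
Mesenchymal cells proliferate less (growth arrest, MGA) and evade clearance
(immune evasion, MIE); $\Delta_{MIE}=1$ is complete evasion.

A simulation runs a **warmup** of 1000 cycles (no mutations, NK only,
inflammation held at its start state) during which the tumor grows to the
mean-field carrying capacity $N^* = K_0\,(p/d_C-1)$, then a **main phase**
in which mutation is enabled and the adaptive compartments respond. The
tumor has *progressed* when the fraction of cells carrying at least one
mutation reaches 50%; the patient-level summary is the **time to
invasion**, right-censored at 2000 post-warmup cycles.

## Design choices where the design was open

**Rest as the complement.** Treating the four active fates plus rest as a
probability vector requires $\rho_R$ to be the complement of the other
four; we clamp it at 0 and rescale the active four proportionally in the
(parameter-pathological) case their sum exceeds 1. Proliferation mass
suppressed by growth arrest thereby flows into rest, preserving the
semantics of $G_0$.

**CTL clearance.** CTLs clear like NK cells but with their own efficacy
$E_{CTL} > E_{NK}$ (they are the more efficient effector), reusing the
saturation constants $K_1$, $K_2$. Both are suppressed by Tregs.

**Within-cycle ordering.** Fates are drawn synchronously against
cycle-start populations, then applied; daughters are not exposed to fate
draws until the next cycle. Immune exhaustion (one effector removed per
kill, attributed to the clearing compartment) is applied before the
population update. Each immune compartment is then advanced by the *exact*
solution $N(1) = a/d + (N_0-a/d)e^{-d}$ of its linear ODE with forcing
(cleared-mutant count $N^*_{MUT}$, TGF-$\beta$, inflammation-resolved
recruitment rates) frozen at cycle-start values. This matches the per-cycle
update granularity of the simulation loop and removes integrator tolerance
as a hidden parameter; the test suite verifies agreement with adaptive
fine-step integration to $10^{-8}$ relative error. $N^*_{MUT}$ is the
count of mutant cells cleared *this* cycle (a rate forcing, not a
cumulative count). TGF-$\beta$ is recomputed algebraically after the
population update, and EMT scores are updated last.

**EMT score update.** The score responds to TGF-$\beta$ through a
saturating gain and linear decay,
$s' = \mathrm{clamp}_{[0,1]}\!\big(s + g\,(1-s) - \lambda s\big)$ with
$g = \texttt{emt\_gain}\cdot\tau/(\tau+K_\tau)$ and
$\lambda = \texttt{emt\_decay}$. Under constant $\tau$ the score converges
to $g/(g+\lambda)$; the phenotype switch is strict
($\zeta \iff s > T_{MES}$), so a score sitting exactly at the threshold is
epithelial. This functional form is the package's own parameterization of
"EMT score driven by TGF-$\beta$, decaying without stimulus"; partial or
intermediate EMT states are deliberately out of scope.

**Mutation machinery.** A proliferating cell mutates with its
cell-autonomous probability; on mutation exactly one not-yet-mutated
pathway is chosen uniformly and the probability resets to 0, otherwise it
grows by the fixed increment $10^{-4}$. A mutation acquired at division is
clonal (parent and daughter both carry it). Daughters inherit the parent's
full state *including* the post-division mutation probability. The
inheritance choice is load-bearing: if daughters restarted at 0, the mean
mutation probability would be stationary at roughly one increment (a cell
at carrying capacity proliferates about once per lifetime), pinning the
population mutation supply at $N\rho_P \cdot 10^{-4} \approx 2\times10^{-3}$
per cycle — far too small for any tumor to progress within the 2000-cycle
horizon. With inheritance the probability counts non-mutating
proliferations along the ancestral lineage, the supply grows linearly in
time, and simulations show the characteristic quiet phase of a few hundred
cycles in which early mutants are cleared, followed by escape — the
dynamics the model is meant to produce. Mutation accrual is disabled
during warmup ("no mutations occur"), so the main phase starts with all
probabilities at 0.

**Inflammation.** The inflammatory state follows a deterministic schedule:
constant low, constant high, or cycling with half-open blocks of `ild` LOW
cycles and `ihd` HIGH cycles. Only the CTL and Treg recruitment rates are
state-paired (`sigma_CTL_low/high`, `sigma_Treg_low/high`); all other
parameters are state-independent.

## The calibrated default parameter set

No reference value table ships with the model, so the package provides its
own calibrated defaults (units: probabilities per 18 h cycle; populations
in scaled cells). The calibration targets, re-checked by
`scripts/calibrate.R`, are:

- warmup carrying capacity of order $10^2$:
  $N^* = K_0 (p/d_C - 1) = 100\,(0.3/0.1 - 1) = 200$ cells;
- nontrivial progression: under cycling inflammation, invasion times spread
  over roughly 400–1800 cycles with only a small censored fraction;
- the mesenchymal directional effects: restricted mean invasion-free
  survival decreasing in $\Delta_{MIE}$ over $\{0.2, 0.5, 0.8\}$, and an
  interior optimum in $\Delta_{MGA}$ on $[0, 0.4]$ under cycling
  inflammation. The first is met robustly; the second is not attainable in
  this model formulation — see *Known limitations* below.

The escape dynamics under these defaults are worth stating explicitly,
because they explain the parameter choices. A fresh mutant faces NK
pressure ($E_{NK} = 0.2$, saturating in tumor load via $K_1$) that exceeds
any single mutation's growth advantage, so early mutant clones are cleared
— except immune-evasion mutants ($\Delta_{IE} = 0.95$), which are nearly
neutral and drift. Escape requires a second hit (typically
$\delta_A$ on a $\delta_{IE}$ background) whose arrival rate grows with
the inherited mutation probability; the resulting invasion times are
stochastic with the right order of magnitude (hundreds of cycles,
~750 days at 18 h/cycle). As the mutant burden grows, TGF-$\beta$
($\tau_{MUT} = 0.05$ per mutant cell, $K_\tau = 2$) pushes the shared EMT
score over $T_{MES} = 0.5$, making the late phase mesenchymal — this is
the window where $\Delta_{MIE}$ (evasion, accelerating invasion) and
$\Delta_{MGA}$ (growth arrest, delaying it) act. Treg feedback
($\tau_{Treg} = 0.2$,
recruitment saturating in $\tau$ via $K_4$) suppresses cytotoxicity
through $K_2$ late in progression.

Because every cell experiences the same TGF-$\beta$ concentration and
daughters inherit the parent's EMT score, the deterministic score update
keeps the population synchronized: the tumor is entirely epithelial or
entirely mesenchymal at any one time, switching as $\tau$ crosses the
threshold region. Per-cell EMT heterogeneity would require cell-intrinsic
noise or asymmetric division, both outside the present scope.

## Cohort statistics

Invasion-free survival is summarized by the Kaplan–Meier product-limit
estimator with right censoring (ties grouped; censored subjects leave the
risk set after the events at their time). "Average time to invasion" is
the **restricted mean survival time** (RMST): the area under the KM step
function up to the 2000-cycle horizon. It is preferred over the mean of
uncensored times (also available, `mean_uncensored()`) because it handles
censored patients; a patient censored exactly at the horizon contributes
to risk sets but not events there. Cohorts are compared with the standard
two-group log-rank test (1 df). All three are implemented in the package
and cross-checked in the test suite against the `survival` package to
$10^{-10}$ on random small datasets.

## Sensitivity analysis

Morris one-step-at-a-time elementary effects over 31 tunable parameters
(the substantive model parameters; run-control settings are fixed).
Parameters with an anchor estimate $m_e$ get a truncated-normal prior
$N(m_e, 2m_e)$ on their valid range — the variance is twice the estimate
so sampling does not lean too heavily on prior values — with unbounded
tails clipped at the 1st/99th percentile so the unit interval maps to a
finite range; phenotype parameters with no prior information
($\Delta$-effects, efficacies, $T_{MES}$) are uniform on $[0,1]$.

The design uses $r = 30$ base trajectories by default (at least 10 is the
usual recommendation) on a 4-level grid with step
$\Delta = \ell/(2(\ell-1)) = 2/3$; each trajectory visits $k+1$ points
differing in one coordinate at a time. Elementary effects are computed in
normalized (unit-cube) coordinates, so $\mu^*$ — the mean absolute effect —
is the average absolute change of the output over each parameter's range
of variation; $\sigma$ is the effect standard deviation. The output
statistic is the cohort RMST (the area under the survival curve), with the
uncensored mean as an alternative. Design points share per-patient seed
streams (common random numbers), which removes Monte-Carlo noise from the
elementary effects of inert parameters entirely and reduces it elsewhere;
an explicitly inert `dummy` parameter can be included to benchmark the
remaining noise floor.

## Reproducibility and numerical conventions

- `(parameters, scheme, seed)` fully determine every output; per-patient
  seeds derive from the master seed by a fixed documented draw, so cohorts
  are independent of execution order.
- Warmup uses a count-based fast path: all cells are statistically
  identical there (no mutations, shared EMT score, zero TGF-$\beta$), so
  per-cycle fates are drawn as one multinomial over the population count —
  distributionally identical to per-cell draws and much faster.
- Probabilities are conserved to $10^{-12}$; immune populations and the
  EMT score are floored/clamped to their ranges; progression uses $\geq$
  at the threshold, the EMT phenotype switch uses strict $>$.
- Times in cycles convert to days as `cycles * 18 / 24`, rounded to the
  nearest day in summaries (841 cycles → 631 days).

## Known limitations

**No interior optimum in growth arrest.** The restricted-mean survival
response to $\Delta_{MGA}$ is monotone non-decreasing over all of $[0,1]$
in this model (measured on 80–200-patient cohorts across several seeds;
differences between nearby $\Delta_{MGA}$ values are within Monte-Carlo
error). The reason is structural: progression is a mutant-*fraction*
threshold in a well-mixed tumor whose cells share one synchronized EMT
state, so growth arrest multiplies mutant and non-mutant proliferation
identically and cancels from the fraction dynamics at first order; for
death-advantage escape clones the within-window differential is
MGA-independent, and the crowding term re-equilibrates the population at
the lower mesenchymal carrying capacity. Every remaining channel (reduced
mutation supply, weaker TGF-$\beta$ feedback, shorter mesenchymal windows,
extinction) favors the patient, so more arrest never shortens survival
here. A non-monotone growth-arrest effect would require per-cell EMT
heterogeneity (stochastic or locally driven EMT, or asymmetric division)
or spatial structure, both outside the present scope. The corresponding
cohort check in the test suite asserts the interior optimum and is
expected to fail; it is kept as an explicit record of this limitation.

**Synchronized EMT.** Because all cells see the same TGF-$\beta$ and
daughters inherit the parent's score, the tumor's mesenchymal proportion
is effectively 0 or 1 at any time rather than a smooth mixture.

## What the simulated cohorts do and do not show

The generator emulates idealized, well-mixed in-silico patients: known
tumor onset, no treatment, no spatial structure, EMT driven solely by
TGF-$\beta$, inflammation exogenous and strictly periodic. Cohort-level
conclusions (such as the monotone MIE effect) are statements about this
model, demonstrated on cohorts of 200 patients in the test suite (scaled
down from the 1000-patient cohorts used for production figures, with
correspondingly wider Monte-Carlo error); they are not evidence about
clinical populations. Extinction of the simulated tumor is possible at
small `N_0` and is reported as a flagged, censored record rather than an
error.

## Worked example

```{r example, eval = FALSE}
pars <- model_params()
scheme <- inflammation_scheme("CYCLING", ihd = 50, ild = 100)
cohort <- simulate_cohort(pars, scheme, n_patients = 200, master_seed = 1)
glance(cohort)
km <- km_estimate(cohort_surv_data(cohort))
restricted_mean(km, horizon = pars$max_cycles)
autoplot(km)
```
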