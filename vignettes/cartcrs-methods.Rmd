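---
title: "Modelling CAR-T cell therapy and macrophage-mediated cytokine release with cartcrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CAR-T cell therapy and macrophage-mediated cytokine release with cartcrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartcrs)
library(dplyr)
```

## The model

`cartcrs` implements a three-layer ordinary-differential-equation model of
chimeric antigen receptor (CAR) T-cell therapy in haematological
malignancies.

**Layer 1 — CAR-T phenotypes and antigen-positive tumour.** Infused
(injected) CAR-T cells $C_I$ either die and redistribute at rate $\mu_I$
or are activated into proliferating *expander* cells $C_E$ at rate
$\eta F(T_P)$, where

$$F(T_P) = \frac{T_P}{A + T_P}$$

is the Michaelis–Menten antigen-recognition fraction with half-saturation
$A$ (a proxy for the antigen density of the tumour).  Expanders
proliferate at $\kappa F$, die or exhaust at $\mu_E$, convert to
long-lived low-cytotoxicity *persister* (memory) cells at
$\epsilon(1 - F)$, and persisters reactivate at $\theta F$ and decay at
$\mu_P$.  Antigen-positive tumour cells $T_P$ grow logistically (rate
$\rho$, carrying capacity $K$) and are killed by expanders with a
Holling type-II response $\gamma\,C_E / (B + C_E)$, where $B$ reflects
CAR receptor density.

**Layer 2 — antigen-negative escape.** An antigen-negative clone $T_N$
shares the logistic crowding term $1 - (T_P + T_N)/K$, contributes
nothing to antigen signalling, and is killed only at the residual
fraction $g_0 \in [0, 1]$ (bystander effect and endogenous TCR).

**Layer 3 — macrophages and IL-6.** Naive macrophages $M_i$ (production
$\sigma_M$, death $\delta_M$) are activated at per-capita rate

$$h = \underbrace{\beta_K \frac{C_E}{B + C_E}(T_P + g_0 T_N)}_{\text{DAMP
release by killed tumour}} +
\underbrace{\beta_B F(T_P)\, C_E}_{\text{antigen-binding signalling}} +
\underbrace{\beta_C \frac{M_a}{C + M_a} C_E}_{\text{CD40--CD40L
contact}},$$

activated macrophages $M_a$ die at the same $\delta_M$, and IL-6 obeys
$\dot{IL6} = \sigma_I + \alpha M_a - \delta_I\, IL6$.  The CD40 term is
a positive feedback: it needs previously activated macrophages, so it
can amplify but never initiate cytokine release.

Units are days, absolute cell counts in a 5 L blood compartment, and
ng/L for IL-6.  Clinical reporting conventions are converted exactly:
1 transgene copy/µg DNA = 10⁴ cells, 1 cell/µL peripheral blood =
5×10⁶ cells, 1 cell/µL bone marrow = 5×10⁸ cells (1% peripheral
fraction), and %blasts × WBC = tumour cells with WBC defaulting to the
mean 4.25×10¹⁰ of the 2.0–6.5×10¹⁰ range.

Two parameters are universal constants rather than patient-specific:
$K = 4.25\times10^{12}$ cells and $\theta = 10^{-8}$/day; the CD40
half-saturation is fixed at $C = 10^{10}$ cells, inside the plausible
range of the naive macrophage pool.

### The below-one-cell rule

To prevent artificial regrowth of practically extinct populations,
proliferation and growth terms of $C_E$, $T_P$ and $T_N$ are switched
off when that population drops below one cell; death, killing and
transition terms are unaffected, so the rule is reversible if influx
repopulates the compartment.  Numerically the switch is a linear ramp
on $[0.5, 1]$ cells rather than a hard indicator: a discontinuous
right-hand side makes the adaptive stiff integrator fail near upward
crossings, while the ramp preserves both stated properties (zero growth
at half a cell, full growth at one cell) and keeps the vector field
continuous.

### Integration

The full system (plus the activation-source sub-populations and their
cumulative integrals, see below) is integrated with the
stiffness-switching `lsoda` solver through a compiled right-hand side;
populations span roughly twelve orders of magnitude, so the defaults
are `rtol = 1e-8` with absolute tolerances of 1e-6 cells and 1e-8 ng/L.
Infusion events and blocking-window edges are hard integration restarts
with state jumps — no delta functions are smuggled into the
right-hand side.  Dense output uses a 0.05-day grid by default so peak
days are resolved well below the 1-day scale at which they are
reported.  Fitting loops relax to `rtol = 1e-6`, evaluate only at
observation times, and cap the solver step budget so that pathological
parameter draws fail fast instead of stalling the optimiser.

## Phase analysis

```{r phases}
p <- cart_params(eta = 0.2, mu_I = 0.6, kappa = 1.2, mu_E = 0.3,
                 epsilon = 0.05, mu_P = 0.01, rho = 0.15, gamma = 1.5,
                 A = 1e7, B = 1e7)
traj <- simulate_therapy(p, init = model_state(T_P = 2e10),
                         regimen = dose_regimen(0, 1e8), horizon = 90)
segment_phases(traj)
```

On a log scale each response phase is approximately exponential, and
its extremal log-slope estimates one mechanistic quantity:
distribution $\to -\mu_I$, expansion $\to \kappa - \mu_E$, contraction
$\to -\mu_E$, persistence $\to -\mu_P$ for CAR-T cells; transient
$\to \rho$, shrinkage $\to \rho - \gamma$, response (relapse regrowth)
$\to \rho$ for the tumour.  On model solutions the slope is computed
analytically from the right-hand side; on sampled data it is the
extremal finite difference of $\log y$ between consecutive points.

Segmentation is automated with a reproducible rule: the distribution
phase ends at the first local minimum of total CAR-T cells within five
days; expansion ends at the global peak; the contraction/persistence
change-point is the first time after the most negative post-peak slope
at which the slope rises above half of it.  Automating this boundary is
a design choice — a manual per-patient choice of endpoints is not
reproducible — and the half-of-minimum threshold marks the switch from
fast expander-driven decay to slow persister-driven decay.

`slope_parameter_map()` inverts the analysis into an initial parameter
estimate: slopes give $\mu_I, \kappa, \mu_E, \mu_P, \rho, \gamma$;
$\eta$ is found by 1-D search so the simulated post-distribution
minimum matches the observed one; $(A, B)$ by a bounded log-grid search
matching the CAR-T peak and minimum tumour burden (when the observed
tumour minimum is censoring-limited it is treated as an upper bound,
not a target); $\epsilon$ by matching the persister level.

## Two-step parameter estimation

Layer 1 (CAR-T and tumour equations) is independent of the cytokine
layer, so fitting the ten patient-specific layer-1 parameters first and
the eight cytokine parameters second is equivalent to a joint fit —
the package exploits this and the test suite asserts it.

**Layer 1** (`fit_cart_layer()`): the objective is the weighted least
squares prescribed for the problem — squared residuals of each series
divided by the square of that series' maximum observed value, with
below-detection points (CAR-T under 2.5×10⁵ cells, tumour at ≈0
%blasts) excluded.  Because that weighting gives persistence-phase
points ~10⁻⁶ of the peak's leverage, the optimiser would be blind to
$\mu_P$, $\epsilon$ and the late dynamics if it used the WLS surface
alone.  The search is therefore staged: a slope-informed start;
bounds on the slope-pinned rates narrowed to a factor 2.5 around their
slope estimates (the stepwise rationale: slopes first, then shape
features); alternating Nelder–Mead rounds on a mean-squared-log
objective, first over the shape parameters
($\eta, \epsilon, A, B$, plus $g_0, T_N(0)$ for antigen-negative
relapse) and then over all free parameters, until the improvement is
under 2%; and a final polish on the reported WLS objective.  Bounds
are enforced with a logistic transform on the log scale, so plain
Nelder–Mead never leaves the box.

**Layer 2** (`fit_cytokine_layer()`): following the fixing rules,
$M_a(0) = 0$, $IL6(0)$ is the first observed value,
$\sigma_I = \delta_I \min_i IL6_i$ (the endogenous steady state is a
floor for the observed minimum), and $C = 10^{10}$ cells.  The eight
remaining parameters ($\sigma_M, \delta_M, \delta_I, \alpha, \beta_B,
\beta_K, \beta_C, M_i(0)$) are sampled log-uniformly (the bounds span
orders of magnitude) for 10⁴ Monte-Carlo tuples, scored by
$LR = \ln \sum_i w_i (IL6(t_i) - IL6_i)^2$ with peak-emphasising
weights $w_i = w_0 + (1 - w_0) IL6_i / \max_j IL6_j$ and $w_0 = 0.15$;
the best 100 tuples are refined with bounded Nelder–Mead, and the
winner receives a restarted polish (rebuilding the simplex at the
incumbent escapes the long degenerate valleys typical of this
landscape).  During this search the cytokine layer alone is
integrated, driven by the fixed layer-1 solution as interpolated
forcings on a 0.25-day grid — exact up to interpolation because of the
layer independence, and an order of magnitude cheaper than re-solving
the full system.  All randomness flows from one seed; the same seed
reproduces the fit bit-identically.

A perfect IL-6 fit would make $LR = -\infty$; the implementation
returns the log of the smallest representable double as a flagged
sentinel instead.

## Macrophage activation sources

Splitting $M_a$ by activation source gives three linear sub-population
equations $\dot M_{a,j} = h_j M_i - \delta_M M_{a,j}$.  These, plus the
cumulative activation integrals $\int_0^{t_F} h_j M_i\,dt$, are
integrated as augmented states of the full system rather than
post-hoc, so the identity $\sum_j M_{a,j} = M_a$ holds to solver
tolerance and the integrals involve no quadrature error.  The default
$t_F$ is the simulation horizon.

```{r decomposition}
q <- cytokine_params(sigma_M = 1e9, delta_M = 0.3, sigma_I = 20,
                     delta_I = 4, alpha = 5e-7, beta_B = 2e-11,
                     beta_K = 5e-11, beta_C = 1e-8)
full <- simulate_therapy(p, q, model_state(T_P = 2e10, M_i = 1e10,
                                           IL6 = 5),
                         dose_regimen(0, 1e8), horizon = 60)
decompose_activation(full)$summary
```

With a CD40-dominant parameter structure the three sources peak in
sequence — DAMP-driven activation during tumour shrinkage, antigen-
driven activation alongside CAR-T expansion, CD40-driven activation
last — and CD40 contact accounts for the majority of cumulative
activation even though it cannot start the cascade.

## Interventions and model comparison

`run_scenario()` compares a reference simulation against a
counterfactual: scaled dose, scaled initial tumour burden, or a
fractional mechanism block (the targeted $\beta$ multiplied by a
residual fraction inside a time window, with integration restarts at
the window edges).  For blocking schedules, stop times given relative
to "the CAR-T peak" are resolved against the *reference* simulation's
peak day: a clinical schedule cannot depend on the counterfactual's own
peak.  This is exposed in `blocking_grid()`.

`rank_variants()` rebuilds the reduced model variants (DC, AC, DA, D,
A) by structurally zeroing the excluded $\beta$ coefficients, refits
each with the same Monte-Carlo budget and seed stream as the full DAC
model (anything else would bias the comparison), and ranks by
$AIC = 2k + n_d(1 + LR - \ln n_d + \ln 2\pi)$ with $k \in \{6, 7, 8\}$
free parameters, ties broken in favour of fewer parameters.  The
variant with CD40 contact alone is rejected at construction: with
$M_a(0) = 0$ it can never activate a macrophage.

## Virtual patients

`generate_cohort()` draws virtual patients from five archetypes
(complete and partial responders, antigen-positive and
antigen-negative relapse, and a high-inflammation class), simulates
them, samples at a sparse clinical schedule (days 0, 1, 2, 3, 5, 7,
10, 14, 21, 28, 45, 60, 90 — denser early, as in real
pharmacokinetic sampling), applies multiplicative lognormal noise
(default CV 20% for CAR-T, 15% for tumour, 25% for IL-6 — positive
data spanning decades make a multiplicative error model the natural
convention), converts to reporting units and censors below the
detection limits (CAR-T below 2.5×10⁵ cells; tumour below 0.01
%blasts).  Censored rows carry the limit, never a guess.

Choices worth knowing about:

* Parameter draws are log-uniform within archetype ranges chosen so
  that noiseless cohorts reproduce the canonical orderings of the
  system (activated macrophages peak 0–2 days before IL-6; IL-6 peaks
  before the CAR-T peak for most patients; DAMP → antigen → CD40 peak
  order).  The DAMP trigger is drawn as its initial activation scale
  $\beta_K T_P(0) \in [0.7, 2]$/day rather than as a bare coefficient,
  so trigger strength is comparable across tumour burdens.
* The monocyte production rate is drawn below $\delta_M M_i(0)$
  (fraction 0.25–0.5): lymphodepleting pre-conditioning leaves the
  circulating pool above its production steady state, and the ensuing
  depletion of naive macrophages under strong activation is what puts
  the activated-macrophage peak ahead of the CAR-T peak.
* Antigen-positive relapse requires loss of CAR-T persistence — fast
  expander contraction, little memory formation, short-lived
  persisters — otherwise the returning antigen re-expands the CAR-T
  pool and the virtual patient oscillates instead of relapsing.
* Degenerate draws (solver blow-up, unphysical CAR-T burdens above
  10¹³ cells, extinction before the second sample) are regenerated
  from a derived seed and the final seed recorded.

What the generator does *not* emulate: between-assay differences in
measurement error, missing visits and irregular per-patient schedules,
dose fractionation heterogeneity (split dosing is available but not
drawn at random), tumour-type differences in WBC scaling, or any
pharmacodynamic effect of supportive medication such as tocilizumab.
Passing recovery tests on these virtual patients therefore shows the
pipeline is self-consistent under the stated noise model, not that
clinical parameters of real patients are identifiable to the same
accuracy.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use cohorts of 5–20
virtual patients, Nelder–Mead budgets of 500–800 iterations per stage,
and a reduced Monte-Carlo budget (`n_mc = 500`) for the variant
comparison; these sizes were chosen to make the full pipeline
exercisable on a single CPU while leaving the defaults
(`n_mc = 10^4`, `n_refine = 100`) at the values a full analysis would
use.  Ties in peak ordering are broken by mechanism order (DAMP,
antigen, CD40).  Zero-variance scatter pairs in `cohort_metrics()`
report `NA` rather than an arbitrary $R^2$.  Parameters pinned by a
missing phase fall back to documented mid-range defaults and are
flagged in the fit object.

## Known limitations

* $\rho$ is structurally unidentifiable for complete responders (no
  regrowth is ever observed), and $B$ is weakly identified whenever
  the expander pool stays far above it; recovery tests therefore
  report medians over parameters and patients.
* The IL-6 landscape of the cytokine layer is multimodal with long
  degenerate valleys; only $\alpha$, $\beta_C$ and the dominant decay
  rates are reliably recovered on noise-free data, which matches the
  known partial non-identifiability of the remaining parameters.
* Layer-2 bounds are the package's own documented placeholder ranges
  spanning the biologically plausible orders of magnitude; users with
  better prior information should override them in `fit_config()`.
* IL-6 feedback on macrophage activation and other cytokines (IL-1,
  TNF-α, IFN-γ) are deliberately out of scope.
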