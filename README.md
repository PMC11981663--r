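# cartcrs

Mechanistic modelling of CAR-T cell therapy kinetics and
macrophage-mediated cytokine release syndrome (CRS).

CAR-T cell therapy shows a characteristic multiphasic course —
distribution, expansion, contraction, persistence — while the tumour
shrinks and sometimes relapses, and serum IL-6 typically peaks *before*
the CAR-T cells do, driven by activated macrophages. `cartcrs`
implements a three-layer ordinary-differential-equation model of this
system and the analysis pipeline around it, for modellers and
pharmacometricians studying treatment response and CRS:

* **CAR-T / tumour layer** — injected cells $C_I$ activate into
  proliferating expanders $C_E$ under antigen recognition
  $F(T_P) = T_P/(A + T_P)$ and convert into long-lived persisters
  $C_P$; antigen-positive tumour cells grow logistically and are killed
  with a Holling type-II response $\gamma\,C_E/(B + C_E)$.
* **Antigen-negative escape** — a resistant clone $T_N$ killed only at
  a residual fraction $g_0$, sharing the logistic crowding term.
* **Macrophage / IL-6 layer** — naive macrophages are activated by
  three mechanisms (DAMP release from killed tumour cells,
  antigen-binding-mediated signalling, and CD40–CD40L contact — the
  last a positive feedback that can amplify but not initiate), and
  activated macrophages release IL-6.

On top of the simulator the package provides:

* phase segmentation and extremal log-slope analysis, mapping each
  response phase to one mechanistic rate
  ($-\mu_I,\ \kappa-\mu_E,\ -\mu_E,\ -\mu_P,\ \rho,\ \rho-\gamma$);
* two-step parameter estimation: slope-informed bounded Nelder–Mead for
  the ten CAR-T/tumour parameters, then a seeded Monte-Carlo global
  search with local refinement for the eight cytokine parameters under
  the peak-weighted objective
  $LR = \ln \sum_i w_i (IL6(t_i) - IL6_i)^2$;
* exact decomposition of activated macrophages by activation source,
  with peak timelines and cumulative activation fractions;
* counterfactual scenarios (dose scaling, tumour-burden scaling,
  windowed mechanism blocking) and cohort-level correlation tables;
* AIC-based comparison of reduced activation-mechanism variants
  (DAC, DC, AC, DA, D, A), with
  $AIC = 2k + n_d(1 + LR - \ln n_d + \ln 2\pi)$;
* a virtual-patient generator emulating sparse clinical sampling,
  reporting units (transgene copies/µg DNA, %blasts, ng/L) and
  detection limits, so the whole pipeline is testable without clinical
  data.

## Worked example

```r
library(cartcrs)

p <- cart_params(eta = 0.2, mu_I = 0.6, kappa = 1.2, mu_E = 0.3,
                 epsilon = 0.05, mu_P = 0.01, rho = 0.15, gamma = 1.5,
                 A = 1e7, B = 1e7)
q <- cytokine_params(sigma_M = 1e9, delta_M = 0.3, sigma_I = 20,
                     delta_I = 4, alpha = 5e-7, beta_B = 2e-11,
                     beta_K = 5e-11, beta_C = 1e-8)
traj <- simulate_therapy(p, q,
                         model_state(T_P = 2e10, M_i = 1e10, IL6 = 5),
                         dose_regimen(0, 1e8), horizon = 60)
observables(traj)[c("Cmax", "Cmax_day", "il6_peak", "il6_peak_day",
                    "il6_fold_change", "macrophage_peak_day", "Tmin")]
#>          Cmax Cmax_day il6_peak il6_peak_day il6_fold_change macrophage_peak_day     Tmin
#> 1 2692291193.     7.45     546.          5.5            109.                5.25 0.000285
```

A dose of 10⁸ CAR-T cells against 2×10¹⁰ tumour cells expands ~27-fold
to its peak on day 7.5; activated macrophages peak on day 5.25, IL-6
follows on day 5.5 (a 109-fold rise from the 5 ng/L baseline,
consistent with significant CRS), and the tumour is driven to
extinction (`Tmin` far below one cell).

```r
segment_phases(traj)
#>   compartment phase        t_start t_end   slope
#> 1 cart        distribution    0     1.1  -0.600
#> 2 cart        expansion       1.1   7.45  0.852
#> 3 cart        contraction     7.45 14.6  -0.234
#> 4 cart        persistence    14.6  60    -0.0100
#> 5 tumor       transient       0     0.05  0.149
#> 6 tumor       shrinkage       0.05 19.0  -1.34
#> 7 tumor       response       NA    NA    NA
```

The extremal log-slopes recover the generating rates: the distribution
slope −0.600 is $-\mu_I$, the expansion slope 0.852 approximates
$\kappa - \mu_E = 0.9$, the persistence slope −0.0100 is $-\mu_P$, and
the shrinkage slope −1.34 approximates $\rho - \gamma = -1.35$; no
response phase exists because the tumour never regrows.

```r
decompose_activation(traj)$summary
#>   mechanism peak_day  peak_cells   cumulative fraction
#> 1 damp          1.75 2932242043.  4510847496.  0.24019
#> 2 antigen       5.5    21126099.    45293104.  0.00241
#> 3 cd40          7.05 3238577333. 14253473147.  0.75800
```

DAMP-activated macrophages peak first (day 1.75, during tumour
shrinkage), antigen-activated next, CD40-activated last — and the CD40
feedback accounts for 76% of all macrophage activation despite being
unable to start the cascade. Halving the CD40 coefficient over the
whole course (`run_scenario()` with a `mechanism_block` intervention)
lowers the IL-6 peak by 8.8% for this patient; `blocking_grid()` sweeps
block start/stop schedules and shows the earliest starts are the most
effective.

Virtual patients for testing and calibration come from
`generate_cohort()`:

```r
coh <- generate_cohort(25, c(responder_cr = 0.76, agneg_relapse = 0.24),
                       seed = 1)
fit <- fit_cart_layer(coh[[1]]$tc)          # layer 1: CAR-T + tumour
cyt <- fit_cytokine_layer(coh[[1]]$tc, fit) # layer 2: macrophages + IL-6
tidy(cyt); glance(cyt)
```

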