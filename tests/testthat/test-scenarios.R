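scenario_patient <- function() {
  list(p = ref_cart_params(), q = ref_cytokine_params(),
       init = ref_init(), regimen = dose_regimen(0, 1e8), horizon = 60)
}

test_that("the identity intervention reproduces the reference exactly", {
  pat <- scenario_patient()
  sc <- run_scenario(pat, intervention("dose_scale", factor = 1),
                     grid_step = 0.1)
  expect_identical(sc$reference, sc$counterfactual)
  expect_equal(sc$delta$il6_peak_reduction_pct, 0)
  expect_equal(sc$delta$cmax_ratio, 1)
  sc2 <- run_scenario(pat, intervention("tumor_scale", factor = 1),
                      grid_step = 0.1)
  expect_identical(sc2$reference, sc2$counterfactual)
})

test_that("a full CD40 block with no other activation path keeps IL-6 flat", {
  pat <- scenario_patient()
  pat$q <- ref_cytokine_params(beta_K = 0, beta_B = 0)
  pat$init <- ref_init(M_i = pat$q$sigma_M / pat$q$delta_M,
                       IL6 = pat$q$sigma_I / pat$q$delta_I)
  sc <- run_scenario(pat, intervention("mechanism_block", factor = 0,
                                       mechanism = "cd40",
                                       window = c(0, 60)),
                     grid_step = 0.1)
  cf <- sc$cf_traj$data
  expect_lt(diff(range(cf$IL6)) / cf$IL6[1], 1e-6)
})

test_that("smaller doses lower the IL-6 fold change and delay its peak", {
  pat <- scenario_patient()
  s01 <- run_scenario(pat, intervention("dose_scale", factor = 0.1),
                      grid_step = 0.1)
  s001 <- run_scenario(pat, intervention("dose_scale", factor = 0.01),
                       grid_step = 0.1)
  expect_lt(s01$counterfactual$il6_fold_change,
            s01$reference$il6_fold_change)
  expect_lt(s001$counterfactual$il6_fold_change,
            s01$counterfactual$il6_fold_change)
  expect_gt(s01$delta$il6_peak_day_shift, 0)
  expect_gt(s01$delta$cmax_day_shift, 0)
})

test_that("dose scaling only touches the regimen", {
  pat <- scenario_patient()
  sc <- run_scenario(pat, intervention("dose_scale", factor = 0.1),
                     grid_step = 0.2)
  expect_identical(sc$cf_traj$p, pat$p)
  expect_identical(sc$cf_traj$q, pat$q)
  expect_equal(total_dose(sc$cf_traj$regimen), 0.1 * total_dose(pat$regimen))
  sc2 <- run_scenario(pat, intervention("tumor_scale", factor = 10),
                      grid_step = 0.2)
  expect_equal(sc2$cf_traj$data$T_P[1], 10 * pat$init[["T_P"]])
})

test_that("mechanism blocking never increases the IL-6 peak", {
  for (k in 1:4) {
    sp <- sample_patient_params(patient_archetype("high_crs"), 900 + k)
    pat <- list(p = sp$p, q = sp$q, init = sp$init, regimen = sp$regimen,
                horizon = 45)
    for (mech in c("damp", "antigen", "cd40")) {
      sc <- run_scenario(pat, intervention("mechanism_block", factor = 0.5,
                                           mechanism = mech,
                                           window = c(0, 45)),
                         grid_step = 0.2)
      expect_gte(sc$delta$il6_peak_reduction_pct, -1e-6)
    }
  }
})

test_that("blocks starting after the reference peak cannot lower it", {
  pat <- scenario_patient()
  ref <- run_scenario(pat, intervention("dose_scale", factor = 1),
                      grid_step = 0.1)
  peak_day <- ref$reference$il6_peak_day
  sc <- run_scenario(pat, intervention(
    "mechanism_block", factor = 0.5, mechanism = "cd40",
    window = c(peak_day + 0.5, pat$horizon)), grid_step = 0.1)
  expect_lt(abs(sc$delta$il6_peak_reduction_pct), 1)
})

test_that("blocking grid: earlier starts achieve larger reductions", {
  pat <- scenario_patient()
  grid <- blocking_grid(pat, mechanism = "cd40", residual = 0.5,
                        start_days = c(0, 4, 10), stop_offsets = 5,
                        grid_step = 0.2)
  expect_true(all(grid$valid))
  red <- grid$il6_peak_reduction_pct
  expect_true(all(diff(red) <= 1e-6))
  expect_gt(red[1], 0)
  # residual 1.0 means no block at all
  g0 <- blocking_grid(pat, mechanism = "cd40", residual = 1,
                      start_days = c(0, 5), stop_offsets = 0,
                      grid_step = 0.2)
  expect_true(all(abs(g0$il6_peak_reduction_pct) < 1e-3))
})

test_that("cohort metrics report R-squared and degenerate cases", {
  obs <- tibble::tibble(
    dose = c(1e8, 2e8, 3e8, 4e8),
    T0 = c(1e10, 2e10, 3e10, 4e10),
    il6_fold_change = c(2, 4, 6, 8),
    cart_fold_change = c(10, 10, 10, 10),
    il6_peak_day = c(4, 5, 6, 7),
    Cmax_day = c(6, 7, 8, 9),
    macrophage_peak_day = c(3.5, 4.5, 5.5, 6.5),
    tumor_day28 = c(1e6, 2e6, 3e6, 4e6),
    tumor_day90 = c(1e5, 2e5, 3e5, 4e5))
  cm <- cohort_metrics(obs)
  p <- cm$pairs
  # exact linear relation gives R^2 = 1
  expect_equal(p$r_squared[p$x == "dose" & p$y == "il6_fold_change"], 1)
  # constant predictor gives missing R^2
  expect_true(is.na(p$r_squared[p$x == "cart_fold_change" &
                                  p$y == "tumor_day28"]))
  expect_equal(cm$gaps$mean[cm$gaps$gap == "cart_minus_il6_peak_day"], 2)
})

test_that("IL-6 precedes CAR-T and follows macrophages across a cohort", {
  coh <- generate_cohort(10, c(responder_cr = 0.5, high_crs = 0.5),
                         seed = 77, noise = FALSE, grid_step = 0.1)
  obs <- dplyr::bind_rows(lapply(coh, function(sp) {
    o <- observables(sp$trajectory)
    o$T0 <- sp$trajectory$data$T_total[1]
    o
  }))
  gap_c <- obs$Cmax_day - obs$il6_peak_day
  gap_m <- obs$il6_peak_day - obs$macrophage_peak_day
  # IL-6 peak at or before the CAR-T peak, within 5 days, for most
  expect_gte(mean(gap_c >= -0.1 & gap_c <= 5), 0.6)
  # macrophage peak 0-2 days before the IL-6 peak
  expect_true(all(gap_m >= -0.1 & gap_m <= 2))
})
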