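test_that("layer-1 WLS objective matches hand computation", {
  # synthetic patient: objective at the generating parameters is ~0
  sp <- generate_patient("responder_cr", 11, noise = FALSE,
                         grid_step = 0.1)
  obj <- wls_objective_layer1(sp$tc, sp$truth$p,
                              model_state(T_P = sp$truth$init[["T_P"]]))
  expect_lt(obj, 1e-4)
  # hand computation: decay-only kinetics are exactly D exp(-mu_I t), so
  # residuals are the shifts we inject; weights are 1 / max(observed)^2
  p <- ref_cart_params(mu_I = 0.5, eta = 0, rho = 0, gamma = 0)
  ct_exact <- 1e8 * exp(-0.5 * c(1, 2, 3))
  T0 <- 1e9
  data <- dplyr::bind_rows(
    tibble::tibble(series = "cart", time = c(1, 2, 3),
                   value = ct_exact + c(1e7, 3e7, 0),
                   unit = "cells", censored = FALSE),
    tibble::tibble(series = "tumor", time = 0, value = T0,
                   unit = "cells", censored = TRUE))
  tc <- patient_timecourse("h", data, dose_regimen(0, 1e8))
  # all tumour points censored -> precondition violated
  expect_error(wls_objective_layer1(tc, p, model_state(T_P = T0)),
               "tumour")
  data$censored[4] <- FALSE
  tc <- patient_timecourse("h", data, dose_regimen(0, 1e8))
  got <- wls_objective_layer1(tc, p, model_state(T_P = T0))
  # tumour residual at t = 0 is 0 (rho = gamma = 0 keeps it constant)
  want <- (1e7^2 + 3e7^2) / max(ct_exact + c(1e7, 3e7, 0))^2
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("objectives are invariant to data-point order", {
  sp <- generate_patient("responder_cr", 12, noise = TRUE, grid_step = 0.2)
  tc <- sp$tc
  tc2 <- tc
  tc2$data <- tc$data[rev(seq_len(nrow(tc$data))), ]
  p <- sp$truth$p
  init <- model_state(T_P = sp$truth$init[["T_P"]])
  expect_equal(wls_objective_layer1(tc, p, init),
               wls_objective_layer1(tc2, p, init))
})

test_that("layer-1 fit with collapsed bounds returns the point", {
  sp <- generate_patient("responder_cr", 13, noise = FALSE,
                         grid_step = 0.2)
  pt <- sp$truth$p
  b <- lapply(c(mu_I = "mu_I", kappa = "kappa", mu_E = "mu_E",
                mu_P = "mu_P", rho = "rho", gamma = "gamma", eta = "eta",
                epsilon = "epsilon", A = "A", B = "B"),
              function(nm) c(pt[[nm]], pt[[nm]]))
  b$g0 <- c(0.01, 0.5); b$T_N0 <- c(1, 2.5e5)
  cfg <- fit_config(bounds1 = b, maxit = 10)
  fit <- fit_cart_layer(sp$tc, cfg, agneg = FALSE,
                        init_tumor = sp$truth$init[["T_P"]])
  for (nm in c("mu_I", "kappa", "gamma", "A")) {
    expect_equal(fit$params[[nm]], pt[[nm]])
  }
  expect_lt(fit$objective, 1e-4)
})

test_that("two-step split: layer-1 residuals ignore cytokine parameters", {
  sp <- generate_patient("responder_cr", 14, noise = FALSE,
                         grid_step = 0.2)
  init <- model_state(T_P = sp$truth$init[["T_P"]])
  base <- wls_objective_layer1(sp$tc, sp$truth$p, init)
  # layer-2 parameters enter the full simulation but not the layer-1
  # equations: perturbing them must leave layer-1 residuals unchanged
  tr1 <- simulate_therapy(sp$truth$p, sp$truth$q, sp$truth$init,
                          sp$truth$regimen, horizon = 30, grid_step = 0.1)
  q2 <- sp$truth$q
  q2$alpha <- q2$alpha * 10; q2$beta_C <- q2$beta_C * 10
  q2 <- do.call(cytokine_params, q2[])
  tr2 <- simulate_therapy(sp$truth$p, q2, sp$truth$init,
                          sp$truth$regimen, horizon = 30, grid_step = 0.1)
  expect_lt(max(abs(tr1$data$C_T - tr2$data$C_T)) / max(tr1$data$C_T),
            1e-6)
  expect_lt(max(abs(tr1$data$T_total - tr2$data$T_total)) /
              max(tr1$data$T_total), 1e-6)
  expect_false(isTRUE(all.equal(tr1$data$IL6, tr2$data$IL6)))
  expect_equal(wls_objective_layer1(sp$tc, sp$truth$p, init), base)
})

test_that("cytokine-layer fit is deterministic under its seed", {
  sp <- generate_patient("high_crs", 22, noise = FALSE, grid_step = 0.2)
  layer1 <- list(params = sp$truth$p, init = sp$truth$init,
                 regimen = sp$truth$regimen)
  cfg <- fit_config(n_mc = 120, n_refine = 6, seed = 9)
  f1 <- fit_cytokine_layer(sp$tc, layer1, cfg, refine_maxit = 25)
  f2 <- fit_cytokine_layer(sp$tc, layer1, cfg, refine_maxit = 25)
  expect_identical(f1$lr, f2$lr)
  expect_identical(unlist(f1$params[]), unlist(f2$params[]))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$n_d, nrow(timecourse_series(sp$tc, "il6")))
  # AIC consistency with the formula
  expect_equal(f1$aic, aic_score(f1$lr, 8, f1$n_d))
})

test_that("cytokine-layer search recovers the dominant coefficients", {
  # noise-free patient with CD40-dominant activation and a known first
  # layer: the global search should land in the generating basin, giving
  # alpha and beta_C back while the remaining parameters stay only
  # partially identified
  sp <- generate_patient("high_crs", 21, noise = FALSE, grid_step = 0.1)
  layer1 <- list(params = sp$truth$p, init = sp$truth$init,
                 regimen = sp$truth$regimen)
  fit <- fit_cytokine_layer(sp$tc, layer1,
                            fit_config(n_mc = 4000, n_refine = 60,
                                       seed = 42),
                            refine_maxit = 100)
  tq <- sp$truth$q
  expect_lt(abs(fit$params$alpha - tq$alpha) / tq$alpha, 0.5)
  expect_lt(abs(fit$params$beta_C - tq$beta_C) / tq$beta_C, 0.5)
  # optimizer sanity: the fit explains the IL-6 series to well under 1%
  # of the peak (weighted RMS residual)
  il6 <- timecourse_series(sp$tc, "il6")
  rms <- exp(fit$lr / 2) / sqrt(nrow(il6))
  expect_lt(rms / max(il6$cells), 0.01)
})

test_that("noise-free layer-1 recovery stays within tolerance", {
  # parameter-recovery experiment on two archetypes
  errs <- c()
  for (seed in c(7, 13)) {
    sp <- generate_patient("responder_cr", seed, noise = FALSE,
                           grid_step = 0.1)
    fit <- fit_cart_layer(sp$tc, fit_config(maxit = 600))
    tr <- tidy(fit)
    truth <- vapply(tr$term, function(n) sp$truth$p[[n]], numeric(1))
    errs <- c(errs, abs(tr$estimate - truth) / truth)
  }
  expect_lt(median(errs), 0.15)
})
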