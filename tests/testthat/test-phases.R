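test_that("log slopes of exact exponentials are recovered", {
  t <- seq(0, 5, 0.1)
  expect_equal(extremal_log_slope(t, exp(-2 * t), c(0, 5), "min"), -2)
  expect_equal(extremal_log_slope(t, 3 * exp(0.9 * t), c(0, 5), "max"), 0.9)
  # logistic far below carrying capacity grows at ~rho
  K <- 1e12; rho <- 0.3
  y <- 1e6 * K * exp(rho * t) / (K + 1e6 * (exp(rho * t) - 1))
  expect_equal(extremal_log_slope(t, y, c(0, 2), "max"), rho,
               tolerance = 0.01)
  expect_error(extremal_log_slope(t, t - 1, c(0, 5), "min"), "positive")
  expect_error(extremal_log_slope(t, exp(t), c(10, 11), "min"), "window")
})

test_that("segmentation of a simulated course recovers the slope map", {
  p <- ref_cart_params()
  tr <- simulate_therapy(p, init = model_state(T_P = 2e10),
                         regimen = dose_regimen(0, 1e8), horizon = 90,
                         grid_step = 0.05)
  seg <- segment_phases(tr)
  g <- function(ph, cm) seg$slope[seg$phase == ph & seg$compartment == cm]
  expect_equal(g("distribution", "cart"), -p$mu_I, tolerance = 0.15)
  expect_equal(g("expansion", "cart"), p$kappa - p$mu_E, tolerance = 0.15)
  expect_equal(g("contraction", "cart"), -p$mu_E, tolerance = 0.25)
  expect_equal(g("persistence", "cart"), -p$mu_P, tolerance = 0.15)
  expect_equal(g("shrinkage", "tumor"), p$rho - p$gamma, tolerance = 0.15)
  # boundaries ordered
  cartseg <- seg[seg$compartment == "cart" & !is.na(seg$t_start), ]
  expect_true(all(diff(cartseg$t_start) >= 0))
  expect_true(all(cartseg$t_end >= cartseg$t_start))
})

test_that("pure decay yields a single distribution phase", {
  p <- ref_cart_params()
  tr <- simulate_therapy(p, init = model_state(),
                         regimen = dose_regimen(0, 1e8), horizon = 30,
                         grid_step = 0.1)
  seg <- segment_phases(tr)
  cart <- seg[seg$compartment == "cart", ]
  expect_false(is.na(cart$slope[cart$phase == "distribution"]))
  expect_true(all(is.na(cart$slope[cart$phase != "distribution"])))
})

test_that("tumour response phase appears only on regrowth", {
  # strong kill drives extinction: no response phase
  tr <- simulate_therapy(ref_cart_params(gamma = 2.5),
                         init = model_state(T_P = 1e10),
                         regimen = dose_regimen(0, 1e8), horizon = 90,
                         grid_step = 0.1)
  seg <- segment_phases(tr)
  expect_true(is.na(seg$slope[seg$phase == "response"]))
  # gamma = 0: tumour only grows; slope ~ rho, no shrinkage
  tr2 <- simulate_therapy(ref_cart_params(gamma = 0, rho = 0.25),
                          init = model_state(T_P = 1e8),
                          regimen = dose_regimen(0, 1e8), horizon = 20,
                          grid_step = 0.1)
  seg2 <- segment_phases(tr2)
  expect_true(is.na(seg2$slope[seg2$phase == "shrinkage"]))
  m_T <- seg2$slope[seg2$phase == "transient"]
  expect_equal(m_T, 0.25, tolerance = 0.02)
})

test_that("slope-to-parameter algebra inverts the mapping", {
  seg <- dplyr::bind_rows(
    tibble::tibble(compartment = "cart",
                   phase = c("distribution", "expansion", "contraction",
                             "persistence"),
                   t_start = c(0, 2, 7, 20), t_end = c(2, 7, 20, 90),
                   slope = c(-0.5, 1.0, -0.3, -0.01)),
    tibble::tibble(compartment = "tumor",
                   phase = c("transient", "shrinkage", "response"),
                   t_start = c(NA, 0, 20), t_end = c(NA, 20, 90),
                   slope = c(NA, -1.2, 0.25)))
  obs <- tibble::tibble(Cmax = 1e9, Cmax_day = 7, Cmin = 5e7,
                        Cmin_day = 2, Tmin = 1e5, Tmin_day = 20,
                        tmin_is_bound = FALSE, persister_day28 = 1e7)
  sm <- slope_parameter_map(seg, obs, model_state(T_P = 1e10),
                            dose_regimen(0, 1e8), refine = FALSE)
  p <- sm$params
  expect_equal(p$mu_I, 0.5)
  expect_equal(p$mu_E, 0.3)
  expect_equal(p$kappa, 1.3)
  expect_equal(p$mu_P, 0.01)
  expect_equal(p$rho, 0.25)
  expect_equal(p$gamma, 0.25 + 1.2)
})

test_that("slope estimates track parameters across a virtual cohort", {
  # property over random draws: the six characteristic slopes match
  # their parameter combinations along the identity line
  mix <- c(responder_cr = 0.5, responder_pr = 0.2, agpos_relapse = 0.15,
           agneg_relapse = 0.15)
  coh <- generate_cohort(10, mix, seed = 31, noise = FALSE,
                         grid_step = 0.1)
  errs <- list(D = c(), E = c(), C = c(), P = c(), S = c())
  for (sp in coh) {
    seg <- segment_phases(sp$trajectory)
    g <- function(ph, cm) {
      r <- seg$slope[seg$phase == ph & seg$compartment == cm]
      if (length(r)) r else NA_real_
    }
    p <- sp$truth$p
    pairs <- list(D = c(g("distribution", "cart"), -p$mu_I),
                  E = c(g("expansion", "cart"), p$kappa - p$mu_E),
                  C = c(g("contraction", "cart"), -p$mu_E),
                  P = c(g("persistence", "cart"), -p$mu_P),
                  S = c(g("shrinkage", "tumor"), p$rho - p$gamma))
    for (nm in names(pairs)) {
      v <- pairs[[nm]]
      if (all(is.finite(v))) {
        errs[[nm]] <- c(errs[[nm]], abs(v[1] - v[2]) / abs(v[2]))
      }
    }
  }
  for (nm in names(errs)) {
    expect_lt(median(errs[[nm]]), 0.2)
  }
})
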