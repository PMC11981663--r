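test_that("antigen binding saturates correctly and rejects bad input", {
  expect_equal(antigen_binding(0, 1e6), 0)
  expect_equal(antigen_binding(1e6, 1e6), 0.5)
  expect_equal(antigen_binding(9e6, 1e6), 0.9)
  # monotone increasing, bounded in [0, 1]
  tp <- 10^seq(0, 12, length.out = 50)
  f <- antigen_binding(tp, 1e6)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(antigen_binding(1e6, 0), "A")
  expect_error(antigen_binding(-1, 1e6), "T_P")
})

test_that("CAR-T/tumour derivatives match the model structure", {
  # pure injected decay: eta = 0 removes activation
  p <- ref_cart_params(eta = 0, mu_I = 0.5, mu_P = 0, rho = 0, gamma = 0)
  d <- cart_tumor_rhs(model_state(C_I = 1e6)[1:5], p)
  expect_equal(unname(d["C_I"]), -5e5)
  # expanders at saturating antigen grow at kappa - mu_E
  p <- ref_cart_params(A = 1e6, epsilon = 0.05)
  s <- model_state(C_E = 1e7, T_P = 1e12)[1:5]
  d <- cart_tumor_rhs(s, p)
  expect_equal(unname(d["C_E"]), (p$kappa - p$mu_E) * 1e7,
               tolerance = 1e-4)
  # tumour alone follows logistic growth
  p <- ref_cart_params(rho = 0.2, K = 4.25e12)
  d <- cart_tumor_rhs(model_state(T_P = 1e8)[1:5], p)
  expect_equal(unname(d["T_P"]), 0.2 * 1e8 * (1 - 1e8 / 4.25e12))
  expect_error(cart_tumor_rhs(c(C_I = -1, C_E = 0, C_P = 0, T_P = 0,
                                T_N = 0), p), "negative")
})

test_that("proliferation gate switches growth off below one cell only", {
  p <- ref_cart_params(rho = 0.3, gamma = 2)
  # tumour below one cell: growth zero, kill still active
  s <- c(C_I = 0, C_E = 1e9, C_P = 0, T_P = 0.4, T_N = 0)
  d <- cart_tumor_rhs(s, p)
  kill <- p$gamma * 1e9 / (p$B + 1e9) * 0.4
  expect_equal(unname(d["T_P"]), -kill)
  # at exactly one cell growth is fully active
  s1 <- c(C_I = 0, C_E = 0, C_P = 0, T_P = 1, T_N = 0)
  d1 <- cart_tumor_rhs(s1, p)
  expect_equal(unname(d1["T_P"]), p$rho * 1 * (1 - 1 / p$K))
  # all populations >= 1: gated and ungated derivatives coincide
  s2 <- c(C_I = 1e5, C_E = 1e6, C_P = 1e3, T_P = 1e8, T_N = 1e2)
  expect_equal(cart_tumor_rhs(s2, p, gate = TRUE),
               cart_tumor_rhs(s2, p, gate = FALSE))
})

test_that("activation rate splits into its three mechanisms", {
  q <- ref_cytokine_params()
  p <- ref_cart_params(g0 = 0.05)
  # every term is proportional to C_E
  h0 <- activation_rate(0, 1e9, 1e6, 1e8, q, p)
  expect_equal(unname(h0), rep(0, 4))
  # CD40 term proportional to M_a
  h1 <- activation_rate(1e9, 1e9, 0, 0, ref_cytokine_params(
    beta_K = 0, beta_B = 0), p)
  expect_equal(unname(h1[["h_total"]]), 0)
  # CD40 saturation limit: M_a >> C gives beta_C * C_E
  h2 <- activation_rate(1e9, 0, 0, 1e16, q, p)
  expect_equal(h2[["h_cd40"]], q$beta_C * 1e9, tolerance = 1e-5)
  # hand-computed components
  h3 <- activation_rate(1e9, 1e10, 1e6, 1e8, q, p)
  expect_equal(h3[["h_damp"]],
               q$beta_K * 1e9 / (p$B + 1e9) * (1e10 + 0.05 * 1e6))
  expect_equal(h3[["h_antigen"]], q$beta_B * 1e10 / (p$A + 1e10) * 1e9)
  expect_equal(h3[["h_cd40"]], q$beta_C * 1e8 / (q$C + 1e8) * 1e9)
  expect_equal(h3[["h_total"]],
               sum(h3[c("h_damp", "h_antigen", "h_cd40")]))
})

test_that("macrophage layer derivatives and steady states", {
  q <- ref_cytokine_params()
  # naive macrophages at steady state with no activation
  s <- c(M_i = q$sigma_M / q$delta_M, M_a = 0, IL6 = q$sigma_I / q$delta_I)
  d <- macrophage_rhs(s, q, h = 0)
  expect_equal(unname(d["M_i"]), 0)
  # IL-6 at the sigma_I / delta_I steady state with no macrophages
  expect_equal(unname(d["IL6"]), 0)
  # pure decay
  q2 <- ref_cytokine_params(alpha = 0, sigma_I = 0, delta_I = 1)
  d2 <- macrophage_rhs(c(M_i = 0, M_a = 0, IL6 = 2), q2, h = 0)
  expect_equal(unname(d2["IL6"]), -2)
})

test_that("parameter constructors validate invariants", {
  expect_error(ref_cart_params(mu_I = -0.1), "mu_I")
  expect_error(ref_cart_params(A = 0), "A")
  expect_error(ref_cart_params(g0 = 1.5), "g0")
  expect_error(ref_cytokine_params(alpha = -1), "alpha")
  expect_error(model_state(C_I = -5), "non-negative")
  expect_error(dose_regimen(c(3, 1), c(1e7, 1e7)), "ordered")
  expect_error(dose_regimen(0, -1), "positive")
  expect_equal(total_dose(split_dose(1e8)), 1e8)
  expect_equal(split_dose(1e8)$cells, c(1e7, 3e7, 6e7))
})

test_that("compiled right-hand side agrees with the R reference", {
  p <- ref_cart_params(g0 = 0.05)
  q <- ref_cytokine_params()
  y <- c(C_I = 1e7, C_E = 3e8, C_P = 1e5, T_P = 5e9, T_N = 2e5,
         M_i = 8e9, M_a = 2e8, IL6 = 50, Ma_damp = 1e8,
         Ma_antigen = 5e7, Ma_cd40 = 5e7, J_damp = 0, J_antigen = 0,
         J_cd40 = 0)
  r_sol <- deSolve::lsoda(y, c(0, 0.5), func = cartcrs:::.full_rhs,
                          parms = list(p = p, q = q, gate = TRUE,
                                       beta_scale = NULL),
                          rtol = 1e-10, atol = 1e-8)
  c_sol <- deSolve::lsoda(y, c(0, 0.5), func = "derivs_cartcrs",
                          dllname = "cartcrs",
                          initfunc = "initmod_cartcrs",
                          parms = cartcrs:::.parms_vector(p, q, TRUE, NULL),
                          rtol = 1e-10, atol = 1e-8)
  rel <- abs(r_sol[2, -1] - c_sol[2, -1]) /
    pmax(abs(r_sol[2, -1]), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("unit conversions follow the clinical conventions and invert", {
  expect_equal(convert_units(25, "copies/ug", "cells"), 2.5e5)
  expect_equal(convert_units(1, "cells/uL", "cells"), 5e6)
  expect_equal(convert_units(1, "cells/uL BM", "cells"), 5e8)
  # %blasts via the mean WBC of 4.25e10: 100% is the whole pool
  expect_equal(convert_units(100, "%blasts", "cells"), 4.25e10)
  expect_equal(convert_units(0, "copies/ug", "cells"), 0)
  # round trips to machine precision
  for (u in c("copies/ug", "cells/uL", "cells/uL BM", "%blasts")) {
    expect_equal(convert_units(convert_units(123.4, u, "cells"),
                               "cells", u), 123.4)
  }
  expect_error(convert_units(1, "furlongs", "cells"), "unrecognized")
  # custom context changes the scale coherently
  ctx <- unit_context(blood_volume = 4)
  expect_equal(convert_units(1, "cells/uL", "cells", ctx), 4e6)
})
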