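# shared fixtures: a mid-range parameterisation used across tests
ref_cart_params <- function(...) {
  args <- list(eta = 0.2, mu_I = 0.6, kappa = 1.2, mu_E = 0.3,
               epsilon = 0.05, mu_P = 0.01, rho = 0.15, gamma = 1.5,
               A = 1e7, B = 1e7)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(cart_params, args)
}

ref_cytokine_params <- function(...) {
  args <- list(sigma_M = 1e9, delta_M = 0.3, sigma_I = 20, delta_I = 4,
               alpha = 5e-7, beta_B = 2e-11, beta_K = 5e-11,
               beta_C = 1e-8)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(cytokine_params, args)
}

ref_init <- function(...) {
  args <- list(T_P = 2e10, M_i = 1e10, IL6 = 5)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(model_state, args)
}

ref_sim <- function(horizon = 60, grid_step = 0.1, ...) {
  simulate_therapy(ref_cart_params(), ref_cytokine_params(), ref_init(),
                   dose_regimen(0, 1e8), horizon = horizon,
                   grid_step = grid_step, ...)
}
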