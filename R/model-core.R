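#' Antigen-receptor binding fraction
#'
#' Michaelis-Menten saturation of antigen recognition,
#' `F(T_P) = T_P / (A + T_P)`.  Drives activation of injected CAR-T cells,
#' expander proliferation, persister reactivation and (through `1 - F`)
#' persister formation.
#'
#' @param T_P antigen-positive tumour cells (>= 0).
#' @param A half-saturation constant (cells, > 0).
#' @return Binding fraction in \[0, 1\], monotone increasing in `T_P`.
#' @examples
#' antigen_binding(1e6, A = 1e6)  # 0.5
#' @export
antigen_binding <- function(T_P, A) {
  if (any(A <= 0)) stop("antigen_binding: 'A' must be > 0", call. = FALSE)
  if (any(T_P < 0)) stop("antigen_binding: 'T_P' must be >= 0", call. = FALSE)
  T_P / (A + T_P)
}

# proliferation gate: growth terms are switched off for populations below
# one cell, preventing artificial regrowth; death/kill/transition terms
# are never gated.  Reversible: influx can repopulate past the threshold.
# Implemented as a linear ramp on [0.5, 1] cells (0 at <= 0.5, 1 at >= 1)
# so the right-hand side stays continuous for the adaptive integrator.
.grow_gate <- function(x) pmin(pmax(2 * (x - 0.5), 0), 1)

#' Right-hand side of the CAR-T / tumour layer
#'
#' Time derivatives of injected (`C_I`), expander (`C_E`) and persister
#' (`C_P`) CAR-T cells and the antigen-positive (`T_P`) and
#' antigen-negative (`T_N`) tumour compartments.  Both tumour clones share
#' logistic crowding `1 - (T_P + T_N)/K`; antigen-negative cells are
#' killed at the residual fraction `g0` and do not feed antigen signalling
#' (`F` is evaluated on `T_P` only).  Proliferation terms are gated to
#' zero for populations below one cell.
#'
#' @param state a [model_state()] or named numeric vector.
#' @param p a [cart_params()].
#' @param gate apply the below-one-cell proliferation gate (default TRUE).
#' @return Named numeric vector of derivatives for
#'   `C_I, C_E, C_P, T_P, T_N` (cells/day).
#' @export
cart_tumor_rhs <- function(state, p, gate = TRUE) {
  s <- state
  if (any(s[c("C_I", "C_E", "C_P", "T_P", "T_N")] < 0)) {
    stop("cart_tumor_rhs: negative state component", call. = FALSE)
  }
  Fv <- s[["T_P"]] / (p$A + s[["T_P"]])
  kill <- p$gamma * s[["C_E"]] / (p$B + s[["C_E"]])
  gE <- if (gate) .grow_gate(s[["C_E"]]) else 1
  gTP <- if (gate) .grow_gate(s[["T_P"]]) else 1
  gTN <- if (gate) .grow_gate(s[["T_N"]]) else 1
  crowd <- 1 - (s[["T_P"]] + s[["T_N"]]) / p$K
  dC_I <- -p$eta * Fv * s[["C_I"]] - p$mu_I * s[["C_I"]]
  dC_E <- p$eta * Fv * s[["C_I"]] + gE * p$kappa * Fv * s[["C_E"]] -
    p$epsilon * (1 - Fv) * s[["C_E"]] + p$theta * Fv * s[["C_P"]] -
    p$mu_E * s[["C_E"]]
  dC_P <- p$epsilon * (1 - Fv) * s[["C_E"]] - p$theta * Fv * s[["C_P"]] -
    p$mu_P * s[["C_P"]]
  dT_P <- gTP * p$rho * s[["T_P"]] * crowd - kill * s[["T_P"]]
  dT_N <- gTN * p$rho * s[["T_N"]] * crowd - p$g0 * kill * s[["T_N"]]
  c(C_I = dC_I, C_E = dC_E, C_P = dC_P, T_P = dT_P, T_N = dT_N)
}

#' Macrophage activation rate, split by mechanism
#'
#' The total per-capita activation rate of naive macrophages and its three
#' components: DAMP release by CAR-T-mediated tumour killing
#' (`beta_K * C_E/(B + C_E) * (T_P + g0 T_N)`), antigen-binding-mediated
#' inflammatory signalling (`beta_B * T_P/(A + T_P) * C_E`), and
#' CD40-CD40L contact with already-activated macrophages
#' (`beta_C * M_a/(C + M_a) * C_E`).
#'
#' @param C_E expander CAR-T cells.
#' @param T_P,T_N antigen-positive / negative tumour cells.
#' @param M_a activated macrophages.
#' @param q a [cytokine_params()].
#' @param p a [cart_params()] (supplies `A`, `B`, `g0`).
#' @return Named numeric vector `h_total, h_damp, h_antigen, h_cd40`
#'   (/day).
#' @export
activation_rate <- function(C_E, T_P, T_N, M_a, q, p) {
  h_damp <- q$beta_K * C_E / (p$B + C_E) * (T_P + p$g0 * T_N)
  h_antigen <- q$beta_B * T_P / (p$A + T_P) * C_E
  h_cd40 <- q$beta_C * M_a / (q$C + M_a) * C_E
  c(h_total = h_damp + h_antigen + h_cd40,
    h_damp = h_damp, h_antigen = h_antigen, h_cd40 = h_cd40)
}

#' Right-hand side of the macrophage / IL-6 layer
#'
#' Naive macrophages are produced at `sigma_M`, activated at the supplied
#' per-capita rate `h`, and both compartments die at `delta_M`.  IL-6 is
#' produced endogenously at `sigma_I`, released by activated macrophages
#' at `alpha` per cell, and decays at `delta_I`.
#'
#' @param state named state containing `M_i`, `M_a`, `IL6`.
#' @param q a [cytokine_params()].
#' @param h total macrophage activation rate (/day).
#' @return Named derivatives `M_i, M_a, IL6`.
#' @export
macrophage_rhs <- function(state, q, h) {
  dM_i <- q$sigma_M - h * state[["M_i"]] - q$delta_M * state[["M_i"]]
  dM_a <- h * state[["M_i"]] - q$delta_M * state[["M_a"]]
  dIL6 <- q$sigma_I + q$alpha * state[["M_a"]] - q$delta_I * state[["IL6"]]
  c(M_i = dM_i, M_a = dM_a, IL6 = dIL6)
}

# flat parameter vector for the compiled right-hand sides (src/model_rhs.c)
.parms_vector <- function(p, q = NULL, gate = TRUE, beta_scale = NULL) {
  qv <- if (is.null(q)) rep(0, 9) else
    c(q$sigma_M, q$delta_M, q$sigma_I, q$delta_I, q$alpha,
      q$beta_B, q$beta_K, q$beta_C, q$C)
  if (is.null(q) || qv[9] <= 0) qv[9] <- 1  # keep C positive in the C code
  bs <- if (is.null(beta_scale)) c(1, 1, 1) else
    unname(beta_scale[c("damp", "antigen", "cd40")])
  c(p$eta, p$mu_I, p$kappa, p$mu_E, p$epsilon, p$theta, p$mu_P, p$rho,
    p$K, p$gamma, p$A, p$B, p$g0, qv, as.numeric(gate), bs)
}

# deSolve-facing RHS of the full (optionally augmented) system.
# State layout: C_I, C_E, C_P, T_P, T_N [, M_i, M_a, IL6,
#                Ma_damp, Ma_antigen, Ma_cd40, J_damp, J_antigen, J_cd40]
# The Ma_* sub-populations split activated macrophages by activation
# source; J_* accumulate the activation integrals  int h_j M_i dt.
.full_rhs <- function(t, y, parms) {
  p <- parms$p
  y <- pmax(y, 0)  # clamp solver undershoot
  dcart <- cart_tumor_rhs(y[1:5], p, gate = parms$gate)
  if (is.null(parms$q)) {
    return(list(dcart))
  }
  q <- parms$q
  if (!is.null(parms$beta_scale)) {
    q$beta_K <- q$beta_K * parms$beta_scale[["damp"]]
    q$beta_B <- q$beta_B * parms$beta_scale[["antigen"]]
    q$beta_C <- q$beta_C * parms$beta_scale[["cd40"]]
  }
  h <- activation_rate(y[["C_E"]], y[["T_P"]], y[["T_N"]], y[["M_a"]], q, p)
  dmac <- macrophage_rhs(y, q, h[["h_total"]])
  dsub <- c(
    Ma_damp = h[["h_damp"]] * y[["M_i"]] - q$delta_M * y[["Ma_damp"]],
    Ma_antigen = h[["h_antigen"]] * y[["M_i"]] - q$delta_M * y[["Ma_antigen"]],
    Ma_cd40 = h[["h_cd40"]] * y[["M_i"]] - q$delta_M * y[["Ma_cd40"]],
    J_damp = h[["h_damp"]] * y[["M_i"]],
    J_antigen = h[["h_antigen"]] * y[["M_i"]],
    J_cd40 = h[["h_cd40"]] * y[["M_i"]]
  )
  list(c(dcart, dmac, dsub))
}
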