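#' Fitting configuration
#'
#' Bounds and budgets for the two-step estimation pipeline.  Layer-1
#' bounds cover the ten patient-specific CAR-T/tumour parameters (the
#' carrying capacity `K` and reactivation rate `theta` are universal
#' constants); layer-2 bounds cover the eight free cytokine parameters.
#' Bounds span orders of magnitude, so Monte-Carlo sampling and the bound
#' transform both work on the log scale.
#'
#' @param bounds1 named list of `c(lower, upper)` for the layer-1
#'   parameters `mu_I, kappa, mu_E, mu_P, rho, gamma, eta, epsilon, A, B`
#'   (plus `g0`, `T_N0` for antigen-negative relapse fits).
#' @param bounds2 named list of bounds for the layer-2 parameters
#'   `sigma_M, delta_M, delta_I, alpha, beta_B, beta_K, beta_C, M_i0`.
#' @param w0 IL-6 weight floor in (0, 1\] (default 0.15, giving the IL-6
#'   peak roughly seven times the weight of the minimum).
#' @param n_mc Monte-Carlo samples for the layer-2 global search.
#' @param n_refine number of best tuples refined locally.
#' @param seed master RNG seed for the fit.
#' @param maxit Nelder-Mead iteration cap.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @return A `fit_config` list.
#' @export
fit_config <- function(bounds1 = default_bounds_layer1(),
                       bounds2 = default_bounds_layer2(),
                       w0 = 0.15, n_mc = 1e4, n_refine = 100,
                       seed = 1, maxit = 500, reltol = 1e-8) {
  stopifnot(w0 > 0, w0 <= 1, n_refine <= n_mc, n_mc >= 1)
  for (b in c(bounds1, bounds2)) {
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2]) {
      stop("fit_config: each bound must be finite c(lower, upper)",
           call. = FALSE)
    }
  }
  structure(list(bounds1 = bounds1, bounds2 = bounds2, w0 = w0,
                 n_mc = as.integer(n_mc), n_refine = as.integer(n_refine),
                 seed = seed, maxit = maxit, reltol = reltol),
            class = "fit_config")
}

#' @rdname fit_config
#' @export
default_bounds_layer1 <- function() {
  list(mu_I = c(1e-2, 5), kappa = c(5e-2, 5), mu_E = c(1e-2, 3),
       mu_P = c(1e-4, 1), rho = c(1e-2, 1), gamma = c(1e-2, 10),
       eta = c(1e-3, 10), epsilon = c(1e-4, 1),
       A = c(1e4, 1e10), B = c(1e4, 1e10),
       g0 = c(1e-3, 0.5), T_N0 = c(1, 2.5e5))
}

#' @rdname fit_config
#' @export
default_bounds_layer2 <- function() {
  list(sigma_M = c(1e6, 5e10), delta_M = c(1e-2, 2),
       delta_I = c(0.5, 20), alpha = c(1e-9, 1e-4),
       beta_B = c(1e-13, 1e-8), beta_K = c(1e-13, 1e-8),
       beta_C = c(1e-12, 1e-6), M_i0 = c(1e9, 1e11))
}

# logistic transform mapping the real line onto (lo, hi) on the log scale;
# lets plain Nelder-Mead respect bounds
.to_unconstrained <- function(x, lo, hi) {
  z <- (log(x) - log(lo)) / (log(hi) - log(lo))
  z <- pmin(pmax(z, 1e-10), 1 - 1e-10)
  stats::qlogis(z)
}
.to_bounded <- function(u, lo, hi) {
  exp(log(lo) + stats::plogis(u) * (log(hi) - log(lo)))
}

#' Layer-1 weighted least-squares objective
#'
#' Sum over the CAR-T and tumour series of squared residuals between the
#' simulated and observed points, each series weighted by the inverse
#' square of its maximum observed value.  Points below the CAR-T
#' detection limit (and tumour points censored at approximately zero
#' %blasts) are excluded.  A failed simulation returns `Inf`.
#'
#' @param tc a [patient_timecourse()].
#' @param p a [cart_params()].
#' @param init initial [model_state()] (tumour seed; CAR-T enters via the
#'   regimen).
#' @param grid_step simulation step for objective evaluation.
#' @param rtol solver tolerance used inside the objective.
#' @return The weighted sum of squares (non-negative scalar).
#' @export
wls_objective_layer1 <- function(tc, p, init, grid_step = 0.25,
                                 rtol = 1e-6) {
  pts <- .layer1_points(tc)
  sim <- .layer1_sim_at(tc, p, init, pts, grid_step, rtol)
  if (is.null(sim)) return(Inf)
  sse <- sum((sim$cart - pts$cart$cells)^2) / max(pts$cart$cells)^2 +
    sum((sim$tumor - pts$tumor$cells)^2) / max(pts$tumor$cells)^2
  if (!is.finite(sse)) Inf else sse
}

.layer1_points <- function(tc) {
  cart <- timecourse_series(tc, "cart", censored = FALSE)
  tum <- timecourse_series(tc, "tumor", censored = FALSE)
  if (nrow(cart) < 3) {
    stop("layer-1 objective: need at least 3 quantified CAR-T points",
         call. = FALSE)
  }
  if (nrow(tum) < 1) {
    stop("layer-1 objective: need at least 1 quantified tumour point",
         call. = FALSE)
  }
  list(cart = cart, tumor = tum)
}

# lean objective-path simulation: piecewise lsoda over the dose events
# with output only at the observation times, no trajectory container
.layer1_sim_at <- function(tc, p, init, pts, grid_step, rtol) {
  obs_times <- sort(unique(c(pts$cart$time, pts$tumor$time)))
  horizon <- max(tc$horizon, max(obs_times) + 1)
  regimen <- tc$regimen
  y <- as.numeric(init)[1:5]
  names(y) <- c("C_I", "C_E", "C_P", "T_P", "T_N")
  breaks <- sort(unique(c(0, regimen$time, horizon)))
  pv <- .parms_vector(p)
  out <- NULL
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    dosed <- regimen$cells[abs(regimen$time - t0) < 1e-12]
    if (length(dosed)) y[["C_I"]] <- y[["C_I"]] + sum(dosed)
    times <- unique(c(t0, obs_times[obs_times > t0 & obs_times < t1], t1))
    sol <- tryCatch(
      suppressWarnings(deSolve::lsoda(
        y, times, func = "derivs_cartcrs", dllname = "cartcrs",
        initfunc = "initmod_cartcrs", parms = pv,
        rtol = rtol, atol = 1e-6, maxsteps = 5000)),
      error = function(e) NULL)
    if (is.null(sol) || attr(sol, "istate")[1] < 0 ||
        nrow(sol) < length(times)) return(NULL)
    y <- pmax(sol[nrow(sol), -1], 0)
    out <- rbind(out, sol[-nrow(sol), , drop = FALSE])
    if (k == length(breaks) - 1) out <- rbind(out, sol[nrow(sol), ])
  }
  tt <- out[, 1]
  ct <- pmax(out[, 2] + out[, 3] + out[, 4], 0)
  tot <- pmax(out[, 5] + out[, 6], 0)
  f_ct <- approxfun(tt, ct, rule = 2)
  f_tt <- approxfun(tt, tot, rule = 2)
  list(cart = f_ct(pts$cart$time), tumor = f_tt(pts$tumor$time))
}

# log-scale pre-fit objective: mean squared log residual across both
# series.  Gives every decade of the dynamics equal leverage, which the
# max-weighted WLS cannot (persistence-phase points are ~1e-6 of the peak
# weight there); used only to steer the search before the WLS polish.
.log_objective_layer1 <- function(tc, p, init, pts, grid_step = 0.25,
                                  rtol = 1e-6, floor = 1) {
  sim <- .layer1_sim_at(tc, p, init, pts, grid_step, rtol)
  if (is.null(sim)) return(Inf)
  v <- c(log(pmax(sim$cart, floor)) - log(pmax(pts$cart$cells, floor)),
         log(pmax(sim$tumor, floor)) - log(pmax(pts$tumor$cells, floor)))
  m <- mean(v^2)
  if (!is.finite(m)) Inf else m
}

#' Fit the CAR-T / tumour layer
#'
#' Slope-informed estimation of the ten patient-specific layer-1
#' parameters: the time course is segmented into phases, the
#' characteristic slopes and shape features seed an initial guess via
#' [slope_parameter_map()], and a bounded Nelder-Mead search (logistic
#' bound transform on the log scale) minimises the weighted
#' least-squares objective.  `K` and `theta` stay fixed.  For
#' antigen-negative relapse patients (`agneg = TRUE`) the residual kill
#' fraction `g0` and the antigen-negative seed `T_N(0)` are additionally
#' free, the latter bounded above by the detection limit unless the
#' bounds say otherwise.
#'
#' @param tc a [patient_timecourse()].
#' @param config a [fit_config()].
#' @param agneg fit the antigen-negative extension? Default: `TRUE` when
#'   the disease label contains `"agneg"`.
#' @param init_tumor initial antigen-positive burden (cells); defaults to
#'   the first quantified tumour point, or 1e7 when absent.
#' @param start optional [cart_params()] overriding the slope-based
#'   initial guess.
#' @return A `cart_fit` with elements `params`, `T_N0`, `objective`,
#'   `convergence`, `counts`, `start`, `flagged`, `tc`.
#' @export
fit_cart_layer <- function(tc, config = fit_config(), agneg = NULL,
                           init_tumor = NULL, start = NULL,
                           trust_factor = 2.5) {
  agneg <- agneg %||% isTRUE(grepl("agneg", tc$disease))
  tum <- timecourse_series(tc, "tumor", censored = FALSE)
  init_tumor <- init_tumor %||%
    (if (nrow(tum) && tum$time[1] <= 1) tum$cells[1] else 1e7)
  flagged <- character()
  if (is.null(start)) {
    seg <- segment_phases(tc)
    obs <- .tc_observables(tc)
    sm <- slope_parameter_map(seg, obs, model_state(T_P = init_tumor),
                              tc$regimen, horizon = tc$horizon)
    start <- sm$params
    flagged <- sm$flagged
  }
  free <- c("mu_I", "kappa", "mu_E", "mu_P", "rho", "gamma", "eta",
            "epsilon", "A", "B")
  b <- config$bounds1
  start_vec <- vapply(free, function(nm) {
    min(max(start[[nm]], b[[nm]][1]), b[[nm]][2])
  }, numeric(1))
  # slope-informed bounds: rates pinned by a characteristic phase slope
  # are trusted to a factor around their estimate (the stepwise procedure
  # narrows bounds for the dominant rates before optimising)
  pinned <- setdiff(c("mu_I", "kappa", "mu_E", "mu_P", "rho", "gamma"),
                    flagged)
  for (nm in pinned) {
    b[[nm]] <- c(max(b[[nm]][1], start_vec[[nm]] / trust_factor),
                 min(b[[nm]][2], start_vec[[nm]] * trust_factor))
  }
  if (agneg) {
    free <- c(free, "g0", "T_N0")
    tn_hi <- min(b$T_N0[2], tc$detection_limit)
    b$T_N0 <- c(b$T_N0[1], tn_hi)
    start_vec <- c(start_vec, g0 = 0.05,
                   T_N0 = sqrt(b$T_N0[1] * tn_hi))
  }
  lo <- vapply(free, function(nm) b[[nm]][1], numeric(1))
  hi <- vapply(free, function(nm) b[[nm]][2], numeric(1))
  degenerate <- hi <= lo * (1 + 1e-12)
  make_params <- function(x) {
    g0 <- if (agneg) unname(x["g0"]) else 0
    cart_params(eta = x[["eta"]], mu_I = x[["mu_I"]], kappa = x[["kappa"]],
                mu_E = x[["mu_E"]], epsilon = x[["epsilon"]],
                mu_P = x[["mu_P"]], rho = x[["rho"]], gamma = x[["gamma"]],
                A = x[["A"]], B = x[["B"]], g0 = g0)
  }
  make_init <- function(x) {
    model_state(T_P = init_tumor,
                T_N = if (agneg) unname(x["T_N0"]) else 0)
  }
  pts <- .layer1_points(tc)
  obj_wls <- function(x) {
    wls_objective_layer1(tc, make_params(x), make_init(x))
  }
  obj_log <- function(x) {
    .log_objective_layer1(tc, make_params(x), make_init(x), pts)
  }
  if (all(degenerate)) {
    x <- lo
    val <- obj_wls(x)
    fit <- list(par_bounded = x, value = val, convergence = 0L,
                counts = c(0L, 0L))
  } else {
    x_cur <- start_vec
    n_evals <- 0
    run_nm <- function(x0, active, objective, maxit, reltol = 1e-10) {
      act <- active & !degenerate
      if (!any(act)) return(x0)
      u0 <- .to_unconstrained(x0[act], lo[act], hi[act])
      wrap <- function(u) {
        x <- x0
        x[act] <- .to_bounded(u, lo[act], hi[act])
        objective(x)
      }
      opt <- optim(u0, wrap, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
      n_evals <<- n_evals + opt$counts[1]
      x1 <- x0
      x1[act] <- .to_bounded(opt$par, lo[act], hi[act])
      x1
    }
    shape <- free %in% c("eta", "epsilon", "A", "B", "g0", "T_N0")
    all_free <- rep(TRUE, length(free))
    # alternate shape-only and joint log-scale refinement until the
    # objective plateaus (mirrors the stepwise estimation rationale:
    # slopes pin the rates, shape features pin the rest, then polish)
    f_prev <- obj_log(x_cur)
    for (round in 1:5) {
      x_cur <- run_nm(x_cur, shape, obj_log, config$maxit)
      x_cur <- run_nm(x_cur, all_free, obj_log, config$maxit)
      f_now <- obj_log(x_cur)
      if (is.finite(f_prev) && is.finite(f_now) &&
          f_prev - f_now < 0.02 * abs(f_prev)) break
      f_prev <- f_now
    }
    # deep final refinement of the log objective
    x_cur <- run_nm(x_cur, all_free, obj_log, 2 * config$maxit,
                    reltol = 1e-12)
    # final polish on the reported WLS objective
    x_cur <- run_nm(x_cur, all_free, obj_wls, min(config$maxit, 500),
                    reltol = config$reltol)
    val <- obj_wls(x_cur)
    fit <- list(par_bounded = x_cur, value = val, convergence = 0L,
                counts = c(n_evals, 0L))
  }
  structure(list(
    params = make_params(fit$par_bounded),
    T_N0 = if (agneg) unname(fit$par_bounded["T_N0"]) else 0,
    init_tumor = init_tumor, agneg = agneg,
    objective = fit$value, convergence = fit$convergence,
    counts = fit$counts, start = start, flagged = flagged,
    free = free, tc = tc, config = config), class = "cart_fit")
}

# observables from sampled data (for the slope map): peak/min CAR-T,
# minimum tumour, persister level proxy at the last sample
.tc_observables <- function(tc) {
  cart <- timecourse_series(tc, "cart", censored = FALSE)
  tum <- timecourse_series(tc, "tumor", censored = FALSE)
  i_peak <- which.max(cart$cells)
  pre <- cart[cart$time <= min(5, cart$time[i_peak]), ]
  cmin <- if (nrow(pre)) min(pre$cells) else min(cart$cells)
  cmin_day <- if (nrow(pre)) pre$time[which.min(pre$cells)] else cart$time[1]
  late <- cart[cart$time >= 21, ]
  tum_all <- timecourse_series(tc, "tumor", censored = TRUE)
  tibble::tibble(
    Cmax = max(cart$cells), Cmax_day = cart$time[i_peak],
    Cmin = cmin, Cmin_day = max(cmin_day, 0.5),
    Tmin = if (nrow(tum)) min(tum$cells) else NA_real_,
    Tmin_day = if (nrow(tum)) tum$time[which.min(tum$cells)] else NA_real_,
    # censored tumour points make the observed minimum an upper bound only
    tmin_is_bound = any(tum_all$censored),
    persister_day28 = if (nrow(late)) late$cells[1] else NA_real_)
}

#' @export
print.cart_fit <- function(x, ...) {
  cat("<cart_fit>", x$tc$id, "- WLS objective", signif(x$objective, 4),
      if (x$convergence == 0) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' @export
tidy.cart_fit <- function(x, ...) {
  nm <- x$free
  est <- vapply(nm, function(n) {
    if (n == "T_N0") x$T_N0 else x$params[[n]]
  }, numeric(1))
  start <- vapply(nm, function(n) {
    if (n %in% c("g0", "T_N0")) NA_real_ else x$start[[n]]
  }, numeric(1))
  tibble::tibble(term = nm, estimate = unname(est), start = unname(start))
}

#' @export
glance.cart_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$convergence == 0,
                 n_free = length(x$free),
                 evaluations = unname(x$counts[1]))
}

#' IL-6 residual weights
#'
#' `w_i = w0 + (1 - w0) * IL6_i / max_j(IL6_j)`: the peak observation
#' gets weight 1, the smallest values get the floor `w0`, emphasising the
#' peak (about seven-fold over the minimum at the default
#' `w0 = 0.15`).
#'
#' @param il6 observed IL-6 values (at least one positive).
#' @param w0 weight floor in (0, 1\].
#' @return Weights in `[w0, 1]`.
#' @export
il6_weights <- function(il6, w0 = 0.15) {
  m <- max(il6)
  if (!is.finite(m) || m <= 0) {
    stop("il6_weights: need at least one positive IL-6 value", call. = FALSE)
  }
  w0 + (1 - w0) * il6 / m
}

#' Log-weighted-residual objective for the cytokine layer
#'
#' `LR = ln( sum_i w_i (IL6_sim(t_i) - IL6_i)^2 )` with weights from
#' [il6_weights()].  A numerically zero weighted sum (perfect fit)
#' returns the sentinel `-745` (log of the smallest double), flagged via
#' attribute `perfect = TRUE`.
#'
#' @param observed observed IL-6 values.
#' @param simulated simulated IL-6 at the same times.
#' @param w0 weight floor.
#' @return `LR` (scalar).
#' @export
lr_objective <- function(observed, simulated, w0 = 0.15) {
  w <- il6_weights(observed, w0)
  sse <- sum(w * (simulated - observed)^2)
  if (sse <= .Machine$double.xmin) {
    return(structure(log(.Machine$double.xmin), perfect = TRUE))
  }
  log(sse)
}

#' Patient-specific fixed cytokine quantities
#'
#' The rules that pin four of the twelve cytokine-layer quantities
#' before fitting: activated macrophages start at zero, the IL-6 initial
#' condition is the first observed value, the endogenous production rate
#' is tied to the decay rate through the patient's minimum observed IL-6
#' (`sigma_I = delta_I * min_i IL6_i`, the steady-state floor), and the
#' CD40 half-saturation is fixed at `C = 1e10` cells.
#'
#' @param tc a [patient_timecourse()] with a non-empty IL-6 series.
#' @return List with `M_a0`, `IL6_0`, `sigma_I_per_delta_I`, `C`.
#' @export
fix_cytokine_params <- function(tc) {
  il6 <- timecourse_series(tc, "il6")
  if (!nrow(il6)) {
    stop("fix_cytokine_params: time course has no IL-6 series", call. = FALSE)
  }
  list(M_a0 = 0, IL6_0 = il6$cells[1],
       sigma_I_per_delta_I = min(il6$cells), C = 1e10)
}

# integrate only the cytokine layer, driven by the fixed layer-1
# trajectories supplied as interpolated forcings (the first layer is
# independent of the second, so this is exact up to interpolation on the
# dense grid)
.cytokine_only_sim <- function(q, fixed, M_i0, forcings, times, p) {
  y0 <- c(M_i = M_i0, M_a = fixed$M_a0, IL6 = fixed$IL6_0)
  sol <- tryCatch(
    suppressWarnings(deSolve::lsoda(
      y0, times, func = "derivs_cyto_cartcrs", dllname = "cartcrs",
      initfunc = "initmod_cartcrs", initforc = "initforc_cartcrs",
      forcings = forcings,
      fcontrol = list(method = "linear", rule = 2),
      parms = .parms_vector(p, q),
      rtol = 1e-6, atol = c(1e-3, 1e-3, 1e-8), maxsteps = 10000)),
    error = function(e) NULL)
  if (is.null(sol) || attr(sol, "istate")[1] < 0 ||
      nrow(sol) < length(times)) return(NULL)
  sol
}

#' Fit the macrophage / IL-6 layer
#'
#' Monte-Carlo global search plus local refinement for the eight free
#' cytokine parameters (`sigma_M, delta_M, delta_I, alpha, beta_B,
#' beta_K, beta_C, M_i(0)`), conditional on a fitted (or known) CAR-T /
#' tumour layer.  `n_mc` tuples are drawn log-uniformly within bounds,
#' ranked by the `LR` objective, and the best `n_refine` are polished
#' with bounded Nelder-Mead; the overall best tuple is returned.  Fixed
#' quantities follow [fix_cytokine_params()].  The whole procedure is
#' deterministic given `config$seed`.
#'
#' @param tc a [patient_timecourse()] with an IL-6 series.
#' @param layer1 a `cart_fit`, or a list with `params` ([cart_params()])
#'   and `init` ([model_state()]) describing the known first layer.
#' @param config a [fit_config()].
#' @param variant a [model_variant()] restricting the active activation
#'   mechanisms (default: full DAC model).
#' @param refine_maxit Nelder-Mead budget per refined tuple.
#' @param warm_starts optional list of named parameter tuples added to
#'   the refinement pool (used by [rank_variants()] to seed a variant
#'   with the optima of the variants it nests; coefficients absent from
#'   a tuple start at their lower bound).
#' @return A `cytokine_fit` with `params` ([cytokine_params()]), `M_i0`,
#'   `lr`, `aic`, `n_d`, `k`, `refined` (tibble of refined tuples),
#'   `seed`, `fixed`, `variant`.
#' @export
fit_cytokine_layer <- function(tc, layer1, config = fit_config(),
                               variant = model_variant(c("D", "A", "C")),
                               refine_maxit = 60, warm_starts = list()) {
  fixed <- fix_cytokine_params(tc)
  il6 <- timecourse_series(tc, "il6")
  p <- layer1$params
  init <- if (inherits(layer1, "cart_fit")) {
    model_state(T_P = layer1$init_tumor, T_N = layer1$T_N0)
  } else layer1$init
  horizon <- max(tc$horizon, max(il6$time) + 1)
  base <- simulate_therapy(p, q = NULL, init = init, regimen = tc$regimen,
                           horizon = horizon, grid_step = 0.25)
  forcings <- list(
    cbind(base$data$time, base$data$C_E),
    cbind(base$data$time, base$data$T_P),
    cbind(base$data$time, base$data$T_N))
  sim_times <- sort(unique(c(0, il6$time)))
  idx <- match(il6$time, sim_times)

  free <- c("sigma_M", "delta_M", "delta_I", "alpha",
            setdiff(c("beta_K", "beta_B", "beta_C"), variant$removed_betas),
            "M_i0")
  b <- config$bounds2
  eval_tuple <- function(x) {
    beta <- c(beta_K = 0, beta_B = 0, beta_C = 0)
    for (nm in intersect(names(x), names(beta))) beta[[nm]] <- x[[nm]]
    q <- cytokine_params(
      sigma_M = x[["sigma_M"]], delta_M = x[["delta_M"]],
      sigma_I = x[["delta_I"]] * fixed$sigma_I_per_delta_I,
      delta_I = x[["delta_I"]], alpha = x[["alpha"]],
      beta_B = beta[["beta_B"]], beta_K = beta[["beta_K"]],
      beta_C = beta[["beta_C"]], C = fixed$C)
    sol <- .cytokine_only_sim(q, fixed, x[["M_i0"]], forcings, sim_times, p)
    if (is.null(sol)) return(Inf)
    lr_objective(il6$cells, sol[idx, "IL6"], config$w0)
  }

  lo <- vapply(free, function(nm) b[[nm]][1], numeric(1))
  hi <- vapply(free, function(nm) b[[nm]][2], numeric(1))
  n_mc <- config$n_mc
  draws <- .with_seed(.sub_seed(config$seed, 1), {
    matrix(exp(runif(n_mc * length(free), log(rep(lo, each = n_mc)),
                     log(rep(hi, each = n_mc)))),
           nrow = n_mc, dimnames = list(NULL, free))
  })
  lr_mc <- apply(draws, 1, function(r) eval_tuple(setNames(r, free)))
  ord <- order(lr_mc)
  n_ref <- min(config$n_refine, sum(is.finite(lr_mc)))
  refine_from <- function(x0) {
    u0 <- .to_unconstrained(x0, lo, hi)
    opt <- optim(u0, function(u) eval_tuple(setNames(.to_bounded(u, lo, hi),
                                                     free)),
                 method = "Nelder-Mead",
                 control = list(maxit = refine_maxit, reltol = 1e-8))
    list(x = setNames(.to_bounded(opt$par, lo, hi), free), lr = opt$value)
  }
  refined <- lapply(ord[seq_len(n_ref)], function(i) {
    refine_from(setNames(draws[i, ], free))
  })
  # warm starts (e.g. optima of nested variants, with absent coefficients
  # clamped to the lower bound) join the refinement pool
  for (w in warm_starts) {
    x0 <- setNames(lo, free)
    keep <- intersect(names(w), free)
    x0[keep] <- pmin(pmax(w[keep], lo[keep]), hi[keep])
    refined <- c(refined, list(refine_from(x0)))
  }
  lrs <- vapply(refined, `[[`, numeric(1), "lr")
  # restarted polish of the leading tuples: rebuilding the simplex at the
  # incumbent repeatedly escapes the long degenerate valleys of the
  # 8-parameter landscape, and polishing several leaders guards against
  # the best refined tuple sitting in a shallow basin
  polish_one <- function(cand) {
    for (r in 1:6) {
      u0 <- .to_unconstrained(cand$x, lo, hi)
      polish <- optim(u0, function(u) eval_tuple(setNames(
        .to_bounded(u, lo, hi), free)),
        method = "Nelder-Mead",
        control = list(maxit = 8 * refine_maxit, reltol = 1e-12))
      gain <- cand$lr - polish$value
      if (polish$value < cand$lr) {
        cand <- list(x = setNames(.to_bounded(polish$par, lo, hi), free),
                     lr = polish$value)
      }
      if (!is.finite(gain) || gain < 0.01) break
    }
    cand
  }
  leaders <- order(lrs)[seq_len(min(3, length(lrs)))]
  polished <- lapply(refined[leaders], polish_one)
  best <- polished[[which.min(vapply(polished, `[[`, numeric(1), "lr"))]]
  x <- best$x
  beta <- c(beta_K = 0, beta_B = 0, beta_C = 0)
  for (nm in intersect(names(x), names(beta))) beta[[nm]] <- x[[nm]]
  q_best <- cytokine_params(
    sigma_M = x[["sigma_M"]], delta_M = x[["delta_M"]],
    sigma_I = x[["delta_I"]] * fixed$sigma_I_per_delta_I,
    delta_I = x[["delta_I"]], alpha = x[["alpha"]],
    beta_B = beta[["beta_B"]], beta_K = beta[["beta_K"]],
    beta_C = beta[["beta_C"]], C = fixed$C)
  n_d <- nrow(il6)
  k <- variant$k
  ref_tbl <- tibble::as_tibble(do.call(rbind, lapply(refined, `[[`, "x")))
  ref_tbl$lr <- lrs
  structure(list(
    params = q_best, M_i0 = unname(x[["M_i0"]]), lr = best$lr,
    aic = aic_score(best$lr, k, n_d), n_d = n_d, k = k,
    refined = ref_tbl, seed = config$seed, fixed = fixed,
    variant = variant, layer1 = layer1, free = free,
    mc_best_lr = min(lr_mc)), class = "cytokine_fit")
}

#' @export
print.cytokine_fit <- function(x, ...) {
  cat("<cytokine_fit> variant", x$variant$label, "- LR", signif(x$lr, 4),
      "AIC", signif(x$aic, 5), "(n_d =", x$n_d, ")\n")
  invisible(x)
}

#' @export
tidy.cytokine_fit <- function(x, ...) {
  est <- c(unlist(x$params[x$free[x$free != "M_i0"]]), M_i0 = x$M_i0)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' @export
glance.cytokine_fit <- function(x, ...) {
  tibble::tibble(lr = x$lr, aic = x$aic, n_d = x$n_d, k = x$k,
                 variant = x$variant$label, seed = x$seed)
}

#' Pairwise parameter correlations across the refined tuples
#'
#' Correlation of every parameter pair across the locally refined best
#' fits, plus the median of all pairwise correlations.  Parameters that
#' are constant across the set yield `NA` entries.
#'
#' @param fit a `cytokine_fit` (uses its `refined` table), or the table
#'   itself.
#' @return List with `correlations` (long tibble: `param1`, `param2`,
#'   `r`) and `median_abs` / `median_r` summaries.
#' @export
top_fit_correlations <- function(fit) {
  tbl <- if (inherits(fit, "cytokine_fit")) fit$refined else
    tibble::as_tibble(fit)
  tbl <- tbl[setdiff(names(tbl), "lr")]
  if (nrow(tbl) < 3) {
    stop("top_fit_correlations: need at least 3 refined fits", call. = FALSE)
  }
  nm <- names(tbl)
  pairs <- utils::combn(nm, 2)
  r <- apply(pairs, 2, function(pp) {
    x <- tbl[[pp[1]]]; y <- tbl[[pp[2]]]
    if (var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)
  })
  out <- tibble::tibble(param1 = pairs[1, ], param2 = pairs[2, ], r = r)
  list(correlations = out,
       median_r = median(r, na.rm = TRUE),
       median_abs = median(abs(r), na.rm = TRUE))
}
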