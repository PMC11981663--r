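#' Logarithmic slope of a positive series
#'
#' For a sampled series, pairwise finite differences of `log(y)` between
#' consecutive points, reported at interval midpoints.  For a simulated
#' trajectory the slope of a model compartment is computed analytically as
#' `(dy/dt) / y` from the right-hand side, which avoids differencing
#' error on the dense grid.
#'
#' @param time sample times (days, strictly increasing).
#' @param value strictly positive values.
#' @return Tibble with columns `time` (midpoints) and `slope` (/day,
#'   natural-log scale).
#' @export
log_slope <- function(time, value) {
  if (any(value <= 0)) {
    stop("log_slope: values must be strictly positive (log undefined)",
         call. = FALSE)
  }
  if (length(time) < 2) stop("log_slope: need at least 2 points", call. = FALSE)
  dt <- diff(time)
  tibble::tibble(time = time[-length(time)] + dt / 2,
                 slope = diff(log(value)) / dt)
}

#' Extremal log-slope over a window
#'
#' Minimum or maximum of `d log(y) / dt` over `[t0, t1]`.  This is the
#' characteristic slope of an exponential phase: for `y = c e^(m t)` it
#' returns `m` for either mode.
#'
#' @param time,value the sampled series (value > 0 on the window).
#' @param window numeric `c(t0, t1)`.
#' @param mode `"min"` or `"max"`.
#' @return The extremal slope (/day).
#' @examples
#' t <- seq(0, 5, 0.1)
#' extremal_log_slope(t, exp(-2 * t), c(0, 5), "min")  # -2
#' @export
extremal_log_slope <- function(time, value, window = range(time),
                               mode = c("min", "max")) {
  mode <- match.arg(mode)
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 2) {
    stop("extremal_log_slope: fewer than 2 points in window", call. = FALSE)
  }
  sl <- log_slope(time[keep], value[keep])$slope
  if (mode == "min") min(sl) else max(sl)
}

# analytic log-slope of C_T and T_total along a simulated trajectory
.traj_log_slopes <- function(traj, floor = 1e-6) {
  df <- traj$data
  n <- nrow(df)
  dct <- dtt <- numeric(n)
  for (i in seq_len(n)) {
    s <- pmax(as.numeric(df[i, c("C_I", "C_E", "C_P", "T_P", "T_N")]), 0)
    names(s) <- c("C_I", "C_E", "C_P", "T_P", "T_N")
    d <- cart_tumor_rhs(s, traj$p)
    dct[i] <- sum(d[c("C_I", "C_E", "C_P")])
    dtt[i] <- sum(d[c("T_P", "T_N")])
  }
  tibble::tibble(
    time = df$time,
    cart_slope = dct / pmax(df$C_T, floor),
    tumor_slope = dtt / pmax(df$T_total, floor)
  )
}

#' Segment a simulated course into its response phases
#'
#' Splits the total CAR-T series into distribution, expansion,
#' contraction and persistence phases, and the total tumour series into
#' transient, shrinkage and response phases, reporting each phase's
#' characteristic extremal log-slope.
#'
#' Boundaries: distribution runs from the (first) dose to the first local
#' minimum of total CAR-T cells within 5 days; expansion from that
#' minimum to the global peak; contraction from the peak to the
#' persistence onset, detected as the first time after the most negative
#' post-peak slope where the log-slope rises above half of that slope
#' (a change-point from fast contraction to slow decay); persistence is
#' the remainder.  The tumour transient phase (possibly empty) runs to
#' the tumour maximum, shrinkage to the tumour minimum, and the response
#' phase covers post-minimum regrowth when the tumour is not extinct.
#'
#' Slopes reported: `m_D` (min, distribution), `m_E` (max, expansion),
#' `m_C` (min, contraction), `m_Pst` (max, persistence), `m_T` (max,
#' transient), `m_S` (min, shrinkage), `m_R` (max, response).  On a
#' `cart_trajectory` slopes are analytic; on sampled data they are finite
#' differences.
#'
#' @param x a `cart_trajectory` or a `patient_timecourse`.
#' @param ... passed on between methods.
#' @return A `phase_segmentation`: tibble with columns `compartment`,
#'   `phase`, `t_start`, `t_end`, `slope` (`NA` rows mark absent phases).
#' @export
segment_phases <- function(x, ...) UseMethod("segment_phases")

#' @rdname segment_phases
#' @param extinction_threshold tumour count below which the tumour is
#'   considered extinct (cells, default 1).
#' @export
segment_phases.cart_trajectory <- function(x, extinction_threshold = 1, ...) {
  sl <- .traj_log_slopes(x)
  t <- x$data$time
  cart <- .segment_cart(t, x$data$C_T, sl$cart_slope)
  tum <- .segment_tumor(t, x$data$T_total, sl$tumor_slope,
                        extinction_threshold)
  structure(dplyr::bind_rows(cart, tum),
            class = c("phase_segmentation", class(tibble::tibble())))
}

#' @rdname segment_phases
#' @export
segment_phases.patient_timecourse <- function(x, ...) {
  cart <- timecourse_series(x, "cart", censored = FALSE)
  tum <- timecourse_series(x, "tumor", censored = FALSE)
  seg_c <- if (nrow(cart) >= 4) {
    sl <- log_slope(cart$time, cart$cells)
    slope_at <- approxfun(sl$time, sl$slope, rule = 2)
    .segment_cart(cart$time, cart$cells, slope_at(cart$time),
                  slope_fun = .fd_slope_fun(cart$time, cart$cells))
  } else .empty_cart_seg()
  seg_t <- if (nrow(tum) >= 2 && all(tum$cells > 0)) {
    sl <- log_slope(tum$time, tum$cells)
    slope_at <- approxfun(sl$time, sl$slope, rule = 2)
    .segment_tumor(tum$time, tum$cells, slope_at(tum$time), 1,
                   slope_fun = .fd_slope_fun(tum$time, tum$cells))
  } else .empty_tumor_seg()
  structure(dplyr::bind_rows(seg_c, seg_t),
            class = c("phase_segmentation", class(tibble::tibble())))
}

.phase_row <- function(compartment, phase, t0 = NA_real_, t1 = NA_real_,
                       slope = NA_real_) {
  tibble::tibble(compartment = compartment, phase = phase,
                 t_start = t0, t_end = t1, slope = slope)
}

.empty_cart_seg <- function() {
  dplyr::bind_rows(
    .phase_row("cart", "distribution"), .phase_row("cart", "expansion"),
    .phase_row("cart", "contraction"), .phase_row("cart", "persistence"))
}

.empty_tumor_seg <- function() {
  dplyr::bind_rows(
    .phase_row("tumor", "transient"), .phase_row("tumor", "shrinkage"),
    .phase_row("tumor", "response"))
}

.window_slope <- function(t, slope, t0, t1, mode) {
  keep <- t >= t0 & t <= t1 & is.finite(slope)
  if (!sum(keep)) return(NA_real_)
  if (mode == "min") min(slope[keep]) else max(slope[keep])
}

# on sampled data, phase slopes are extremal finite differences of log(y)
# between consecutive points whose interval lies inside the phase window
.fd_slope_fun <- function(t, y) {
  sl <- log_slope(t, y)
  left <- t[-length(t)]; right <- t[-1]
  function(t0, t1, mode) {
    keep <- left >= t0 - 1e-9 & right <= t1 + 1e-9 & is.finite(sl$slope)
    if (!sum(keep)) return(NA_real_)
    if (mode == "min") min(sl$slope[keep]) else max(sl$slope[keep])
  }
}

.segment_cart <- function(t, ct, slope, slope_fun = NULL) {
  if (is.null(slope_fun)) {
    slope_fun <- function(t0, t1, mode) .window_slope(t, slope, t0, t1, mode)
  }
  i_peak <- which.max(ct)
  # distribution: dose to first local minimum within 5 days
  early <- which(t <= min(5, t[i_peak]))
  i_min <- NA_integer_
  if (length(early) > 2) {
    dy <- diff(ct[early])
    turn <- which(dy[-length(dy)] < 0 & dy[-1] >= 0)
    if (length(turn)) i_min <- early[turn[1] + 1]
  }
  monotone <- is.na(i_min) && i_peak == 1
  if (monotone) {
    # pure decay: single distribution phase
    out <- dplyr::bind_rows(
      .phase_row("cart", "distribution", t[1], t[length(t)],
                 slope_fun(t[1], t[length(t)], "min")),
      .phase_row("cart", "expansion"), .phase_row("cart", "contraction"),
      .phase_row("cart", "persistence"))
    return(out)
  }
  if (is.na(i_min)) i_min <- which.min(ct[seq_len(i_peak)])
  t_min <- t[i_min]; t_peak <- t[i_peak]
  m_D <- slope_fun(t[1], t_min, "min")
  m_E <- if (t_peak > t_min) slope_fun(t_min, t_peak, "max") else NA_real_
  # contraction / persistence change-point
  post <- which(t > t_peak)
  if (length(post) > 2) {
    s_post <- slope[post]
    m_C_raw <- min(s_post, na.rm = TRUE)
    i_mc <- post[which.min(s_post)]
    thresh <- m_C_raw + 0.5 * abs(m_C_raw)
    cand <- post[post > i_mc]
    after <- cand[is.finite(slope[cand]) & slope[cand] > thresh]
    i_onset <- if (length(after)) after[1] else post[length(post)]
    t_onset <- t[i_onset]
    m_C <- slope_fun(t_peak, t_onset, "min")
    m_Pst <- if (t_onset < t[length(t)])
      slope_fun(t_onset, t[length(t)], "max") else NA_real_
    out <- dplyr::bind_rows(
      .phase_row("cart", "distribution", t[1], t_min, m_D),
      .phase_row("cart", "expansion", t_min, t_peak, m_E),
      .phase_row("cart", "contraction", t_peak, t_onset, m_C),
      .phase_row("cart", "persistence", t_onset, t[length(t)], m_Pst))
  } else {
    out <- dplyr::bind_rows(
      .phase_row("cart", "distribution", t[1], t_min, m_D),
      .phase_row("cart", "expansion", t_min, t_peak, m_E),
      .phase_row("cart", "contraction"), .phase_row("cart", "persistence"))
  }
  out
}

.segment_tumor <- function(t, tt, slope, extinction_threshold,
                           slope_fun = NULL) {
  if (is.null(slope_fun)) {
    slope_fun <- function(t0, t1, mode) .window_slope(t, slope, t0, t1, mode)
  }
  if (all(tt < extinction_threshold)) return(.empty_tumor_seg())
  i_max <- which.max(tt)
  alive <- tt >= extinction_threshold
  last_alive <- max(which(alive))
  i_min <- which.min(replace(tt, !alive & seq_along(tt) > 1, Inf))
  # restrict the minimum to after the maximum
  cand <- seq(i_max, last_alive)
  i_min <- cand[which.min(tt[cand])]
  t_max <- t[i_max]; t_min <- t[i_min]
  transient <- if (i_max > 1 && tt[i_max] > tt[1]) {
    .phase_row("tumor", "transient", t[1], t_max,
               slope_fun(t[1], t_max, "max"))
  } else .phase_row("tumor", "transient")
  shrink_start <- if (i_max > 1 && tt[i_max] > tt[1]) t_max else t[1]
  shrinkage <- if (t_min > shrink_start) {
    .phase_row("tumor", "shrinkage", shrink_start, t_min,
               slope_fun(shrink_start, t_min, "min"))
  } else .phase_row("tumor", "shrinkage")
  extinct <- tt[last_alive] < extinction_threshold ||
    last_alive < length(t) || tt[length(t)] <= tt[i_min] * 1.001
  response <- if (!extinct && t[i_min] < t[length(t)]) {
    .phase_row("tumor", "response", t_min, t[length(t)],
               slope_fun(t_min, t[length(t)], "max"))
  } else .phase_row("tumor", "response")
  dplyr::bind_rows(transient, shrinkage, response)
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation>\n")
  NextMethod()
}

#' Plot a phase segmentation
#' @param object a `phase_segmentation`.
#' @param ... unused.
#' @return A ggplot object showing phase windows and slopes.
#' @export
autoplot.phase_segmentation <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$t_start))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                                       y = .data$phase, yend = .data$phase,
                                       colour = .data$slope),
                          linewidth = 3) +
    ggplot2::facet_wrap(~compartment, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL, colour = "log-slope (/day)") +
    ggplot2::theme_minimal()
}

#' Map characteristic slopes and observables to initial parameter values
#'
#' First-order inversion of the phase analysis: the distribution,
#' expansion, contraction and persistence slopes give `mu_I = -m_D`,
#' `mu_E = -m_C`, `kappa = m_E + mu_E`, `mu_P = -m_Pst`; the tumour
#' response (or transient) slope gives `rho`, and the shrinkage slope
#' gives `gamma = rho - m_S`.  The remaining parameters are set from the
#' other shape features: `eta` by 1-D search so the simulated
#' post-distribution CAR-T minimum matches the observed one, `(A, B)` by
#' a bounded log-scale grid search matching `(Cmax, Tmin)`, and `epsilon`
#' by matching the late persistence level.  Missing phases fall back to
#' mid-range defaults and are flagged.
#'
#' @param seg a `phase_segmentation`.
#' @param obs a one-row observables tibble from [observables()].
#' @param init initial state used for the matching simulations.
#' @param regimen dose regimen used for the matching simulations.
#' @param horizon matching-simulation horizon (days).
#' @param defaults named list of fallback values for parameters whose
#'   phase is missing.
#' @param refine logical: run the `eta`, `(A, B)` and `epsilon` matching
#'   searches (default TRUE); otherwise use defaults for those.
#' @return A list with `params` (a [cart_params()]) and `flagged`
#'   (character vector of parameters that fell back to defaults).
#' @export
slope_parameter_map <- function(seg, obs, init, regimen, horizon = 90,
                                defaults = list(eta = 0.2, epsilon = 0.05,
                                                A = 1e7, B = 1e7,
                                                mu_I = 0.5, kappa = 1.0,
                                                mu_E = 0.3, mu_P = 0.01,
                                                rho = 0.15, gamma = 1.0),
                                refine = TRUE) {
  g <- function(phase, comp) {
    r <- seg$slope[seg$phase == phase & seg$compartment == comp]
    if (length(r) == 1 && is.finite(r)) r else NA_real_
  }
  flagged <- character()
  take <- function(value, name, transform = identity) {
    if (is.finite(value)) transform(value) else {
      flagged <<- c(flagged, name)
      defaults[[name]]
    }
  }
  mu_I <- take(g("distribution", "cart"), "mu_I", function(m) max(-m, 1e-4))
  mu_E <- take(g("contraction", "cart"), "mu_E", function(m) max(-m, 1e-4))
  m_E <- g("expansion", "cart")
  kappa <- if (is.finite(m_E)) max(m_E + mu_E, 1e-4) else {
    flagged <- c(flagged, "kappa"); defaults$kappa
  }
  mu_P <- take(g("persistence", "cart"), "mu_P", function(m) max(-m, 1e-5))
  m_R <- g("response", "tumor"); m_T <- g("transient", "tumor")
  rho <- if (is.finite(m_R)) max(m_R, 1e-4) else
    if (is.finite(m_T)) max(m_T, 1e-4) else {
      flagged <- c(flagged, "rho"); defaults$rho
    }
  m_S <- g("shrinkage", "tumor")
  gamma <- if (is.finite(m_S)) max(rho - m_S, 1e-4) else {
    flagged <- c(flagged, "gamma"); defaults$gamma
  }
  base <- cart_params(eta = defaults$eta, mu_I = mu_I, kappa = kappa,
                      mu_E = mu_E, epsilon = defaults$epsilon, mu_P = mu_P,
                      rho = rho, gamma = gamma, A = defaults$A,
                      B = defaults$B)
  if (!refine) {
    flagged <- c(flagged, "eta", "A", "B", "epsilon")
    return(list(params = base, flagged = unique(flagged)))
  }
  p <- base
  p <- .match_eta(p, obs, init, regimen)
  p <- .match_AB(p, obs, init, regimen, horizon)
  p <- .match_epsilon(p, obs, init, regimen, horizon)
  list(params = p, flagged = unique(flagged))
}

.quick_sim <- function(p, init, regimen, horizon, grid_step = 0.5) {
  tryCatch(
    suppressWarnings(
      simulate_therapy(p, q = NULL, init = init, regimen = regimen,
                       horizon = horizon, grid_step = grid_step,
                       rtol = 1e-6, maxsteps = 5000)),
    error = function(e) NULL)
}

.with_par <- function(p, ...) {
  upd <- list(...)
  for (nm in names(upd)) p[[nm]] <- upd[[nm]]
  do.call(cart_params, p[setdiff(names(p), character())])
}

# eta: bisection on log10(eta) so the simulated post-distribution minimum
# matches the observed one (higher eta -> earlier activation -> higher min)
.match_eta <- function(p, obs, init, regimen, lo = 1e-3, hi = 10) {
  target <- obs$Cmin
  if (!is.finite(target) || target <= 0) return(p)
  horizon <- max(obs$Cmin_day * 3, 10)
  f <- function(le) {
    tr <- .quick_sim(.with_par(p, eta = 10^le), init, regimen, horizon, 0.1)
    if (is.null(tr)) return(NA_real_)
    o <- observables(tr)
    log(o$Cmin) - log(target)
  }
  flo <- f(log10(lo)); fhi <- f(log10(hi))
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    grid <- seq(log10(lo), log10(hi), length.out = 9)
    vals <- vapply(grid, function(x) abs(f(x)), numeric(1))
    best <- grid[which.min(replace(vals, !is.finite(vals), Inf))]
    return(.with_par(p, eta = 10^best))
  }
  root <- uniroot(f, c(log10(lo), log10(hi)), tol = 0.01)$root
  .with_par(p, eta = 10^root)
}

# (A, B): coarse log-grid search matching peak CAR-T and minimum tumour
.match_AB <- function(p, obs, init, regimen, horizon,
                      bounds = c(1e4, 1e10), n = 6) {
  if (!is.finite(obs$Cmax) || !is.finite(obs$Tmin)) return(p)
  grid <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = n)
  tmin_floor <- 1
  bound_only <- isTRUE(obs$tmin_is_bound)
  best <- c(Inf, p$A, p$B)
  for (A in grid) for (B in grid) {
    tr <- .quick_sim(.with_par(p, A = A, B = B), init, regimen, horizon, 0.25)
    if (is.null(tr)) next
    o <- observables(tr)
    dT <- log(max(o$Tmin, tmin_floor)) - log(max(obs$Tmin, tmin_floor))
    # when the observed minimum is censoring-limited, only penalise
    # simulations that stay ABOVE it
    if (bound_only && dT < 0) dT <- 0
    err <- (log(o$Cmax) - log(obs$Cmax))^2 + dT^2
    if (is.finite(err) && err < best[1]) best <- c(err, A, B)
  }
  .with_par(p, A = best[2], B = best[3])
}

# epsilon: 1-D log-scale search matching the late-time persistence level
.match_epsilon <- function(p, obs, init, regimen, horizon,
                           bounds = c(1e-4, 1)) {
  # target: persister pool at day 28 (persistence level)
  if (!is.finite(obs$persister_day28) || obs$persister_day28 <= 0) return(p)
  target <- obs$persister_day28
  day <- 28
  f <- function(leps) {
    tr <- .quick_sim(.with_par(p, epsilon = 10^leps), init, regimen,
                     max(horizon, day + 1), 0.25)
    if (is.null(tr)) return(Inf)
    o <- observables(tr)
    v <- o$persister_day28
    if (!is.finite(v) || v <= 0) return(Inf)
    (log(v) - log(target))^2
  }
  opt <- optimize(f, log10(bounds))
  if (is.finite(opt$objective)) .with_par(p, epsilon = 10^opt$minimum) else p
}
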