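#' Simulate the multi-layer therapy model
#'
#' Integrates the CAR-T / tumour layer, optionally coupled to the
#' macrophage / IL-6 layer, over a dense time grid.  Infusion events are
#' implemented as hard integration restarts with a state jump on the
#' injected compartment (no delta functions in the right-hand side).
#' When the cytokine layer is present the activated-macrophage
#' sub-populations (by activation source) and their cumulative activation
#' integrals are integrated alongside the full system, so the
#' source decomposition is exact up to solver tolerance.
#'
#' The integrator is stiffness-switching (`deSolve::lsoda`) with
#' `rtol = 1e-8` and absolute tolerances of 1e-6 cells (1e-8 ng/L for
#' IL-6): populations span roughly twelve orders of magnitude.
#'
#' @param p a [cart_params()].
#' @param q a [cytokine_params()], or `NULL` to simulate the first layer
#'   only.
#' @param init a [model_state()]; the regimen adds to `C_I` on top of it.
#' @param regimen a [dose_regimen()]; all event times must lie before
#'   `horizon`.
#' @param horizon simulation end (days, > 0).
#' @param grid_step dense output step (days, default 0.05 for 1-day-scale
#'   peak-day resolution).
#' @param blocking optional mechanism-blocking window: a list with
#'   `mechanism` (`"damp"`, `"antigen"` or `"cd40"`), `residual` (fraction
#'   of the targeted beta kept inside the window, in \[0,1\]) and `window`
#'   (`c(t_start, t_stop)` days); the beta is piecewise constant with
#'   integration restarts at the window edges.
#' @param gate apply the below-one-cell proliferation gate.
#' @param rtol relative solver tolerance (default 1e-8; fitting loops may
#'   relax it).
#' @param maxsteps solver step budget per output interval; fitting loops
#'   lower it so pathological parameter draws fail fast.
#' @param times optional explicit output times overriding the uniform
#'   grid (objective evaluations only need the observation times).
#' @return A `cart_trajectory`: list with `data` (wide tibble: `time`,
#'   states, totals `C_T`, `T_total`), `p`, `q`, `regimen`, `horizon`.
#' @examples
#' p <- cart_params(eta = 0.2, mu_I = 0.6, kappa = 1.2, mu_E = 0.3,
#'                  epsilon = 0.05, mu_P = 0.01, rho = 0.15, gamma = 1.5,
#'                  A = 1e7, B = 1e7)
#' tr <- simulate_therapy(p, init = model_state(T_P = 1e10),
#'                        regimen = dose_regimen(0, 1e8), horizon = 30)
#' @export
simulate_therapy <- function(p, q = NULL, init = model_state(),
                             regimen = dose_regimen(0, 1e8),
                             horizon = 90, grid_step = 0.05,
                             blocking = NULL, gate = TRUE, rtol = 1e-8,
                             maxsteps = 50000, times = NULL) {
  stopifnot(inherits(p, "cart_params"))
  if (!is.null(q)) stopifnot(inherits(q, "cytokine_params"))
  if (horizon <= 0) stop("simulate_therapy: horizon must be > 0", call. = FALSE)
  if (any(regimen$time >= horizon)) {
    stop("simulate_therapy: regimen times must lie before the horizon",
         call. = FALSE)
  }

  y <- as.numeric(init)[1:8]
  names(y) <- c("C_I", "C_E", "C_P", "T_P", "T_N", "M_i", "M_a", "IL6")
  if (is.null(q)) y <- y[1:5] else {
    y <- c(y, Ma_damp = 0, Ma_antigen = 0, Ma_cd40 = 0,
           J_damp = 0, J_antigen = 0, J_cd40 = 0)
  }

  grid <- if (is.null(times)) {
    seq(0, horizon, by = grid_step)
  } else {
    sort(unique(c(0, times[times <= horizon])))
  }
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)

  breaks <- sort(unique(c(0, regimen$time, horizon)))
  block_active <- function(t0) FALSE
  if (!is.null(blocking)) {
    w <- pmin(pmax(blocking$window, 0), horizon)
    if (w[1] < w[2]) {
      breaks <- sort(unique(c(breaks, w)))
      block_active <- function(t0) t0 >= w[1] && t0 < w[2]
    }
  }

  atol <- rep(1e-6, length(y)); names(atol) <- names(y)
  if ("IL6" %in% names(y)) atol[["IL6"]] <- 1e-8
  out_rows <- list()
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    dosed <- regimen$cells[abs(regimen$time - t0) < 1e-12]
    if (length(dosed)) y[["C_I"]] <- y[["C_I"]] + sum(dosed)
    bs <- c(damp = 1, antigen = 1, cd40 = 1)
    if (block_active(t0)) bs[[blocking$mechanism]] <- blocking$residual
    eps <- 1e-9 * max(1, abs(t1))
    times <- c(t0, grid[grid > t0 + eps & grid < t1 - eps], t1)
    sol <- deSolve::lsoda(
      y = y, times = times, func = "derivs_cartcrs",
      dllname = "cartcrs", initfunc = "initmod_cartcrs",
      parms = .parms_vector(p, q, gate, bs),
      rtol = rtol, atol = atol, maxsteps = maxsteps
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("simulate_therapy: integration failed near t = ",
           signif(sol[nrow(sol), 1], 4), call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% grid & (k == length(breaks) - 1 | sol[, 1] < t1)
    out_rows[[k]] <- sol[keep, , drop = FALSE]
  }
  m <- do.call(rbind, out_rows)
  df <- tibble::as_tibble(as.data.frame(m))
  df <- dplyr::mutate(
    df,
    dplyr::across(-time, ~ pmax(.x, 0)),
    C_T = .data$C_I + .data$C_E + .data$C_P,
    T_total = .data$T_P + .data$T_N
  )
  structure(list(data = df, p = p, q = q, regimen = regimen,
                 horizon = horizon, grid_step = grid_step,
                 blocking = blocking),
            class = "cart_trajectory")
}

#' @export
print.cart_trajectory <- function(x, ...) {
  cat("<cart_trajectory> horizon", x$horizon, "days,",
      nrow(x$data), "grid points,",
      if (is.null(x$q)) "CAR-T/tumour layer only\n" else "full system\n")
  print(utils::head(x$data, 4)); invisible(x)
}

#' Tidy a simulated trajectory into long format
#'
#' @param x a `cart_trajectory`.
#' @param ... unused.
#' @return Long tibble with columns `time`, `variable`, `value`.
#' @export
tidy.cart_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$data, -time, names_to = "variable",
                      values_to = "value")
}

#' Trajectory summary observables
#'
#' Extracts the clinically reported summary quantities of a simulated
#' course: peak CAR-T burden (`Cmax`) and its day, the post-distribution
#' CAR-T minimum, minimum tumour burden (`Tmin`), IL-6 baseline / peak /
#' peak day / fold change, activated-macrophage peak day, tumour and
#' persister burdens at days 28 and 90, CAR-T fold change
#' (`Cmax / dose`), and a relapse flag (total tumour cells exceeding the
#' initial burden at any later time).  Baseline IL-6 is the value at
#' `t = 0`.
#'
#' @param traj a `cart_trajectory`.
#' @param dose total infused cells (defaults to the regimen total).
#' @param detection_limit CAR-T detection limit (cells; informational).
#' @return One-row tibble of observables; day-28/90 fields are `NA` when
#'   the horizon is shorter.
#' @export
observables <- function(traj, dose = total_dose(traj$regimen),
                        detection_limit = 2.5e5) {
  df <- traj$data
  stopifnot(nrow(df) > 0)
  t <- df$time
  i_cmax <- which.max(df$C_T)
  # post-distribution minimum: first local minimum of C_T within 5 days
  # (falls back to the pre-peak minimum)
  cmin <- .post_distribution_min(t, df$C_T, i_cmax)
  at_day <- function(col, d) {
    if (traj$horizon < d) return(NA_real_)
    col[which.min(abs(t - d))]
  }
  i_tmin <- which.min(df$T_total)
  T0 <- df$T_total[1]
  relapse <- any(df$T_total[-1] > T0 & t[-1] > t[i_tmin]) && T0 > 0
  has_il6 <- "IL6" %in% names(df)
  il6_base <- if (has_il6) df$IL6[1] else NA_real_
  i_il6 <- if (has_il6) which.max(df$IL6) else NA_integer_
  i_ma <- if (has_il6) which.max(df$M_a) else NA_integer_
  tibble::tibble(
    Cmax = df$C_T[i_cmax],
    Cmax_day = t[i_cmax],
    Cmin = cmin$value,
    Cmin_day = cmin$day,
    cart_fold_change = df$C_T[i_cmax] / dose,
    Tmin = df$T_total[i_tmin],
    Tmin_day = t[i_tmin],
    tumor_day28 = at_day(df$T_total, 28),
    tumor_day90 = at_day(df$T_total, 90),
    persister_day28 = at_day(df$C_P, 28),
    persister_day90 = at_day(df$C_P, 90),
    il6_baseline = il6_base,
    il6_peak = if (has_il6) df$IL6[i_il6] else NA_real_,
    il6_peak_day = if (has_il6) t[i_il6] else NA_real_,
    il6_fold_change = if (has_il6 && il6_base > 0)
      df$IL6[i_il6] / il6_base else NA_real_,
    macrophage_peak_day = if (has_il6) t[i_ma] else NA_real_,
    relapse = relapse,
    dose = dose,
    detection_limit = detection_limit
  )
}

.post_distribution_min <- function(t, y, i_peak) {
  early <- which(t <= 5)
  idx <- NA_integer_
  if (length(early) > 2) {
    dy <- diff(y[early])
    turn <- which(dy[-length(dy)] < 0 & dy[-1] >= 0)
    if (length(turn)) idx <- early[turn[1] + 1]
  }
  if (is.na(idx)) {
    pre <- seq_len(max(i_peak - 1, 1))
    idx <- pre[which.min(y[pre])]
  }
  list(value = y[idx], day = t[idx])
}

#' Plot a simulated trajectory
#'
#' Log-scale panels for total CAR-T cells, tumour burden and (when the
#' cytokine layer is simulated) IL-6 and macrophage compartments.
#'
#' @param object a `cart_trajectory`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cart_trajectory <- function(object, ...) {
  keep <- intersect(c("C_T", "T_total", "IL6", "M_a"), names(object$data))
  long <- tidyr::pivot_longer(object$data[c("time", keep)], -time,
                              names_to = "variable", values_to = "value")
  long$value <- pmax(long$value, 1e-2)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}
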