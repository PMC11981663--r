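#' Counterfactual intervention specification
#'
#' Describes one of the three intervention families explored on fitted
#' patients: scaling the CAR-T dose (`dose_scale`), scaling the initial
#' tumour burden (`tumor_scale`), or fractionally blocking one
#' macrophage-activation mechanism inside a time window
#' (`mechanism_block`, e.g. an anti-CD40 antibody modelled as the
#' targeted beta reduced to `factor` of its value while the block is
#' active).
#'
#' @param kind `"dose_scale"`, `"tumor_scale"` or `"mechanism_block"`.
#' @param factor scale factor (> 0) or, for blocks, the residual
#'   fraction of the targeted beta in \[0, 1\].
#' @param mechanism for blocks: `"damp"`, `"antigen"` or `"cd40"`.
#' @param window for blocks: `c(t_start, t_stop)` in days.
#' @return An `intervention` list.
#' @export
intervention <- function(kind = c("dose_scale", "tumor_scale",
                                  "mechanism_block"),
                         factor = 1, mechanism = NULL, window = NULL) {
  kind <- match.arg(kind)
  if (kind == "mechanism_block") {
    if (factor < 0 || factor > 1) {
      stop("intervention: block residual fraction must be in [0, 1]",
           call. = FALSE)
    }
    if (is.null(mechanism) || !mechanism %in% c("damp", "antigen", "cd40")) {
      stop("intervention: blocks need mechanism damp/antigen/cd40",
           call. = FALSE)
    }
    if (is.null(window) || length(window) != 2 || window[1] > window[2]) {
      stop("intervention: blocks need window c(t_start, t_stop)",
           call. = FALSE)
    }
  } else if (factor <= 0) {
    stop("intervention: scale factor must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, factor = factor, mechanism = mechanism,
                 window = window), class = "intervention")
}

# reference + counterfactual simulation inputs from a fitted patient or
# an explicit list(p, q, init, regimen, horizon)
.scenario_inputs <- function(fit) {
  if (inherits(fit, "cytokine_fit")) {
    l1 <- fit$layer1
    init <- if (inherits(l1, "cart_fit")) {
      model_state(T_P = l1$init_tumor, T_N = l1$T_N0,
                  M_i = fit$M_i0, IL6 = fit$fixed$IL6_0)
    } else {
      s <- l1$init
      model_state(T_P = s[["T_P"]], T_N = s[["T_N"]], M_i = fit$M_i0,
                  IL6 = fit$fixed$IL6_0)
    }
    tc <- if (inherits(l1, "cart_fit")) l1$tc else NULL
    list(p = l1$params, q = fit$params, init = init,
         regimen = if (!is.null(tc)) tc$regimen else l1$regimen,
         horizon = if (!is.null(tc)) tc$horizon else 90)
  } else {
    stopifnot(all(c("p", "init", "regimen") %in% names(fit)))
    list(p = fit$p, q = fit$q %||% NULL, init = fit$init,
         regimen = fit$regimen, horizon = fit$horizon %||% 90)
  }
}

#' Run one counterfactual scenario
#'
#' Simulates the reference system and the intervened system and compares
#' their observables.  Dose scaling multiplies every infusion event;
#' tumour scaling multiplies the initial antigen-positive (and
#' antigen-negative) burden; mechanism blocking multiplies the targeted
#' beta by the residual fraction inside the window, with integration
#' restarts at the window edges.
#'
#' @param fit a `cytokine_fit`, or a list with `p`, `q`, `init`,
#'   `regimen` (and optionally `horizon`) specifying the patient.
#' @param spec an [intervention()].
#' @param grid_step simulation step (days).
#' @return A `scenario_outcome`: list with `reference` and
#'   `counterfactual` observables (one-row tibbles) and `delta`, a
#'   one-row tibble of headline contrasts (IL-6 peak reduction %, Cmax
#'   ratio, peak-day shifts, day-28/90 tumour and persister changes).
#' @export
run_scenario <- function(fit, spec, grid_step = 0.05) {
  inp <- .scenario_inputs(fit)
  ref <- simulate_therapy(inp$p, inp$q, inp$init, inp$regimen,
                          horizon = inp$horizon, grid_step = grid_step)
  cf <- .apply_intervention(inp, spec, grid_step)
  o_ref <- observables(ref)
  o_cf <- observables(cf, dose = o_ref$dose)
  delta <- tibble::tibble(
    il6_peak_reduction_pct =
      100 * (1 - o_cf$il6_peak / o_ref$il6_peak),
    il6_fold_ratio = o_cf$il6_fold_change / o_ref$il6_fold_change,
    cmax_ratio = o_cf$Cmax / o_ref$Cmax,
    cmax_day_shift = o_cf$Cmax_day - o_ref$Cmax_day,
    il6_peak_day_shift = o_cf$il6_peak_day - o_ref$il6_peak_day,
    tumor_day28_ratio = o_cf$tumor_day28 / o_ref$tumor_day28,
    tumor_day90_ratio = o_cf$tumor_day90 / o_ref$tumor_day90,
    persister_day28_ratio = o_cf$persister_day28 / o_ref$persister_day28,
    persister_day90_ratio = o_cf$persister_day90 / o_ref$persister_day90)
  structure(list(reference = o_ref, counterfactual = o_cf, delta = delta,
                 spec = spec, ref_traj = ref, cf_traj = cf),
            class = "scenario_outcome")
}

.apply_intervention <- function(inp, spec, grid_step) {
  p <- inp$p; q <- inp$q; init <- inp$init; regimen <- inp$regimen
  blocking <- NULL
  if (spec$kind == "dose_scale") {
    regimen <- dose_regimen(regimen$time, regimen$cells * spec$factor)
  } else if (spec$kind == "tumor_scale") {
    init[["T_P"]] <- init[["T_P"]] * spec$factor
    init[["T_N"]] <- init[["T_N"]] * spec$factor
  } else {
    w <- spec$window
    if (w[2] > inp$horizon) {
      warning("run_scenario: blocking window truncated at the horizon")
      w[2] <- inp$horizon
    }
    blocking <- list(mechanism = spec$mechanism, residual = spec$factor,
                     window = w)
  }
  simulate_therapy(p, q, init, regimen, horizon = inp$horizon,
                   grid_step = grid_step, blocking = blocking)
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat("<scenario_outcome>", x$spec$kind, "factor", x$spec$factor, "\n")
  print(x$delta); invisible(x)
}

#' Grid of mechanism-blocking schedules
#'
#' Sweeps blocking start days and stop offsets (days relative to the
#' reference CAR-T peak) for one mechanism and residual fraction, and
#' reports the IL-6 peak reduction of every combination.  Stop times are
#' resolved against the reference simulation's CAR-T peak day, since a
#' clinical schedule cannot depend on the counterfactual's own peak.
#' When several fits are given the mean reduction across the cohort is
#' appended.
#'
#' @param fits one fit or a list of fits (as in [run_scenario()]).
#' @param mechanism blocked mechanism.
#' @param residual residual fraction of the beta inside the window.
#' @param start_days vector of block start days (>= 0).
#' @param stop_offsets vector of offsets (days) added to the reference
#'   CAR-T peak day to give the block stop.
#' @param grid_step simulation step.
#' @return Tibble `patient`, `start_day`, `stop_offset`, `stop_day`,
#'   `il6_peak_reduction_pct`, `valid`.
#' @export
blocking_grid <- function(fits, mechanism = "cd40", residual = 0.5,
                          start_days = 0:10, stop_offsets = c(-5, 0, 5),
                          grid_step = 0.1) {
  if (inherits(fits, c("cytokine_fit")) || !is.null(fits$p)) {
    fits <- list(fits)
  }
  rows <- purrr::imap(fits, function(fit, idx) {
    inp <- .scenario_inputs(fit)
    ref <- simulate_therapy(inp$p, inp$q, inp$init, inp$regimen,
                            horizon = inp$horizon, grid_step = grid_step)
    peak_day <- observables(ref)$Cmax_day
    grid <- tidyr::expand_grid(start_day = start_days,
                               stop_offset = stop_offsets)
    grid$stop_day <- pmin(peak_day + grid$stop_offset, inp$horizon)
    grid$valid <- grid$start_day <= grid$stop_day
    red <- purrr::pmap_dbl(grid, function(start_day, stop_offset, stop_day,
                                          valid) {
      if (!valid) return(NA_real_)
      sc <- run_scenario(fit, intervention("mechanism_block",
                                           factor = residual,
                                           mechanism = mechanism,
                                           window = c(start_day, stop_day)),
                         grid_step = grid_step)
      sc$delta$il6_peak_reduction_pct
    })
    grid$il6_peak_reduction_pct <- red
    grid$patient <- as.character(idx)
    grid
  })
  out <- dplyr::bind_rows(rows)
  out[c("patient", "start_day", "stop_offset", "stop_day",
        "il6_peak_reduction_pct", "valid")]
}

#' Cohort-level correlation table of fitted observables
#'
#' Linear-fit R-squared for the canonical scatter pairs of the cohort
#' analysis: IL-6 fold change against dose, initial tumour burden, CAR-T
#' fold change and IL-6 peak day; day-28 against day-90 tumour burden;
#' plus the peak-day gaps (CAR-T minus IL-6, IL-6 minus macrophage).
#' Pairs with degenerate variance report `NA`.
#'
#' @param obs_tbl tibble of per-patient observables (rows = patients),
#'   e.g. built by binding [observables()] rows; must contain a column
#'   `T0` with the initial tumour burden.
#' @return List with `pairs` (tibble: x, y, r_squared, p_value, n) and
#'   `gaps` (tibble of peak-day gap summaries).
#' @export
cohort_metrics <- function(obs_tbl) {
  stopifnot(nrow(obs_tbl) >= 3)
  pair_list <- list(
    c("dose", "il6_fold_change"),
    c("T0", "il6_fold_change"),
    c("cart_fold_change", "il6_fold_change"),
    c("il6_peak_day", "il6_fold_change"),
    c("cart_fold_change", "tumor_day28"),
    c("cart_fold_change", "tumor_day90"),
    c("tumor_day28", "tumor_day90"))
  rows <- purrr::map(pair_list, function(pp) {
    x <- obs_tbl[[pp[1]]]; y <- obs_tbl[[pp[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) {
      return(tibble::tibble(x = pp[1], y = pp[2], r_squared = NA_real_,
                            p_value = NA_real_, n = sum(ok)))
    }
    # an exactly collinear pair is legitimate input; silence the
    # perfect-fit warning from summary.lm
    m <- suppressWarnings(summary(lm(y[ok] ~ x[ok])))
    tibble::tibble(x = pp[1], y = pp[2], r_squared = m$r.squared,
                   p_value = stats::coef(m)[2, 4], n = sum(ok))
  })
  gaps <- tibble::tibble(
    gap = c("cart_minus_il6_peak_day", "il6_minus_macrophage_peak_day"),
    mean = c(mean(obs_tbl$Cmax_day - obs_tbl$il6_peak_day, na.rm = TRUE),
             mean(obs_tbl$il6_peak_day - obs_tbl$macrophage_peak_day,
                  na.rm = TRUE)),
    min = c(min(obs_tbl$Cmax_day - obs_tbl$il6_peak_day, na.rm = TRUE),
            min(obs_tbl$il6_peak_day - obs_tbl$macrophage_peak_day,
                na.rm = TRUE)),
    max = c(max(obs_tbl$Cmax_day - obs_tbl$il6_peak_day, na.rm = TRUE),
            max(obs_tbl$il6_peak_day - obs_tbl$macrophage_peak_day,
                na.rm = TRUE)))
  list(pairs = dplyr::bind_rows(rows), gaps = gaps)
}
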