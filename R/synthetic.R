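# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept below 2^31
.sub_seed <- function(seed, k) (as.numeric(seed) * 7919 + 104729 * k) %% 2147483587

.lunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Virtual-patient archetypes
#'
#' Defines the sampling ranges, initial-condition rules, clinical sampling
#' schedule, noise model and reporting-unit conventions for each class of
#' virtual patient: complete responders (`responder_cr`), partial
#' responders (`responder_pr`), antigen-positive relapse
#' (`agpos_relapse`), antigen-negative relapse (`agneg_relapse`) and a
#' high-inflammation class (`high_crs`) with strong CD40-driven macrophage
#' activation.
#'
#' Parameter ranges are log-uniform and calibrated so that noiseless
#' cohorts reproduce the canonical qualitative orderings of the system:
#' the IL-6 peak precedes the CAR-T peak, activated macrophages peak
#' before IL-6, and DAMP-, antigen- and CD40-activated macrophage
#' sub-populations peak in that order.
#'
#' @param label archetype name.
#' @return A `patient_archetype` list with elements `label`, `ranges`
#'   (named list of `c(lo, hi)`), `schedule` (days), `cv` (lognormal CV
#'   per series), `horizon`, `units`, `detection_limit`.
#' @export
patient_archetype <- function(label = c("responder_cr", "responder_pr",
                                        "agpos_relapse", "agneg_relapse",
                                        "high_crs")) {
  label <- match.arg(label)
  ranges <- list(
    mu_I = c(0.3, 1.2),
    net_expansion = c(0.6, 1.4),   # kappa - mu_E
    mu_E = c(0.2, 0.5),
    mu_P = c(0.003, 0.02),
    eta = c(0.05, 0.5),
    epsilon = c(0.01, 0.06),
    A = c(1e6, 1e8),
    B = c(1e6, 1e8),
    rho = c(0.08, 0.25),
    gamma = c(1.2, 2.5),
    dose = c(5e7, 5e8),
    T_P0 = c(5e9, 1e11),
    g0 = c(0, 0),
    T_N0 = c(0, 0),
    # cytokine layer
    M_i0 = c(5e9, 3e10),
    delta_M = c(0.2, 0.35),
    sigma_M_frac = c(0.25, 0.5),   # sigma_M as fraction of delta_M * M_i0
    delta_I = c(2, 8),
    il6_baseline = c(2, 10),
    alpha = c(2e-7, 1e-6),
    # DAMP trigger drawn as its initial activation scale beta_K * T_P(0)
    # (/day), so the trigger strength is comparable across tumour burdens
    damp_rate0 = c(0.7, 2),
    beta_B = c(1e-11, 5e-11),
    beta_C = c(5e-9, 2e-8)
  )
  if (label == "responder_pr") {
    ranges$gamma <- c(0.8, 1.4)
    ranges$T_P0 <- c(1e9, 2e10)
  }
  if (label == "agpos_relapse") {
    # antigen-positive relapse requires loss of CAR-T persistence: fast
    # expander contraction, little memory formation, short-lived persisters
    ranges$gamma <- c(0.5, 0.8)
    ranges$rho <- c(0.15, 0.25)
    ranges$mu_E <- c(0.55, 0.9)
    ranges$epsilon <- c(0.002, 0.01)
    ranges$mu_P <- c(0.05, 0.2)
    ranges$T_P0 <- c(2e9, 1e10)
  }
  if (label == "agneg_relapse") {
    ranges$g0 <- c(0.02, 0.1)
    ranges$T_N0 <- c(1e4, 2.4e5)   # seeded below the 2.5e5-cell detection limit
    ranges$rho <- c(0.18, 0.3)
    ranges$T_P0 <- c(2e9, 2e10)
  }
  if (label == "high_crs") {
    ranges$T_P0 <- c(2e10, 1e11)
    ranges$beta_C <- c(1e-8, 4e-8)
  }
  structure(list(
    label = label, ranges = ranges,
    schedule = c(0, 1, 2, 3, 5, 7, 10, 14, 21, 28, 45, 60, 90),
    cv = c(cart = 0.20, tumor = 0.15, il6 = 0.25),
    horizon = 90,
    units = c(cart = "copies/ug", tumor = "%blasts", il6 = "ng/L"),
    detection_limit = 2.5e5
  ), class = "patient_archetype")
}

#' Sample mechanistic parameters for a virtual patient
#'
#' Log-uniform draws within the archetype ranges, with archetype
#' constraints enforced by construction: responders draw the kill rate
#' well above the tumour growth rate, antigen-negative relapse patients
#' draw a positive antigen-negative seed below the detection limit and a
#' small residual kill fraction `g0`.
#'
#' @param archetype a [patient_archetype()] or its label.
#' @param seed integer seed; the same seed reproduces the draw exactly.
#' @return List with `p` ([cart_params()]), `q` ([cytokine_params()]),
#'   `init` ([model_state()]) and `regimen` ([dose_regimen()]).
#' @export
sample_patient_params <- function(archetype, seed) {
  if (is.character(archetype)) archetype <- patient_archetype(archetype)
  r <- archetype$ranges
  .with_seed(seed, {
    draw <- function(nm) {
      b <- r[[nm]]
      if (b[1] <= 0) {
        if (b[2] <= 0) 0 else runif(1, b[1], b[2])
      } else .lunif(1, b[1], b[2])
    }
    mu_E <- draw("mu_E")
    kappa <- mu_E + draw("net_expansion")
    delta_M <- draw("delta_M")
    delta_I <- draw("delta_I")
    M_i0 <- draw("M_i0")
    il6_0 <- draw("il6_baseline")
    T_P0 <- draw("T_P0")
    p <- cart_params(
      eta = draw("eta"), mu_I = draw("mu_I"), kappa = kappa, mu_E = mu_E,
      epsilon = draw("epsilon"), mu_P = draw("mu_P"), rho = draw("rho"),
      gamma = draw("gamma"), A = draw("A"), B = draw("B"),
      g0 = draw("g0"))
    q <- cytokine_params(
      # lymphodepleting pre-conditioning leaves the circulating monocyte
      # pool above its production steady state, so replenishment runs at a
      # fraction of delta_M * M_i(0)
      sigma_M = draw("sigma_M_frac") * delta_M * M_i0,
      delta_M = delta_M,
      sigma_I = delta_I * il6_0,         # baseline IL-6 at steady state
      delta_I = delta_I,
      alpha = draw("alpha"),
      beta_B = draw("beta_B"), beta_K = draw("damp_rate0") / T_P0,
      beta_C = draw("beta_C"))
    init <- model_state(T_P = T_P0, T_N = draw("T_N0"),
                        M_i = M_i0, IL6 = il6_0)
    regimen <- dose_regimen(0, draw("dose"))
    list(p = p, q = q, init = init, regimen = regimen)
  })
}

#' Generate one virtual patient
#'
#' Simulates the full system with sampled (or supplied) parameters,
#' samples it at the archetype's clinical schedule, applies multiplicative
#' lognormal noise per series, converts to the archetype's reporting
#' units (CAR-T as transgene copies/ug DNA, tumour as %blasts via the WBC
#' assumption, IL-6 in ng/L) and censors CAR-T values below the detection
#' limit and tumour values at approximately zero %blasts.  Censored rows
#' carry the detection limit as value.
#'
#' @param archetype a [patient_archetype()] or label.
#' @param seed integer seed; regenerating with the same seed reproduces
#'   the patient bit-identically.
#' @param truth optional parameter set from [sample_patient_params()]; by
#'   default drawn from the archetype under `seed`.
#' @param noise logical; `FALSE` produces noise-free sampling (values are
#'   then exactly the model solution after unit conversion).
#' @param grid_step simulation output step (days).
#' @param cv optional named vector overriding the archetype noise CVs,
#'   e.g. `c(cart = 0.1, tumor = 0.1, il6 = 0.1)`.
#' @return A `synthetic_patient`: list with `tc`
#'   ([patient_timecourse()]), `truth`, `trajectory`, `archetype`,
#'   `seed`.
#' @export
generate_patient <- function(archetype, seed, truth = NULL, noise = TRUE,
                             grid_step = 0.05, cv = NULL) {
  if (is.character(archetype)) archetype <- patient_archetype(archetype)
  if (!is.null(cv)) archetype$cv[names(cv)] <- cv
  # degenerate draws (solver blow-up, unphysical CAR-T burden, extinction
  # before the second sample) are regenerated from a derived seed
  attempt <- 0
  repeat {
    seed_k <- if (attempt == 0) seed else .sub_seed(seed, attempt)
    truth_k <- truth %||% sample_patient_params(archetype, seed_k)
    traj <- tryCatch(
      simulate_therapy(truth_k$p, truth_k$q, truth_k$init, truth_k$regimen,
                       horizon = archetype$horizon, grid_step = grid_step),
      error = function(e) NULL)
    ok <- !is.null(traj) && max(traj$data$C_T) < 1e13 &&
      traj$data$C_T[which.min(abs(traj$data$time - archetype$schedule[2]))] > 0
    if (ok || !is.null(truth) || attempt >= 20) break
    attempt <- attempt + 1
  }
  if (is.null(traj)) {
    stop("generate_patient: could not simulate a valid patient", call. = FALSE)
  }
  truth <- truth_k
  sched <- archetype$schedule[archetype$schedule <= archetype$horizon]
  ctx <- unit_context()
  at <- function(col) {
    approxfun(traj$data$time, traj$data[[col]])(sched)
  }
  noisy <- function(x, cv) {
    if (!noise || cv <= 0) return(x)
    sdlog <- sqrt(log(1 + cv^2))
    x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  .with_seed(.sub_seed(seed, 97), {
    cart_cells <- noisy(at("C_T"), archetype$cv[["cart"]])
    tumor_cells <- noisy(at("T_total"), archetype$cv[["tumor"]])
    il6_vals <- noisy(at("IL6"), archetype$cv[["il6"]])
    dl <- archetype$detection_limit
    cart_cens <- cart_cells < dl
    cart_rep <- convert_units(ifelse(cart_cens, dl, cart_cells),
                              "cells", archetype$units[["cart"]], ctx)
    pct <- convert_units(tumor_cells, "cells", "%blasts", ctx)
    tum_cens <- pct < 0.01          # %blasts indistinguishable from zero
    tum_rep <- ifelse(tum_cens, 0.01, pct)
    data <- dplyr::bind_rows(
      tibble::tibble(series = "cart", time = sched, value = cart_rep,
                     unit = archetype$units[["cart"]], censored = cart_cens),
      tibble::tibble(series = "tumor", time = sched, value = tum_rep,
                     unit = archetype$units[["tumor"]], censored = tum_cens),
      tibble::tibble(series = "il6", time = sched, value = il6_vals,
                     unit = archetype$units[["il6"]],
                     censored = FALSE)
    )
    tc <- patient_timecourse(
      id = sprintf("%s_%d", archetype$label, seed), data = data,
      regimen = truth$regimen, disease = archetype$label,
      detection_limit = dl, horizon = archetype$horizon,
      il6_baseline = il6_vals[1], ctx = ctx)
    structure(list(tc = tc, truth = truth, trajectory = traj,
                   archetype = archetype$label, seed = seed),
              class = "synthetic_patient")
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("<synthetic_patient>", x$tc$id, "\n")
  print(x$tc); invisible(x)
}

#' Generate a virtual cohort
#'
#' Deterministic per-patient sub-seeds are derived from the master seed;
#' archetype labels are assigned in proportion to `mix`.
#'
#' @param n cohort size.
#' @param mix named numeric vector of archetype fractions (must sum
#'   to 1), e.g. `c(responder_cr = 0.76, agneg_relapse = 0.24)`.
#' @param seed master seed.
#' @param noise logical, passed to [generate_patient()].
#' @param grid_step simulation step, passed to [generate_patient()].
#' @param cv optional noise-CV override, passed to [generate_patient()].
#' @return List of `synthetic_patient` objects with a `manifest`
#'   attribute (tibble: id, archetype, seed) usable as ground truth.
#' @export
generate_cohort <- function(n, mix = c(responder_cr = 1), seed = 1,
                            noise = TRUE, grid_step = 0.05, cv = NULL) {
  stopifnot(n >= 1, abs(sum(mix) - 1) < 1e-8)
  counts <- floor(mix * n)
  while (sum(counts) < n) {
    i <- which.max(mix * n - counts)
    counts[i] <- counts[i] + 1
  }
  labels <- rep(names(counts), counts)
  patients <- lapply(seq_len(n), function(k) {
    generate_patient(labels[k], .sub_seed(seed, k), noise = noise,
                     grid_step = grid_step, cv = cv)
  })
  manifest <- tibble::tibble(
    id = vapply(patients, function(s) s$tc$id, character(1)),
    archetype = labels,
    seed = vapply(patients, function(s) s$seed, numeric(1)))
  attr(patients, "manifest") <- manifest
  patients
}
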