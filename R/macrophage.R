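#' Decompose activated macrophages by activation source
#'
#' Splits the activated-macrophage pool into DAMP-activated,
#' antigen-activated and CD40-activated sub-populations.  The
#' sub-population ODEs `dMa_j/dt = h_j M_i - delta_M Ma_j` are linear in
#' the full-system solution and are integrated together with it (see
#' [simulate_therapy()]), so the identity `Ma_1 + Ma_2 + Ma_3 = M_a`
#' holds to solver tolerance.  Cumulative activation per mechanism is
#' the integral of `h_j M_i` from 0 to `t_F`.
#'
#' @param traj a `cart_trajectory` simulated with the cytokine layer.
#' @param t_F end time for the cumulative activation integrals (days;
#'   default: the simulation horizon).
#' @return An `activation_decomposition`: list with `trajectories`
#'   (tibble: time, Ma_damp, Ma_antigen, Ma_cd40, M_a), `summary`
#'   (tibble: mechanism, peak_day, peak_cells, cumulative, fraction),
#'   `t_F`.
#' @export
decompose_activation <- function(traj, t_F = traj$horizon) {
  if (!"M_a" %in% names(traj$data)) {
    stop("decompose_activation: trajectory lacks the macrophage layer",
         call. = FALSE)
  }
  d <- traj$data
  mech <- c(damp = "Ma_damp", antigen = "Ma_antigen", cd40 = "Ma_cd40")
  ints <- c(damp = "J_damp", antigen = "J_antigen", cd40 = "J_cd40")
  i_F <- which.min(abs(d$time - t_F))
  cum <- vapply(ints, function(cl) d[[cl]][i_F], numeric(1))
  total <- sum(cum)
  summary <- tibble::tibble(
    mechanism = names(mech),
    peak_day = vapply(mech, function(cl) d$time[which.max(d[[cl]])],
                      numeric(1)),
    peak_cells = vapply(mech, function(cl) max(d[[cl]]), numeric(1)),
    cumulative = unname(cum),
    fraction = if (total > 0) unname(cum) / total else NA_real_)
  structure(list(
    trajectories = d[c("time", unname(mech), "M_a")],
    summary = summary, t_F = d$time[i_F]),
    class = "activation_decomposition")
}

#' @export
print.activation_decomposition <- function(x, ...) {
  cat("<activation_decomposition> t_F =", x$t_F, "days\n")
  print(x$summary); invisible(x)
}

#' @export
tidy.activation_decomposition <- function(x, ...) x$summary

#' Plot an activation decomposition
#' @param object an `activation_decomposition`.
#' @param ... unused.
#' @return A ggplot of the three sub-populations over time.
#' @export
autoplot.activation_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectories, -time,
                              names_to = "population", values_to = "cells")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$cells,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Ordered timeline of activation and response peaks
#'
#' Peak days of the three activated-macrophage sub-populations, total
#' activated macrophages, IL-6 and total CAR-T cells, ordered in time.
#' Identically-zero sub-populations are excluded and flagged; ties keep
#' the mechanism order DAMP, antigen, CD40.
#'
#' @param decomp an `activation_decomposition`.
#' @param traj the `cart_trajectory` it came from.
#' @return Tibble `event`, `peak_day` sorted by peak day, with attribute
#'   `excluded` naming flat sub-populations.
#' @export
activation_timeline <- function(decomp, traj) {
  s <- decomp$summary
  flat <- s$mechanism[s$peak_cells <= 0]
  s <- s[s$peak_cells > 0, ]
  d <- traj$data
  events <- tibble::tibble(
    event = c(paste0("macrophages_", s$mechanism), "il6", "cart"),
    peak_day = c(s$peak_day, d$time[which.max(d$IL6)],
                 d$time[which.max(d$C_T)]))
  events <- events[order(events$peak_day), ]
  attr(events, "excluded") <- flat
  events
}

#' Simulate with a subset of activation mechanisms
#'
#' Re-simulates the full system with the beta coefficients outside the
#' requested subset set to zero, e.g. to ask what IL-6 kinetics each
#' mechanism would produce on its own.
#'
#' @param p a [cart_params()].
#' @param q a [cytokine_params()].
#' @param init initial [model_state()].
#' @param regimen a [dose_regimen()].
#' @param mechanisms character subset of `c("damp", "antigen", "cd40")`;
#'   empty gives the baseline-only simulation.
#' @param ... passed to [simulate_therapy()].
#' @return A `cart_trajectory`.
#' @export
single_mechanism_simulation <- function(p, q, init, regimen,
                                        mechanisms = character(), ...) {
  stopifnot(all(mechanisms %in% c("damp", "antigen", "cd40")))
  q2 <- q
  if (!"damp" %in% mechanisms) q2$beta_K <- 0
  if (!"antigen" %in% mechanisms) q2$beta_B <- 0
  if (!"cd40" %in% mechanisms) q2$beta_C <- 0
  simulate_therapy(p, q2, init, regimen, ...)
}
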