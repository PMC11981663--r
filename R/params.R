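#' Mechanistic parameters of the CAR-T / tumour layer
#'
#' Constructs and validates the rate constants of the first model layer:
#' three CAR-T phenotypes (injected, expander, persister) interacting with
#' antigen-positive and, optionally, antigen-negative tumour cells.
#'
#' All rates are per day, populations are absolute cell counts in a 5 L
#' blood compartment.  `K` (tumour carrying capacity) and `theta`
#' (persister reactivation) are universal constants in the reference
#' calibration and default to 4.25e12 cells and 1e-8 /day.
#'
#' @param eta activation rate of injected CAR-T cells (/day).
#' @param mu_I decay rate of injected CAR-T cells (/day).
#' @param kappa proliferation rate of expander CAR-T cells (/day).
#' @param mu_E depletion (death + exhaustion) rate of expanders (/day).
#' @param epsilon persister (memory) formation rate (/day).
#' @param theta persister reactivation rate (/day).
#' @param mu_P persister decay rate (/day).
#' @param rho tumour growth rate (/day).
#' @param K tumour carrying capacity (cells).
#' @param gamma maximal CAR-T kill rate (/day).
#' @param A antigen-binding half-saturation constant (cells).
#' @param B kill half-saturation constant (cells).
#' @param g0 residual kill fraction for antigen-negative tumour cells,
#'   in \[0, 1\].
#' @return An object of class `cart_params` (named list of doubles).
#' @examples
#' p <- cart_params(eta = 0.2, mu_I = 0.6, kappa = 1.2, mu_E = 0.3,
#'                  epsilon = 0.05, mu_P = 0.01, rho = 0.15, gamma = 1.5,
#'                  A = 1e7, B = 1e7)
#' @export
cart_params <- function(eta, mu_I, kappa, mu_E, epsilon, mu_P, rho, gamma,
                        A, B, theta = 1e-8, K = 4.25e12, g0 = 0) {
  p <- list(eta = eta, mu_I = mu_I, kappa = kappa, mu_E = mu_E,
            epsilon = epsilon, theta = theta, mu_P = mu_P, rho = rho,
            K = K, gamma = gamma, A = A, B = B, g0 = g0)
  p <- lapply(p, as.numeric)
  rates <- c("eta", "mu_I", "kappa", "mu_E", "epsilon", "theta", "mu_P",
             "rho", "gamma")
  for (nm in rates) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("cart_params: '", nm, "' must be a finite non-negative rate",
           call. = FALSE)
    }
  }
  for (nm in c("K", "A", "B")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("cart_params: '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  if (!is.finite(p$g0) || p$g0 < 0 || p$g0 > 1) {
    stop("cart_params: 'g0' must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "cart_params")
}

#' Mechanistic parameters of the macrophage / IL-6 layer
#'
#' Rate constants of the cytokine layer: naive monocytes, activated
#' macrophages and serum IL-6.  Macrophage activation proceeds through
#' three mechanisms with coefficients `beta_K` (DAMP release by killed
#' tumour cells), `beta_B` (antigen-binding-mediated inflammatory
#' signalling) and `beta_C` (CD40-CD40L contact).
#'
#' @param sigma_M production rate of naive macrophages (cells/day).
#' @param delta_M macrophage death rate, shared by naive and activated
#'   cells (/day).
#' @param sigma_I endogenous IL-6 production ((ng/L)/day).
#' @param delta_I IL-6 decay rate (/day).
#' @param alpha IL-6 release per activated macrophage ((ng/L)/(cell day)).
#' @param beta_B antigen-binding activation coefficient (/(cell day)).
#' @param beta_K DAMP activation coefficient (/(cell day)).
#' @param beta_C CD40-contact activation coefficient (/(cell day)).
#' @param C CD40 half-saturation constant (cells); fixed at 1e10 in the
#'   reference calibration.
#' @return An object of class `cytokine_params`.
#' @export
cytokine_params <- function(sigma_M, delta_M, sigma_I, delta_I, alpha,
                            beta_B, beta_K, beta_C, C = 1e10) {
  q <- list(sigma_M = sigma_M, delta_M = delta_M, sigma_I = sigma_I,
            delta_I = delta_I, alpha = alpha, beta_B = beta_B,
            beta_K = beta_K, beta_C = beta_C, C = C)
  q <- lapply(q, as.numeric)
  for (nm in names(q)) {
    if (!is.finite(q[[nm]]) || q[[nm]] < 0) {
      stop("cytokine_params: '", nm, "' must be finite and non-negative",
           call. = FALSE)
    }
  }
  if (q$C <= 0) stop("cytokine_params: 'C' must be > 0", call. = FALSE)
  structure(q, class = "cytokine_params")
}

#' @export
print.cart_params <- function(x, ...) {
  cat("<cart_params>\n")
  print(tibble::as_tibble(x[])); invisible(x)
}

#' @export
print.cytokine_params <- function(x, ...) {
  cat("<cytokine_params>\n")
  print(tibble::as_tibble(x[])); invisible(x)
}

#' Model state vector
#'
#' Named non-negative state of the full system: injected/expander/persister
#' CAR-T cells, antigen-positive/negative tumour cells, naive and activated
#' macrophages, and the IL-6 serum concentration (ng/L).
#'
#' @param C_I,C_E,C_P CAR-T phenotype counts (cells).
#' @param T_P,T_N antigen-positive / antigen-negative tumour cells.
#' @param M_i,M_a naive / activated macrophages (cells).
#' @param IL6 IL-6 concentration (ng/L).
#' @return Named numeric vector of class `model_state`.
#' @export
model_state <- function(C_I = 0, C_E = 0, C_P = 0, T_P = 0, T_N = 0,
                        M_i = 0, M_a = 0, IL6 = 0) {
  s <- c(C_I = C_I, C_E = C_E, C_P = C_P, T_P = T_P, T_N = T_N,
         M_i = M_i, M_a = M_a, IL6 = IL6)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("model_state: all components must be finite and non-negative",
         call. = FALSE)
  }
  structure(s, class = c("model_state", "numeric"))
}

#' Dose regimen
#'
#' A schedule of CAR-T infusion events; each event adds cells to the
#' injected compartment at its time.  The clinically common split-dose
#' protocol gives 10% on day 0, 30% on day 1 and 60% on day 3.
#'
#' @param times infusion days (non-negative, sorted).
#' @param amounts cells infused at each time (positive).
#' @return A tibble of class `dose_regimen` with columns `time`, `cells`.
#' @examples
#' dose_regimen(0, 1e8)                 # single infusion
#' split_dose(1e8)                      # 10/30/60% on days 0/1/3
#' @export
dose_regimen <- function(times, amounts) {
  if (length(times) != length(amounts) || length(times) == 0) {
    stop("dose_regimen: 'times' and 'amounts' must have equal positive length",
         call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times)) {
    stop("dose_regimen: times must be non-negative and ordered", call. = FALSE)
  }
  if (any(amounts <= 0)) {
    stop("dose_regimen: amounts must be positive", call. = FALSE)
  }
  structure(tibble::tibble(time = as.numeric(times),
                           cells = as.numeric(amounts)),
            class = c("dose_regimen", class(tibble::tibble())))
}

#' @rdname dose_regimen
#' @param total total dose (cells) split over the fractions.
#' @param fractions fractions of the total per event (must sum to 1).
#' @param days event days.
#' @export
split_dose <- function(total, fractions = c(0.1, 0.3, 0.6), days = c(0, 1, 3)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-12)
  dose_regimen(days, total * fractions)
}

#' Total cells of a dose regimen
#' @param regimen a [dose_regimen()].
#' @return Total infused cells.
#' @export
total_dose <- function(regimen) sum(regimen$cells)

#' Unit conversion context
#'
#' Conversion constants between clinical reporting units and absolute cell
#' counts: a 5 L blood compartment, 1 CAR-T transgene copy/ug DNA = 1e4
#' cells, peripheral blood holding 1% of the bone-marrow compartment, and
#' a white-blood-cell range of 2.0e10 - 6.5e10 cells used to scale
#' %blasts.
#'
#' @param blood_volume litres of blood (default 5).
#' @param copies_per_ug_factor cells per (copy/ug DNA) (default 1e4).
#' @param pb_fraction_of_bm peripheral-blood fraction of bone marrow.
#' @param wbc_range total white-blood-cell count range (cells).
#' @return A list of class `unit_context`.
#' @export
unit_context <- function(blood_volume = 5, copies_per_ug_factor = 1e4,
                         pb_fraction_of_bm = 0.01,
                         wbc_range = c(2.0e10, 6.5e10)) {
  ctx <- list(blood_volume = blood_volume,
              copies_per_ug_factor = copies_per_ug_factor,
              pb_fraction_of_bm = pb_fraction_of_bm,
              wbc_range = wbc_range)
  if (blood_volume <= 0 || copies_per_ug_factor <= 0 || any(wbc_range <= 0)) {
    stop("unit_context: all constants must be > 0", call. = FALSE)
  }
  if (pb_fraction_of_bm <= 0 || pb_fraction_of_bm > 1) {
    stop("unit_context: pb_fraction_of_bm must be in (0, 1]", call. = FALSE)
  }
  ctx$wbc <- mean(wbc_range)
  structure(ctx, class = "unit_context")
}

.unit_aliases <- c(
  "cells" = "cells", "cell" = "cells",
  "copies/ug" = "copies_per_ug", "copies/ug dna" = "copies_per_ug",
  "copies_per_ug" = "copies_per_ug",
  "cells/ul" = "cells_per_ul_pb", "cells/ul pb" = "cells_per_ul_pb",
  "cells_per_ul_pb" = "cells_per_ul_pb",
  "cells/ul bm" = "cells_per_ul_bm", "cells_per_ul_bm" = "cells_per_ul_bm",
  "%blasts" = "pct_blasts", "pct_blasts" = "pct_blasts",
  "ng/l" = "ng_per_l", "ng_per_l" = "ng_per_l", "pg/ml" = "ng_per_l",
  "fold" = "fold", "fold_change" = "fold"
)

.canon_unit <- function(unit) {
  key <- tolower(trimws(unit))
  key <- gsub("µ", "u", key)
  out <- unname(.unit_aliases[key])
  if (any(is.na(out))) {
    stop("convert_units: unrecognized unit '", unit[is.na(out)][1], "'",
         call. = FALSE)
  }
  out
}

# cells per one unit of each cell-count convention
.cells_per_unit <- function(unit, ctx) {
  switch(unit,
    cells = 1,
    copies_per_ug = ctx$copies_per_ug_factor,
    cells_per_ul_pb = ctx$blood_volume * 1e6,
    cells_per_ul_bm = ctx$blood_volume * 1e6 / ctx$pb_fraction_of_bm,
    pct_blasts = ctx$wbc / 100,
    stop("convert_units: no linear factor for unit '", unit, "'",
         call. = FALSE)
  )
}

#' Convert between clinical units and absolute cell counts
#'
#' Exact linear conversion between the cell-count conventions used across
#' the source studies: transgene `copies/ug` DNA (1 copy/ug = 1e4 cells),
#' `cells/uL` of peripheral blood (1 cell/uL = 5e6 cells at 5 L),
#' `cells/uL` of bone marrow (1% peripheral fraction, so 1 cell/uL BM =
#' 5e8 cells), `%blasts` (tumour cells = WBC x %blasts/100, WBC = mean of
#' the context range) and absolute `cells`.  Conversions are invertible to
#' machine precision.
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit names (case-insensitive; `"copies/ug"`,
#'   `"cells/uL"`, `"cells/uL BM"`, `"%blasts"`, `"cells"`).
#' @param ctx a [unit_context()].
#' @return Converted numeric value(s).
#' @examples
#' convert_units(25, "copies/ug", "cells")   # 2.5e5
#' convert_units(1, "cells/uL", "cells")     # 5e6
#' @export
convert_units <- function(value, from, to, ctx = unit_context()) {
  f <- .canon_unit(from); t <- .canon_unit(to)
  if (f == t) return(value)
  cellish <- c("cells", "copies_per_ug", "cells_per_ul_pb",
               "cells_per_ul_bm", "pct_blasts")
  if (!(f %in% cellish) || !(t %in% cellish)) {
    stop("convert_units: unsupported conversion ", from, " -> ", to,
         call. = FALSE)
  }
  value * .cells_per_unit(f, ctx) / .cells_per_unit(t, ctx)
}
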