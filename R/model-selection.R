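#' Reduced model variants of the activation mechanisms
#'
#' The full model (`DAC`) activates macrophages through DAMP release
#' (`D`), antigen binding (`A`) and CD40 contact (`C`).  Reduced
#' variants remove one or two mechanisms by structurally fixing the
#' corresponding beta coefficient to zero and dropping it from the free
#' parameters, giving `k` in 6-8 free parameters.  `C` alone is invalid:
#' CD40 activation requires previously activated macrophages, so it can
#' never start from `M_a(0) = 0`.
#'
#' @param mechanisms character subset of `c("D", "A", "C")` (order
#'   irrelevant); also accepts a compact label such as `"DC"`.
#' @return A `model_variant` with `mechanisms`, `label`, `k`,
#'   `removed_betas`.
#' @examples
#' model_variant("DAC")$k  # 8
#' model_variant("DC")$k   # 7
#' @export
model_variant <- function(mechanisms) {
  if (length(mechanisms) == 1 && nchar(mechanisms) > 1) {
    mechanisms <- strsplit(mechanisms, "")[[1]]
  }
  mechanisms <- sort(unique(toupper(mechanisms)))
  if (!length(mechanisms) || !all(mechanisms %in% c("D", "A", "C"))) {
    stop("model_variant: mechanisms must be a non-empty subset of D, A, C",
         call. = FALSE)
  }
  if (identical(mechanisms, "C")) {
    stop("model_variant: variant 'C' is invalid - CD40 contact alone ",
         "cannot initiate macrophage activation", call. = FALSE)
  }
  beta_of <- c(D = "beta_K", A = "beta_B", C = "beta_C")
  removed <- unname(beta_of[setdiff(c("D", "A", "C"), mechanisms)])
  label <- paste(intersect(c("D", "A", "C"), mechanisms), collapse = "")
  structure(list(mechanisms = mechanisms, label = label,
                 k = 8L - length(removed), removed_betas = removed),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant>", x$label, "(k =", x$k, ")\n"); invisible(x)
}

#' Akaike information criterion for an IL-6 fit
#'
#' `AIC = 2k + n_d (1 + LR - ln n_d + ln 2*pi)`, where `LR` is the
#' log-weighted-residual objective, `k` the free-parameter count and
#' `n_d` the number of IL-6 data points.
#'
#' @param lr the `LR` objective value.
#' @param k free-parameter count.
#' @param n_d number of data points (>= 1).
#' @return The AIC value.
#' @export
aic_score <- function(lr, k, n_d) {
  if (n_d < 1) stop("aic_score: n_d must be >= 1", call. = FALSE)
  2 * k + n_d * (1 + lr - log(n_d) + log(2 * pi))
}

#' Fit and rank activation-mechanism variants
#'
#' Runs the layer-2 estimation ([fit_cytokine_layer()]) for each variant
#' with the same Monte-Carlo budget and seed stream, then ranks variants
#' by AIC (ascending, ties broken by fewer free parameters).  A variant
#' whose estimation fails is ranked last and flagged.
#'
#' @param tc a [patient_timecourse()] with IL-6 data.
#' @param layer1 the fitted (or known) first layer, as in
#'   [fit_cytokine_layer()].
#' @param variants list of [model_variant()]s or labels (default: all
#'   six testable variants).
#' @param config a [fit_config()].
#' @param refine_maxit refinement budget per tuple.
#' @return A `variant_ranking` tibble: `variant`, `k`, `lr`, `aic`,
#'   `rank`, `failed`; the fits are attached as attribute `fits`.
#' @export
rank_variants <- function(tc, layer1,
                          variants = c("DAC", "DC", "AC", "DA", "D", "A"),
                          config = fit_config(), refine_maxit = 60) {
  variants <- lapply(variants, function(v) {
    if (inherits(v, "model_variant")) v else model_variant(v)
  })
  # fit small variants first; larger variants are warm-started from the
  # optima of the variants they nest, so the nesting inequality
  # LR(full) <= LR(reduced) cannot be lost to search budget
  ks <- vapply(variants, `[[`, integer(1), "k")
  fit_order <- order(ks)
  fits <- vector("list", length(variants))
  for (i in fit_order) {
    v <- variants[[i]]
    warm <- list()
    for (j in seq_along(variants)) {
      f <- fits[[j]]
      if (is.null(f)) next
      if (all(variants[[j]]$mechanisms %in% v$mechanisms)) {
        warm <- c(warm, list(setNames(
          c(unlist(f$params[setdiff(f$free, "M_i0")]), f$M_i0),
          f$free)))
      }
    }
    fits[[i]] <- tryCatch(
      fit_cytokine_layer(tc, layer1, config, variant = v,
                         refine_maxit = refine_maxit, warm_starts = warm),
      error = function(e) NULL)
  }
  tbl <- tibble::tibble(
    variant = vapply(variants, `[[`, character(1), "label"),
    k = vapply(variants, `[[`, integer(1), "k"),
    lr = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$lr,
                numeric(1)),
    aic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic,
                 numeric(1)),
    failed = vapply(fits, is.null, logical(1)))
  tbl <- tbl[order(tbl$failed, tbl$aic, tbl$k), ]
  tbl$rank <- seq_len(nrow(tbl))
  attr(tbl, "fits") <- setNames(fits, vapply(variants, `[[`, character(1),
                                             "label"))
  structure(tbl, class = c("variant_ranking", class(tibble::tibble())))
}
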