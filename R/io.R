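#' Patient time-course container
#'
#' Holds one patient's sampled series — CAR-T abundance, tumour burden and
#' IL-6 concentration — in their reported units, together with the dose
#' regimen, detection limits and unit assumptions needed to map them onto
#' the model scale.
#'
#' @param id patient identifier.
#' @param data tibble with columns `series` (`"cart"`, `"tumor"`,
#'   `"il6"`), `time` (days), `value`, `unit`, `censored` (logical;
#'   censored rows carry the detection limit as value, not a guess).
#' @param regimen a [dose_regimen()].
#' @param disease optional disease label.
#' @param detection_limit CAR-T detection limit in cells (default 2.5e5,
#'   i.e. 25 transgene copies/ug DNA).
#' @param horizon end of analysis (days); defaults to the last sample.
#' @param il6_baseline baseline IL-6 (ng/L) used to expand fold-change
#'   reporting (default 1).
#' @param ctx a [unit_context()].
#' @return An object of class `patient_timecourse`.
#' @export
patient_timecourse <- function(id, data, regimen, disease = NA_character_,
                               detection_limit = 2.5e5, horizon = NULL,
                               il6_baseline = 1, ctx = unit_context()) {
  req <- c("series", "time", "value", "unit", "censored")
  if (!all(req %in% names(data))) {
    stop("patient_timecourse: data needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(data$time < 0)) {
    stop("patient_timecourse: sample times must be >= 0", call. = FALSE)
  }
  if (!inherits(regimen, "dose_regimen")) {
    stop("patient_timecourse: 'regimen' must be a dose_regimen", call. = FALSE)
  }
  bad <- setdiff(unique(data$series), c("cart", "tumor", "il6"))
  if (length(bad)) {
    stop("patient_timecourse: unknown series '", bad[1], "'", call. = FALSE)
  }
  # validate units up front so bad rows fail loudly at load time
  for (u in unique(data$unit)) .canon_unit(u)
  structure(list(id = id, disease = disease,
                 data = tibble::as_tibble(data), regimen = regimen,
                 detection_limit = detection_limit,
                 horizon = horizon %||% max(data$time),
                 il6_baseline = il6_baseline, ctx = ctx),
            class = "patient_timecourse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patient_timecourse <- function(x, ...) {
  cat("<patient_timecourse>", x$id, "-",
      paste(table(x$data$series), names(table(x$data$series)),
            collapse = ", "),
      "points; dose", format(total_dose(x$regimen), big.mark = ","),
      "cells; horizon", x$horizon, "days\n")
  invisible(x)
}

#' Extract one series of a time course in model units
#'
#' Converts the requested series to the model scale: absolute cells for
#' `cart` and `tumor` (via [convert_units()]), ng/L for `il6`
#' (fold-change values are multiplied by the recorded baseline).
#'
#' @param tc a [patient_timecourse()].
#' @param series `"cart"`, `"tumor"` or `"il6"`.
#' @param censored include censored (below-detection) rows? Default
#'   `TRUE`; pass `FALSE` to keep only quantified points.
#' @return Tibble with columns `time`, `value`, `unit`, `censored`,
#'   `cells` (or `ng_per_l` for il6, column still named `cells` for a
#'   uniform interface).
#' @export
timecourse_series <- function(tc, series = c("cart", "tumor", "il6"),
                              censored = TRUE) {
  series <- match.arg(series)
  df <- dplyr::filter(tc$data, .data$series == !!series)
  if (!censored) df <- dplyr::filter(df, !.data$censored)
  if (series == "il6") {
    df$cells <- ifelse(.canon_unit(df$unit) == "fold",
                       df$value * tc$il6_baseline, df$value)
  } else {
    df$cells <- vapply(seq_len(nrow(df)), function(i) {
      convert_units(df$value[i], df$unit[i], "cells", tc$ctx)
    }, numeric(1))
  }
  dplyr::arrange(df[c("time", "value", "unit", "censored", "cells")],
                 .data$time)
}

#' Write a patient time course to CSV + JSON sidecar
#'
#' The series go to `<path>` as a long-format CSV (`series, time, value,
#' unit, censored`); metadata (id, disease, regimen, detection limit,
#' horizon, IL-6 baseline, WBC assumption) go to `<path>` with the
#' extension replaced by `.json`.
#'
#' @param tc a [patient_timecourse()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(tc$data, path, row.names = FALSE)
  meta <- list(id = tc$id, disease = tc$disease,
               dose_times = tc$regimen$time, dose_cells = tc$regimen$cells,
               detection_limit = tc$detection_limit, horizon = tc$horizon,
               il6_baseline = tc$il6_baseline,
               wbc_range = tc$ctx$wbc_range)
  jsonlite::write_json(meta, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar <- function(path) sub("\\.[^.]*$", ".json", path)

#' Read a patient time course written by [write_timecourse()]
#'
#' @param path CSV path; the JSON sidecar is looked up next to it.
#' @return A [patient_timecourse()].
#' @export
read_timecourse <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  df$censored <- as.logical(df$censored)
  meta_path <- .sidecar(path)
  if (!file.exists(meta_path)) {
    stop("read_timecourse: missing metadata sidecar ", meta_path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$dose_cells)) {
    stop("read_timecourse: metadata lacks the dose regimen", call. = FALSE)
  }
  ctx <- if (!is.null(meta$wbc_range)) unit_context(wbc_range = meta$wbc_range)
         else unit_context()
  patient_timecourse(
    id = meta$id %||% basename(path), data = df,
    regimen = dose_regimen(meta$dose_times, meta$dose_cells),
    disease = meta$disease %||% NA_character_,
    detection_limit = meta$detection_limit %||% 2.5e5,
    horizon = meta$horizon, il6_baseline = meta$il6_baseline %||% 1,
    ctx = ctx)
}
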