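#' Annualized rate formulas
#'
#' The three rates relate paired-timepoint measurements (areas in mm^2
#' for the 2D method, volumes in mm^3 for the 3D method) to an
#' annualized change score:
#'
#' * **yrTA** (yearly rate of Thalamic Atrophy):
#'   `[(A1 + A'1) - (A2 + A'2)] * 120 / months` — positive when the
#'   summed bilateral thalamus shrank.
#' * **yrVE** (yearly rate of Ventricular Enlargement):
#'   `(B2 - B1) * 120 / months` in 2D, or
#'   `[(C2 + C'2 + D2) - (C1 + C'1 + D1)] * 120 / months` in 3D —
#'   positive when the ventricles enlarged.
#' * **yrRTA** (yearly rate of Relative Thalamic Atrophy), as printed:
#'   `dTA * 120 / (dVE * months)`, where `dTA` and `dVE` are the raw
#'   (un-annualized) thalamic and ventricular differences.
#'
#' Note that the as-printed yrRTA is *not* the quotient of the two
#' rates: `yrTA / yrVE = dTA / dVE`, a dimension-free ratio with the
#' annualization cancelled. Both conventions are offered
#' (`convention = "as_printed"` is the default, for fidelity to the
#' published formula; `"pure_ratio"` is the algebraic quotient). The
#' annualization constant 120 is configurable via `factor`.
#'
#' When the ventricular difference `dVE` is zero the yrRTA is undefined;
#' it is returned as `NA` (a flagged value, never an error) so that
#' batch tables containing stable patients still compute.
#'
#' All functions are vectorized and recycle arguments like base
#' arithmetic.
#'
#' @param baseline_sum,followup_sum Summed bilateral thalamic measurement
#'   (`A + A'`) at each timepoint (`yr_ta`), or summed ventricular
#'   measurement (`B`, or `C + C' + D`) at each timepoint (`yr_ve`).
#' @param delta_ta Raw thalamic decrease `(A1 + A'1) - (A2 + A'2)`.
#' @param delta_ve Raw ventricular increase (`B2 - B1`, or the
#'   `C + C' + D` difference).
#' @param months Inter-scan interval in months (> 0).
#' @param factor Annualization factor; default 120.
#' @param convention `"as_printed"` or `"pure_ratio"` (see Details).
#' @return Numeric vector of rates; `yr_rta()` yields `NA` where
#'   `delta_ve == 0`.
#' @examples
#' yr_ta(1000, 980, months = 12)               # 200
#' yr_ve(2000, 2100, months = 12)              # 1000
#' yr_rta(20, 100, months = 12)                # 2
#' yr_rta(20, 100, convention = "pure_ratio")  # 0.2
#' @name rates
NULL

check_months <- function(months) {
  if (any(!is.finite(months)) || any(months <= 0)) {
    abort("`months` must be positive and finite.",
          class = "yrrta_validation_error")
  }
}

#' @rdname rates
#' @export
yr_ta <- function(baseline_sum, followup_sum, months, factor = 120) {
  check_months(months)
  (baseline_sum - followup_sum) * factor / months
}

#' @rdname rates
#' @export
yr_ve <- function(baseline_sum, followup_sum, months, factor = 120) {
  check_months(months)
  (followup_sum - baseline_sum) * factor / months
}

#' @rdname rates
#' @export
yr_rta <- function(delta_ta, delta_ve, months = NULL,
                   factor = 120,
                   convention = c("as_printed", "pure_ratio")) {
  convention <- arg_match(convention)
  out <- if (convention == "as_printed") {
    if (is.null(months)) {
      abort("`months` is required for the as_printed convention.",
            class = "yrrta_validation_error")
    }
    check_months(months)
    delta_ta * factor / (delta_ve * months)
  } else {
    delta_ta / delta_ve
  }
  out[rep_len(delta_ve == 0, length(out))] <- NA_real_
  out
}

required_measure_cols <- function(mode) {
  if (mode == "2d") c("A1", "A_prime1", "B1", "A2", "A_prime2", "B2", "months")
  else c("A1", "A_prime1", "C1", "C_prime1", "D1",
         "A2", "A_prime2", "C2", "C_prime2", "D2", "months")
}

#' Compute yrTA, yrVE and yrRTA for a measurement table
#'
#' Takes a table of paired-timepoint measurements — one row per subject,
#' in the column dialect of [read_measurement_table()] /
#' [pair_measurements()] — and appends the three rates. Undefined yrRTA
#' (zero ventricular difference) is `NA`, with `yrRTA_defined = FALSE`.
#'
#' @param data Data frame with the mode's measurement columns
#'   (2D: `A1, A_prime1, B1, A2, A_prime2, B2, months`;
#'   3D: `A1, A_prime1, C1, C_prime1, D1, A2, A_prime2, C2, C_prime2,
#'   D2, months`).
#' @param mode `"2d"` or `"3d"`.
#' @inheritParams rates
#' @return The input tibble with columns `yrTA`, `yrVE`, `yrRTA`,
#'   `yrRTA_defined` appended; the mode, convention and factor are
#'   recorded as attributes and the result carries class `yrrta_rates`.
#' @examples
#' tbl <- tibble::tibble(A1 = 500, A_prime1 = 500, B1 = 2000,
#'                       A2 = 490, A_prime2 = 490, B2 = 2100, months = 12)
#' compute_rates(tbl, mode = "2d")
#' @export
compute_rates <- function(data, mode = c("2d", "3d"), factor = 120,
                          convention = c("as_printed", "pure_ratio")) {
  mode <- arg_match(mode)
  convention <- arg_match(convention)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    abort("`factor` must be a single positive number.",
          class = "yrrta_validation_error")
  }
  need <- required_measure_cols(mode)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing required column(s) for mode ", mode, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "yrrta_schema_error")
  }
  check_months(data$months)
  ta1 <- data$A1 + data$A_prime1
  ta2 <- data$A2 + data$A_prime2
  if (mode == "2d") {
    ve1 <- data$B1; ve2 <- data$B2
  } else {
    ve1 <- data$C1 + data$C_prime1 + data$D1
    ve2 <- data$C2 + data$C_prime2 + data$D2
  }
  out <- as_tibble(data)
  out$yrTA <- yr_ta(ta1, ta2, data$months, factor)
  out$yrVE <- yr_ve(ve1, ve2, data$months, factor)
  out$yrRTA <- yr_rta(ta1 - ta2, ve2 - ve1, data$months, factor, convention)
  out$yrRTA_defined <- (ve2 - ve1) != 0
  attr(out, "mode") <- mode
  attr(out, "convention") <- convention
  attr(out, "factor") <- factor
  class(out) <- c("yrrta_rates", class(out))
  out
}
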