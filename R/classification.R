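#' The qualitative interpretation table
#'
#' The four possible (yrTA, yrVE) category pairs, the derived yrRTA
#' category, the clinical reading, and the a-priori risk of progression.
#' The yrRTA category is defined *by this table* from the two rate
#' categories, not by thresholding the numeric yrRTA: concordant rates
#' (both Low, or both High) give a Normal relative rate, while
#' discordant rates give Low (ventricles outpacing the thalamus) or
#' High (thalamus outpacing the ventricles).
#' @noRd
interpretation_table <- tibble::tibble(
  ta_category  = c("Low", "Low", "High", "High"),
  ve_category  = c("Low", "High", "Low", "High"),
  rta_category = c("Normal", "Low", "High", "Normal"),
  risk         = c("Low", "Low", "High", "High"),
  interpretation = c(
    paste("Healthy subject or patient without significant brain atrophy",
          "(no brain atrophy ongoing) - low risk of progression"),
    paste("Brain getting atrophied but the thalamus is not",
          "(atrophy ongoing but not due to deep GM atrophy) -",
          "low risk of progression"),
    paste("Thalamus getting atrophied but other brain structures not so",
          "significantly (atrophy ongoing due to deep GM atrophy mostly) -",
          "high risk of progression"),
    paste("Global brain atrophy including the thalamus",
          "(generalized atrophy ongoing) - high risk of progression")))

#' Categorize a rate as Low or High against a cutoff
#'
#' Strict-inequality rule: a value is `"High"` when it exceeds the
#' cutoff and `"Low"` otherwise, so a value exactly at the cutoff is
#' `"Low"`. Cutoffs are deliberately *not* defaulted: normative rates
#' are still to be established, so they must come from the user or a
#' config file.
#'
#' @param value Numeric vector of rates (finite).
#' @param cutoff Single finite numeric cutoff in the same units.
#' @return Character vector of `"Low"` / `"High"`.
#' @examples
#' categorize(c(-5, 100, 100.1), cutoff = 100)
#' @export
categorize <- function(value, cutoff) {
  if (any(!is.finite(value))) {
    abort("`value` must be finite to categorize.",
          class = "yrrta_validation_error")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    abort("`cutoff` must be a single finite number.",
          class = "yrrta_validation_error")
  }
  ifelse(value > cutoff, "High", "Low")
}

#' Interpret a pair of rate categories
#'
#' Looks up the interpretation-table row for each (yrTA category,
#' yrVE category) pair (see the package vignette for the full table):
#' the derived yrRTA category, the clinical interpretation text, and
#' the a-priori risk of progression.
#'
#' @param ta_category,ve_category Character vectors of `"Low"`/`"High"`
#'   (recycled to common length).
#' @return Tibble with `ta_category`, `ve_category`, `rta_category`
#'   (`"Normal"`/`"Low"`/`"High"`), `risk` (`"Low"`/`"High"`) and
#'   `interpretation`.
#' @examples
#' interpret_categories("High", "Low")
#' @export
interpret_categories <- function(ta_category, ve_category) {
  ok <- function(x) all(x %in% c("Low", "High"))
  if (!ok(ta_category) || !ok(ve_category)) {
    abort('Categories must be "Low" or "High".',
          class = "yrrta_validation_error")
  }
  n <- max(length(ta_category), length(ve_category))
  q <- tibble(ta_category = rep_len(ta_category, n),
              ve_category = rep_len(ve_category, n))
  left_join(q, interpretation_table, by = c("ta_category", "ve_category"))
}

#' Classify computed rates against user-supplied cutoffs
#'
#' Appends the qualitative classification to a rates table from
#' [compute_rates()] (or any table with `yrTA` and `yrVE` columns):
#' each rate is categorized Low/High by strict comparison with its
#' cutoff, then the category pair is interpreted. An undefined numeric
#' yrRTA (zero ventricular change) does not block classification — the
#' categories derive from yrTA and yrVE alone.
#'
#' @param data Data frame with numeric `yrTA` and `yrVE` columns.
#' @param ta_cutoff,ve_cutoff Finite cutoffs in yrTA / yrVE units.
#'   Mandatory: the package refuses to invent normative thresholds.
#' @return The input tibble with `ta_category`, `ve_category`,
#'   `rta_category`, `risk`, `interpretation` appended.
#' @examples
#' tbl <- tibble::tibble(yrTA = c(200, 0), yrVE = c(1000, 0))
#' classify_rates(tbl, ta_cutoff = 100, ve_cutoff = 500)
#' @export
classify_rates <- function(data, ta_cutoff, ve_cutoff) {
  if (missing(ta_cutoff) || missing(ve_cutoff)) {
    abort(paste("Both `ta_cutoff` and `ve_cutoff` are required:",
                "normative rate cutoffs must be supplied explicitly."),
          class = "yrrta_validation_error")
  }
  for (col in c("yrTA", "yrVE")) {
    if (!col %in% names(data)) {
      abort(paste0("Missing column `", col,
                   "`; run compute_rates() first."),
            class = "yrrta_schema_error")
    }
  }
  out <- as_tibble(data)
  cls <- interpret_categories(categorize(out$yrTA, ta_cutoff),
                              categorize(out$yrVE, ve_cutoff))
  out$ta_category <- cls$ta_category
  out$ve_category <- cls$ve_category
  out$rta_category <- cls$rta_category
  out$risk <- cls$risk
  out$interpretation <- cls$interpretation
  out
}
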