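#' Read a YAML run configuration
#'
#' Recognized keys (all optional): `label_preset` (`"default"` or
#' `"aseg"`), `labels` (named role-to-label overrides),
#' `annualization_factor`, `ratio_convention` (`"as_printed"` or
#' `"pure_ratio"`), `ta_cutoff`, `ve_cutoff`. Unknown keys abort, to
#' catch typos in clinical configs.
#'
#' @param path YAML file path.
#' @return A named list with elements `labels` ([label_map()]),
#'   `factor`, `convention`, `ta_cutoff`, `ve_cutoff` (cutoffs `NULL`
#'   when not configured).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "yrrta_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("label_preset", "labels", "annualization_factor",
             "ratio_convention", "ta_cutoff", "ve_cutoff")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "yrrta_schema_error")
  }
  lm_args <- c(list(preset = raw$label_preset %||% "default"),
               as.list(raw$labels %||% list()))
  list(labels = do.call(label_map, lm_args),
       factor = raw$annualization_factor %||% 120,
       convention = raw$ratio_convention %||% "as_printed",
       ta_cutoff = raw$ta_cutoff,
       ve_cutoff = raw$ve_cutoff)
}

#' Read a YAML cohort specification
#'
#' Keys map directly onto the [cohort_spec()] arguments (`n`,
#' `loss_mean`, `loss_sd`, `gain_mean`, `gain_sd`, `months_range`,
#' `anatomy_cv`, `seed`), plus an optional `phantom` block with
#' [phantom_spec()] arguments for the base anatomy.
#'
#' @param path YAML file path.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Cohort spec file not found: ", path),
          class = "yrrta_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ph <- raw$phantom
  raw$phantom <- NULL
  args <- raw
  if (!is.null(ph)) {
    args$base_spec <- tryCatch(do.call(phantom_spec, ph),
                               error = function(e) {
                                 abort(paste0("Invalid phantom block: ",
                                              conditionMessage(e)),
                                       class = "yrrta_schema_error")
                               })
  }
  for (key in c("n", "loss_mean", "loss_sd", "gain_mean", "gain_sd",
                "months_range")) {
    if (!is.null(args[[key]])) args[[key]] <- unlist(args[[key]])
  }
  tryCatch(do.call(cohort_spec, args),
           error = function(e) {
             abort(paste0("Invalid cohort spec: ", conditionMessage(e)),
                   class = "yrrta_schema_error")
           })
}
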