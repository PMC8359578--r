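#' ECG parameter catalogue
#'
#' The catalogue of automated 12-lead ECG measurements handled by this
#' package: 438 modelling parameters (6 not lead-specific plus 36 measured in
#' each of the 12 standard leads) and 201 parameters excluded from modelling
#' (9 not lead-specific plus 16 per-lead measurements that duplicate timing
#' coordinates or alternative corrections such as QTc Framingham/Fridericia).
#' Lead-specific columns are named `"<Parameter>__<Lead>"` with leads
#' I, II, III, aVR, aVL, aVF and V1-V6; second waveform components are
#' written with a plain ASCII apostrophe (e.g. `"P' Area"`).
#'
#' @param status Which part of the catalogue to return: `"used"` (the 438
#'   modelling parameters, the default), `"excluded"` (the 201 dropped ones)
#'   or `"all"`.
#' @return A tibble with columns `column` (the table column name),
#'   `parameter`, `lead` (`NA` for not-lead-specific parameters),
#'   `lead_specific` and `status`.
#' @examples
#' nrow(ecg_parameter_catalogue())            # 438
#' nrow(ecg_parameter_catalogue("excluded"))  # 201
#' @export
ecg_parameter_catalogue <- function(status = c("used", "excluded", "all")) {
  status <- match.arg(status)
  path <- system.file("extdata", "ecg_parameter_catalogue.tsv",
                      package = "ecgbioage", mustWork = TRUE)
  cat_df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      column = readr::col_character(),
      parameter = readr::col_character(),
      lead = readr::col_character(),
      lead_specific = readr::col_logical(),
      status = readr::col_character()
    ),
    progress = FALSE
  )
  if (status != "all") {
    cat_df <- dplyr::filter(cat_df, .data$status == .env$status)
  }
  cat_df
}

#' Identify ECG parameter columns in a cohort table
#'
#' Returns the names of columns in `data` that belong to the modelling
#' catalogue, in catalogue order.
#'
#' @param data A data frame.
#' @return Character vector of column names.
#' @export
ecg_parameter_columns <- function(data) {
  intersect(ecg_parameter_catalogue()$column, names(data))
}

# Demographic / outcome / covariate columns recognised by the reader; every
# other non-catalogue column is reported and dropped.
cohort_schema <- function() {
  list(
    required = c("patient_id", "sex", "ca_years", "followup_days",
                 "status", "death_cause"),
    optional = c("flag_structural_heart_disease", "flag_pacing",
                 "flag_tachyarrhythmia", "flag_indeterminate_axis",
                 "scr_mg_dl", "height_m", "weight_kg")
  )
}
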