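#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end biological-age
#' run. Defaults mirror the analysis design: step-1 age-correlation
#' threshold 0.2, step-2 strong-correlation threshold 0.9, eigenvalue cutoff
#' 1.0, three-year follow-up cap, and chronological-age category edges at
#' 40, 60 and 75 years.
#'
#' @param n_patients Cohort size when simulating (default 5000).
#' @param seed Master seed for the whole run.
#' @param input Optional path to a cohort file ([read_cohort()]); when
#'   `NULL` a synthetic cohort is generated.
#' @param generator Named list of extra arguments for [simulate_cohort()].
#' @param age_threshold,collinearity_threshold Selection thresholds.
#' @param eigen_cutoff Minimum retained eigenvalue for the PCA model.
#' @param followup_cap_days Follow-up truncation horizon.
#' @param sex_mode How per-sex selections combine into the modelling column
#'   list (see [selected_parameters()]).
#' @param columns Optional explicit modelling column list overriding the
#'   selection result.
#' @param age_breaks Interior edges of the chronological-age categories.
#' @return A validated list of class `"ba_config"`.
#' @export
pipeline_config <- function(n_patients = 5000,
                            seed = 1,
                            input = NULL,
                            generator = list(),
                            age_threshold = 0.2,
                            collinearity_threshold = 0.9,
                            eigen_cutoff = 1.0,
                            followup_cap_days = 1095.75,
                            sex_mode = c("union", "intersection",
                                         "male", "female"),
                            columns = NULL,
                            age_breaks = c(40, 60, 75)) {
  sex_mode <- match.arg(sex_mode)
  if (!is.numeric(age_threshold) || age_threshold < 0 || age_threshold > 1) {
    stop("age_threshold must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(collinearity_threshold) || collinearity_threshold <= 0 ||
      collinearity_threshold > 1) {
    stop("collinearity_threshold must be in (0, 1]", call. = FALSE)
  }
  stopifnot(n_patients >= 1, eigen_cutoff > 0, followup_cap_days > 0,
            all(diff(age_breaks) > 0))
  structure(list(
    n_patients = n_patients, seed = seed, input = input,
    generator = generator, age_threshold = age_threshold,
    collinearity_threshold = collinearity_threshold,
    eigen_cutoff = eigen_cutoff, followup_cap_days = followup_cap_days,
    sex_mode = sex_mode, columns = columns, age_breaks = age_breaks
  ), class = "ba_config")
}

#' Run the full biological-age pipeline
#'
#' Executes simulate (or ingest) -> exclusions -> follow-up truncation ->
#' two-step parameter selection -> principal-component and Klemera-Doubal
#' model fits -> per-patient predictions -> stratified AUC evaluation, and
#' assembles summary tables (death distribution by sex; distribution of CA
#' and the three biological ages overall and per age category; the AUC
#' report) plus a manifest (seed, configuration hash, versions, stage sizes).
#' Identical configuration and seed give identical results.
#'
#' @param config A `"ba_config"` from [pipeline_config()].
#' @return An object of class `"ba_pipeline"`: `cohort` (post exclusion and
#'   truncation), `selection`, `pca`, `kdm`, `predictions`, `evaluation`,
#'   `death_distribution`, `age_distribution`, `exclusions`, `manifest` and
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ba_config"))

  data <- if (is.null(config$input)) {
    do.call(simulate_cohort,
            c(list(n_patients = config$n_patients, seed = config$seed),
              config$generator))
  } else {
    read_cohort(config$input)
  }
  truth <- attr(data, "latent_truth", exact = TRUE)
  n_input <- nrow(data)

  data <- apply_exclusions(data)
  excl <- exclusion_report(data)
  data <- truncate_followup(data, cap_days = config$followup_cap_days)

  candidates <- ecg_parameter_columns(data)
  if (length(candidates) == 0) stop("no ECG parameter columns present",
                                    call. = FALSE)
  selection <- select_parameters(
    data, candidates,
    age_threshold = config$age_threshold,
    collinearity_threshold = config$collinearity_threshold
  )
  columns <- config$columns %||%
    selected_parameters(selection, mode = config$sex_mode)
  if (length(columns) == 0) {
    stop("parameter selection retained no columns", call. = FALSE)
  }

  pca <- fit_pca_age(data, columns, eigen_cutoff = config$eigen_cutoff)
  kdm <- fit_kdm(data, columns)

  predictions <- data |>
    dplyr::select(dplyr::all_of(c("patient_id", "sex", "ca_years",
                                  "followup_days", "status",
                                  "death_cause"))) |>
    dplyr::left_join(predict(pca, data), by = c("patient_id", "ca_years")) |>
    dplyr::left_join(predict(kdm, data), by = c("patient_id", "ca_years"))
  if (!is.null(truth)) {
    predictions <- dplyr::left_join(predictions, truth, by = "patient_id")
  }

  evaluation <- evaluate_discrimination(predictions,
                                        age_breaks = config$age_breaks)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecgbioage")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_input = n_input,
    n_after_exclusions = nrow(data),
    n_columns_candidate = length(candidates),
    n_columns_model = length(columns),
    columns = columns
  )

  structure(list(
    cohort = data,
    selection = selection,
    pca = pca,
    kdm = kdm,
    predictions = predictions,
    evaluation = evaluation,
    death_distribution = death_distribution(predictions),
    age_distribution = age_distribution(predictions, config$age_breaks),
    exclusions = excl,
    manifest = manifest,
    config = config
  ), class = "ba_pipeline")
}

#' Death distribution summary
#'
#' Counts and mean/SD chronological age of alive and deceased patients by
#' sex, with the crude all-cause incidence per 100 patient-years.
#'
#' @param predictions Tibble with `sex`, `ca_years`, `followup_days`,
#'   `status`.
#' @return A tibble with one row per sex-by-status cell.
#' @export
death_distribution <- function(predictions) {
  predictions |>
    dplyr::group_by(.data$sex, .data$status) |>
    dplyr::summarise(
      n = dplyr::n(),
      ca_mean = mean(.data$ca_years),
      ca_sd = stats::sd(.data$ca_years),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate_per_100py = incidence_rate(
        sum(predictions$status == "all_cause_death"),
        nrow(predictions),
        mean(predictions$followup_days)
      )
    )
}

#' Distribution of chronological and biological ages
#'
#' Mean, SD, minimum and maximum of each age estimate, overall and within
#' each chronological-age category.
#'
#' @param predictions Prediction tibble from [run_pipeline()] (columns
#'   `ca_years`, `ba_years`, `ba_e_years`, `ba_ec_years`).
#' @param age_breaks Interior category edges (default `c(40, 60, 75)`).
#' @return Long tibble: `stratum`, `measure`, `mean`, `sd`, `min`, `max`.
#' @export
age_distribution <- function(predictions, age_breaks = c(40, 60, 75)) {
  measures <- intersect(c("ca_years", "ba_years", "ba_e_years",
                          "ba_ec_years"), names(predictions))
  strata <- age_strata(predictions$ca_years, age_breaks)
  summarise_block <- function(sub, label) {
    purrr::map_dfr(measures, function(ms) {
      tibble::tibble(stratum = label, measure = ms,
                     mean = mean(sub[[ms]]), sd = stats::sd(sub[[ms]]),
                     min = min(sub[[ms]]), max = max(sub[[ms]]))
    })
  }
  out <- summarise_block(predictions, "total")
  for (st in levels(strata)) {
    sub <- predictions[strata == st, , drop = FALSE]
    if (nrow(sub) > 0) out <- dplyr::bind_rows(out, summarise_block(sub, st))
  }
  out
}

#' @export
print.ba_pipeline <- function(x, ...) {
  cat("ECG biological-age pipeline run\n")
  cat("  seed:", x$manifest$seed, " patients:", x$manifest$n_after_exclusions,
      "(of", x$manifest$n_input, "input)\n")
  cat("  modelling parameters:", x$manifest$n_columns_model, "\n")
  cat("  PCA components:", x$pca$m, "; KDM r_char:",
      signif(x$kdm$r_char, 4), " s2_BA:", signif(x$kdm$s2_ba, 4), "\n")
  print(x$evaluation)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Serialises the stage outputs of a pipeline run as plain text: the
#' post-processing cohort and predictions as CSV, the selection report, both
#' model fits, the summary tables and the manifest as JSON (full numeric
#' precision).
#'
#' @param result A `"ba_pipeline"` object.
#' @param dir Output directory (created if needed).
#' @return `result`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "ba_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$predictions, file.path(dir, "predictions.csv"),
                   progress = FALSE)
  readr::write_csv(result$evaluation$auc, file.path(dir, "auc.csv"),
                   progress = FALSE)
  readr::write_csv(result$age_distribution,
                   file.path(dir, "age_distribution.csv"), progress = FALSE)
  readr::write_csv(result$death_distribution,
                   file.path(dir, "death_distribution.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      selection = tidy(result$selection),
      pca = list(glance = glance(result$pca), loadings = tidy(result$pca)),
      kdm = list(glance = glance(result$kdm), coefficients = tidy(result$kdm)),
      paired_delong = result$evaluation$paired,
      unpaired_delong = result$evaluation$unpaired,
      manifest = result$manifest
    ),
    file.path(dir, "run.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(result)
}
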