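# Fixture builders and independent oracles shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal cohort tibble around a chronological-age vector; extra ECG columns
# passed as a named list of numeric vectors (names must be catalogue names).
make_cohort <- function(ca, sex = NULL, params = list(),
                        status = NULL, death_cause = NULL,
                        followup_days = NULL) {
  n <- length(ca)
  out <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = sex %||% rep("male", n),
    ca_years = ca,
    followup_days = followup_days %||% rep(365, n),
    status = status %||% rep("alive", n),
    death_cause = death_cause %||% rep("none", n)
  )
  for (nm in names(params)) out[[nm]] <- params[[nm]]
  out
}

# First k catalogue column names (handy for naming synthetic parameters).
cat_cols <- function(k) ecg_parameter_catalogue()$column[seq_len(k)]

# Brute-force Mann-Whitney AUC over all event/control pairs.
auc_brute_force <- function(scores, labels) {
  ev <- scores[as.logical(labels)]
  ct <- scores[!as.logical(labels)]
  mean(outer(ev, ct, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Trapezoidal area under the empirical ROC curve.
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Numeric 1-D minimiser of the weighted least-squares criterion behind the
# Klemera-Doubal estimator.
ba_e_wls_oracle <- function(x, k, q, s, interval = c(-500, 500)) {
  obj <- function(t) sum(((x - q - k * t) / s)^2)
  stats::optimize(obj, interval = interval, tol = 1e-10)$minimum
}

# A 10-patient cohort exercising every exclusion criterion.
exclusion_fixture <- function() {
  out <- make_cohort(c(19, rep(50, 9)))
  out$flag_structural_heart_disease <- c(FALSE, TRUE, TRUE, rep(FALSE, 7))
  out$flag_indeterminate_axis <- c(rep(FALSE, 3), TRUE, rep(FALSE, 6))
  out$flag_pacing <- FALSE
  out$flag_tachyarrhythmia <- FALSE
  out
}
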