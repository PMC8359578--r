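#' Mann-Whitney AUC with DeLong placement values
#'
#' Estimates the area under the ROC curve as the Mann-Whitney concordance
#' probability (ties counted 1/2), computed through midranks. The per-event
#' and per-control placement values needed for DeLong variance and
#' covariance estimates are returned alongside.
#'
#' @param scores Numeric predictor values, higher meaning more event-like.
#' @param labels Logical (or 0/1) event indicator; both classes must be
#'   present.
#' @return A list: `auc`, `var` (DeLong variance of the AUC, `NA` when a
#'   class has a single member), `v_events` and `v_controls` (placement
#'   values), `n_events`, `n_controls`.
#' @examples
#' auc_mann_whitney(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0 || n == 0) {
    stop("both events and non-events are required", call. = FALSE)
  }
  r_all <- rank(scores, ties.method = "average")
  r_ev <- rank(scores[labels], ties.method = "average")
  r_ct <- rank(scores[!labels], ties.method = "average")
  # placement of each event among controls, and vice versa
  v_events <- (r_all[labels] - r_ev) / n
  v_controls <- 1 - (r_all[!labels] - r_ct) / m
  auc <- (sum(r_all[labels]) - m * (m + 1) / 2) / (m * n)
  v <- if (m >= 2 && n >= 2) {
    stats::var(v_events) / m + stats::var(v_controls) / n
  } else {
    NA_real_
  }
  list(auc = auc, var = v, v_events = v_events, v_controls = v_controls,
       n_events = m, n_controls = n)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two predictors measured on the same patients. The
#' variance of the AUC difference is built from the empirical covariance of
#' the DeLong placement values, and a two-sided normal p-value is reported.
#' If the difference is exactly zero with zero variance (e.g. comparing a
#' predictor with itself) the p-value is 1 by convention; zero variance with
#' a non-zero difference is an error.
#'
#' @param scores_a,scores_b Predictor values on the same patients.
#' @param labels Logical (or 0/1) event indicator.
#' @return One-row tibble: `auc_a`, `auc_b`, `delta` (a minus b), `z`, `p`.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  a <- auc_mann_whitney(scores_a, labels)
  b <- auc_mann_whitney(scores_b, labels)
  m <- a$n_events
  n <- a$n_controls
  if (m < 2 || n < 2) {
    stop("need at least 2 events and 2 non-events for the paired test",
         call. = FALSE)
  }
  s10 <- stats::cov(cbind(a$v_events, b$v_events))
  s01 <- stats::cov(cbind(a$v_controls, b$v_controls))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  if (var_delta <= 0) {
    if (isTRUE(all.equal(delta, 0))) {
      return(tibble::tibble(auc_a = a$auc, auc_b = b$auc, delta = 0,
                            z = 0, p = 1))
    }
    stop("zero DeLong variance with a non-zero AUC difference", call. = FALSE)
  }
  z <- delta / sqrt(var_delta)
  tibble::tibble(auc_a = a$auc, auc_b = b$auc, delta = delta, z = z,
                 p = 2 * stats::pnorm(-abs(z)))
}

#' Unpaired DeLong test for AUCs from independent cohorts
#'
#' Compares one predictor's AUC across two disjoint patient groups (e.g. two
#' chronological-age categories). The variance of the difference is the sum
#' of the two independent DeLong variances.
#'
#' @param scores_1,labels_1 Predictor values and event indicator in group 1.
#' @param scores_2,labels_2 Same for group 2.
#' @return One-row tibble: `auc_1`, `auc_2`, `delta` (1 minus 2), `z`, `p`.
#' @export
delong_unpaired <- function(scores_1, labels_1, scores_2, labels_2) {
  a <- auc_mann_whitney(scores_1, labels_1)
  b <- auc_mann_whitney(scores_2, labels_2)
  if (is.na(a$var) || is.na(b$var)) {
    stop("need at least 2 events and 2 non-events in each group",
         call. = FALSE)
  }
  var_delta <- a$var + b$var
  delta <- a$auc - b$auc
  if (var_delta <= 0) {
    if (isTRUE(all.equal(delta, 0))) {
      return(tibble::tibble(auc_1 = a$auc, auc_2 = b$auc, delta = 0,
                            z = 0, p = 1))
    }
    stop("zero DeLong variance with a non-zero AUC difference", call. = FALSE)
  }
  z <- delta / sqrt(var_delta)
  tibble::tibble(auc_1 = a$auc, auc_2 = b$auc, delta = delta, z = z,
                 p = 2 * stats::pnorm(-abs(z)))
}

#' Crude incidence rate per 100 patient-years
#'
#' @param events Number of events.
#' @param n_patients Number of patients.
#' @param mean_followup_days Mean follow-up in days (365.25-day years).
#' @return Events per 100 patient-years.
#' @examples
#' incidence_rate(10, 1000, 365.25)  # 1.0
#' @export
incidence_rate <- function(events, n_patients, mean_followup_days) {
  stopifnot(events >= 0)
  py <- n_patients * mean_followup_days / 365.25
  if (py <= 0) stop("non-positive patient-year denominator", call. = FALSE)
  events / py * 100
}
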