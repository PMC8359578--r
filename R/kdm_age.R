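#' Fit the Klemera-Doubal biological age model
#'
#' For each parameter x_j, fits the ordinary least-squares regression of x_j
#' on chronological age (CA), giving slope k_j, intercept q_j, residual root
#' mean squared error s_j (population form, dividing by n) and Pearson age
#' correlation r_j. Since the latent biological age the method is defined
#' against is unobservable, CA stands in for it in these regressions. The
#' characteristic correlation r_char aggregates the |r_j| (see
#' [compute_r_char()]), and the chronological-age weighting variance s2_BA
#' is estimated from the fitting cohort (see [compute_s2_ba()]).
#'
#' @param data Cohort tibble with `ca_years` (at least 3 patients).
#' @param columns Parameter columns (non-constant, not perfectly linear in
#'   age: a parameter with zero residual error or |r_j| = 1 makes the
#'   estimator degenerate and must be removed).
#' @return An object of class `"ba_kdm"`: `coefficients` (tibble `column`,
#'   `k`, `q`, `s`, `r`), `r_char`, `s2_ba`, `ca_min`, `ca_max`, `m`, `n`.
#' @export
fit_kdm <- function(data, columns) {
  stopifnot(all(columns %in% names(data)))
  n <- nrow(data)
  if (n < 3) stop("need at least 3 patients", call. = FALSE)
  ca <- data$ca_years
  if (stats::sd(ca) == 0) stop("chronological age is constant", call. = FALSE)

  coefs <- purrr::map_dfr(columns, function(cl) {
    x <- data[[cl]]
    if (stats::sd(x) == 0) {
      stop("column '", cl, "' is constant; remove it before fitting",
           call. = FALSE)
    }
    k <- stats::cov(x, ca) / stats::var(ca)
    q <- mean(x) - k * mean(ca)
    resid <- x - (q + k * ca)
    s <- sqrt(mean(resid^2))
    r <- stats::cor(x, ca)
    if (s == 0 || abs(r) >= 1) {
      stop("column '", cl, "' is an exact linear function of age ",
           "(zero residual error); remove it before fitting", call. = FALSE)
    }
    tibble::tibble(column = cl, k = k, q = q, s = s, r = r)
  })

  r_char <- compute_r_char(coefs$r)
  model <- kdm_model(coefs, r_char = r_char, s2_ba = Inf,
                     ca_min = min(ca), ca_max = max(ca), n = n)
  ba_e <- predict_ba_e(model, data)
  model$s2_ba <- compute_s2_ba(ba_e, ca, r_char,
                               c(model$ca_min, model$ca_max), model$m)
  model
}

#' Construct a Klemera-Doubal model from explicit coefficients
#'
#' Low-level constructor used by [fit_kdm()] and useful for evaluating the
#' estimators under known coefficients (e.g. noise-free parameter systems
#' where fitting would be degenerate).
#'
#' @param coefficients Tibble with columns `column`, `k`, `q`, `s` (and
#'   optionally `r`); `s` must be positive, `k` non-zero.
#' @param r_char Characteristic correlation (may be `NA` if only BA_E is
#'   needed).
#' @param s2_ba Chronological-age weighting variance (positive; `Inf` makes
#'   BA_EC equal BA_E).
#' @param ca_min,ca_max Age range of the fitting cohort.
#' @param n Number of patients the model was fitted on.
#' @return A `"ba_kdm"` object.
#' @export
kdm_model <- function(coefficients, r_char = NA_real_, s2_ba = Inf,
                      ca_min = NA_real_, ca_max = NA_real_, n = NA_integer_) {
  stopifnot(all(c("column", "k", "q", "s") %in% names(coefficients)),
            all(coefficients$s > 0), all(coefficients$k != 0))
  structure(list(
    coefficients = tibble::as_tibble(coefficients),
    r_char = r_char,
    s2_ba = s2_ba,
    ca_min = ca_min,
    ca_max = ca_max,
    m = nrow(coefficients),
    n = n
  ), class = "ba_kdm")
}

#' Characteristic correlation of a biomarker panel
#'
#' r_char = sum(r_j^2 / sqrt(1 - r_j^2)) / sum(r_j / sqrt(1 - r_j^2)),
#' evaluated on absolute correlations so that parameters declining with age
#' contribute with the same strength as those increasing (their direction is
#' already carried by the slope k_j).
#'
#' @param r Per-parameter age correlations with `|r| < 1`.
#' @return The characteristic correlation, a value in (0, 1) whenever at
#'   least one `0 < |r_j| < 1`.
#' @examples
#' compute_r_char(c(0.4, 0.4, 0.4))  # 0.4
#' @export
compute_r_char <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("|r| must be < 1 for every parameter", call. = FALSE)
  }
  a <- abs(r)
  w <- a / sqrt(1 - a^2)
  if (sum(w) == 0) stop("all correlations are zero", call. = FALSE)
  sum(a * w) / sum(w)
}

#' Chronological-age weighting variance s2_BA
#'
#' s2_BA = Var_n(BA_E - CA) - ((1 - r_char^2) / r_char^2) x
#' ((CA_max - CA_min)^2 / (12 m)), where Var_n is the population variance
#' (dividing by n). The subtracted term removes the sampling noise the m
#' biomarkers contribute to BA_E under a uniform age range; what remains
#' estimates the real dispersion of biological age around chronological age
#' and governs how strongly BA_EC shrinks toward CA. When the correction
#' exceeds the observed variance (possible at small n or weak panels) the
#' result is floored at 1e-8 with a warning.
#'
#' @param ba_e Per-patient BA_E values.
#' @param ca Per-patient chronological ages.
#' @param r_char Characteristic correlation in (0, 1].
#' @param ca_range Length-2 numeric, `c(CA_min, CA_max)`.
#' @param m Number of parameters in the panel.
#' @return The variance estimate (positive).
#' @export
compute_s2_ba <- function(ba_e, ca, r_char, ca_range, m) {
  stopifnot(length(ba_e) == length(ca), length(ba_e) >= 2,
            length(ca_range) == 2, m >= 1)
  if (is.na(r_char) || r_char <= 0) {
    stop("r_char must be positive", call. = FALSE)
  }
  d <- ba_e - ca
  var_n <- mean((d - mean(d))^2)
  correction <- (1 - r_char^2) / r_char^2 *
    (ca_range[2] - ca_range[1])^2 / (12 * m)
  s2 <- var_n - correction
  if (s2 <= 0) {
    warning("noise correction (", signif(correction, 4),
            ") exceeds Var(BA_E - CA) (", signif(var_n, 4),
            "); s2_BA floored at 1e-8", call. = FALSE)
    s2 <- 1e-8
  }
  s2
}

kdm_terms <- function(model, data) {
  missing <- setdiff(model$coefficients$column, names(data))
  if (length(missing) > 0) {
    stop("missing model column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  co <- model$coefficients
  x <- as.matrix(data[, co$column, drop = FALSE])
  num <- drop(sweep(x, 2, co$q) %*% (co$k / co$s^2))
  den <- sum((co$k / co$s)^2)
  list(num = num, den = den)
}

#' Klemera-Doubal biological age without age adjustment (BA_E)
#'
#' BA_E = sum_j (x_j - q_j) k_j / s_j^2 / sum_j (k_j / s_j)^2 — the
#' precision-weighted least-squares inversion of the per-parameter age
#' regressions.
#'
#' @param model A `"ba_kdm"` object.
#' @param data Cohort tibble containing every model column.
#' @return Per-patient BA_E in years.
#' @export
predict_ba_e <- function(model, data) {
  stopifnot(inherits(model, "ba_kdm"))
  t <- kdm_terms(model, data)
  t$num / t$den
}

#' Klemera-Doubal biological age with age adjustment (BA_EC)
#'
#' BA_EC = (sum_j (x_j - q_j) k_j / s_j^2 + CA / s2_BA) /
#' (sum_j (k_j / s_j)^2 + 1 / s2_BA): a precision-weighted compromise
#' between BA_E and chronological age, with weights set by the panel
#' precision and the variance s2_BA. Every BA_EC lies between BA_E and CA.
#'
#' @param model A `"ba_kdm"` object with positive `s2_ba`.
#' @param data Cohort tibble containing every model column.
#' @param ca Per-patient chronological age in years.
#' @return Per-patient BA_EC in years.
#' @export
predict_ba_ec <- function(model, data, ca) {
  stopifnot(inherits(model, "ba_kdm"), nrow(data) == length(ca))
  if (is.na(model$s2_ba) || model$s2_ba <= 0) {
    stop("model s2_ba must be positive", call. = FALSE)
  }
  t <- kdm_terms(model, data)
  if (is.infinite(model$s2_ba)) return(t$num / t$den)
  (t$num + ca / model$s2_ba) / (t$den + 1 / model$s2_ba)
}

#' Predict from a Klemera-Doubal model
#'
#' @param object A `"ba_kdm"` object.
#' @param newdata Cohort tibble with the model columns and `ca_years`.
#' @param ... Unused.
#' @return Tibble with `patient_id` (if present), `ca_years`, `ba_e_years`
#'   and `ba_ec_years`.
#' @export
predict.ba_kdm <- function(object, newdata, ...) {
  out <- tibble::tibble(
    ca_years = newdata$ca_years,
    ba_e_years = predict_ba_e(object, newdata),
    ba_ec_years = predict_ba_ec(object, newdata, newdata$ca_years)
  )
  if ("patient_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = newdata$patient_id), out
    )
  }
  out
}

#' @export
print.ba_kdm <- function(x, ...) {
  cat("Klemera-Doubal biological age model\n")
  cat("  parameters:", x$m, " patients:", x$n, "\n")
  cat("  r_char:", signif(x$r_char, 4), " s2_BA:", signif(x$s2_ba, 4), "\n")
  cat("  CA range: [", x$ca_min, ",", x$ca_max, "]\n")
  invisible(x)
}

#' Tidy a Klemera-Doubal model
#'
#' @param x A `"ba_kdm"` object.
#' @param ... Unused.
#' @return The per-parameter coefficient tibble (`column`, `k`, `q`, `s`,
#'   `r`).
#' @method tidy ba_kdm
#' @export
tidy.ba_kdm <- function(x, ...) {
  x$coefficients
}

#' Model-level summary of a `"ba_kdm"` fit
#'
#' @param x A `"ba_kdm"` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `m_parameters`, `r_char`, `s2_ba`, `ca_min`,
#'   `ca_max`.
#' @method glance ba_kdm
#' @export
glance.ba_kdm <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    m_parameters = x$m,
    r_char = x$r_char,
    s2_ba = x$s2_ba,
    ca_min = x$ca_min,
    ca_max = x$ca_max
  )
}
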