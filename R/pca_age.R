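#' Fit the principal-component biological age model
#'
#' Performs an unrotated eigendecomposition of the correlation matrix of the
#' selected (standardized) ECG parameters, keeps components with eigenvalue
#' >= `eigen_cutoff` (inclusive), and weights each retained component by its
#' share of age-explained variance: p_i = R2_i / sum(R2), where R2_i comes
#' from the univariate regression of chronological age on the component
#' scores. The calibration constant B is the standardized coefficient of the
#' regression of the weighted composite (pre-BA) on chronological age, i.e.
#' their Pearson correlation.
#'
#' Each eigenvector's sign is mathematically arbitrary; loadings are oriented
#' so every retained component correlates non-negatively with chronological
#' age, which makes the weighted composite well defined.
#'
#' @param data Cohort tibble with `ca_years`.
#' @param columns Parameter columns to model (more patients than columns
#'   required).
#' @param eigen_cutoff Minimum retained eigenvalue (default 1.0).
#' @return An object of class `"ba_pca"` with elements `columns`,
#'   `standardization`, `loadings` (parameters x components), `eigenvalues`
#'   (full spectrum), `m` (components retained), `weights` (p_i, summing
#'   to 1), `b` (calibration coefficient), `ca_mean`, `ca_sd`, `n`.
#' @export
fit_pca_age <- function(data, columns, eigen_cutoff = 1.0) {
  stopifnot(all(columns %in% names(data)))
  n <- nrow(data)
  if (n <= length(columns)) {
    stop("need more patients (", n, ") than parameters (", length(columns),
         ")", call. = FALSE)
  }
  std <- fit_standardization(data, columns)
  z <- as.matrix(apply_standardization(data, std)[, columns])
  cmat <- stats::cor(z)
  eig <- eigen(cmat, symmetric = TRUE)
  keep <- which(eig$values >= eigen_cutoff - 1e-12)
  if (length(keep) == 0) {
    stop("no eigenvalue >= ", eigen_cutoff, "; spectrum: ",
         paste(signif(eig$values, 4), collapse = ", "), call. = FALSE)
  }
  loadings <- eig$vectors[, keep, drop = FALSE]
  scores <- z %*% loadings
  ca <- data$ca_years

  # orient each component to correlate non-negatively with CA
  slopes <- drop(stats::cov(scores, ca))
  flip <- ifelse(slopes < 0, -1, 1)
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)

  r2 <- drop(stats::cor(scores, ca))^2
  if (sum(r2) == 0) {
    stop("no retained component correlates with chronological age",
         call. = FALSE)
  }
  weights <- r2 / sum(r2)
  pre_ba <- drop(scores %*% weights)
  b <- stats::cor(pre_ba, ca)
  dimnames(loadings) <- list(columns, paste0("PC", seq_along(keep)))

  structure(list(
    columns = columns,
    standardization = std,
    loadings = loadings,
    eigenvalues = eig$values,
    m = length(keep),
    weights = weights,
    b = b,
    ca_mean = mean(ca),
    ca_sd = stats::sd(ca),
    n = n
  ), class = "ba_pca")
}

#' Uncalibrated principal-component composite (pre-BA)
#'
#' Evaluates the weighted double sum over components and parameters:
#' pre-BA = sum_i p_i sum_j beta_ij z_j, with z_j the standardization stored
#' at fit time applied to the new data.
#'
#' @param model A `"ba_pca"` object.
#' @param data Cohort tibble containing every model column.
#' @return Numeric vector of per-patient pre-BA values (unitless).
#' @export
predict_pre_ba <- function(model, data) {
  stopifnot(inherits(model, "ba_pca"))
  missing <- setdiff(model$columns, names(data))
  if (length(missing) > 0) {
    stop("missing model column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  z <- as.matrix(apply_standardization(data, model$standardization)[
    , model$columns, drop = FALSE])
  drop(z %*% model$loadings %*% model$weights)
}

#' Calibrated principal-component biological age
#'
#' BA = pre-BA x sd(CA) + mean(CA) + (CA - mean(CA)) x (1 - B): the
#' composite is rescaled to the age distribution of the fitting cohort and
#' the share of age variance the composite does not track (1 - B) is
#' restored from chronological age itself.
#'
#' @param model A `"ba_pca"` object.
#' @param pre_ba Per-patient pre-BA (from [predict_pre_ba()]).
#' @param ca Per-patient chronological age in years.
#' @return Biological age in years.
#' @export
predict_ba <- function(model, pre_ba, ca) {
  stopifnot(inherits(model, "ba_pca"))
  pre_ba * model$ca_sd + model$ca_mean + (ca - model$ca_mean) * (1 - model$b)
}

#' Predict from a principal-component biological age model
#'
#' @param object A `"ba_pca"` object.
#' @param newdata Cohort tibble with the model columns and `ca_years`.
#' @param ... Unused.
#' @return Tibble with `patient_id` (if present in `newdata`), `ca_years`,
#'   `pre_ba` and `ba_years`.
#' @export
predict.ba_pca <- function(object, newdata, ...) {
  pre_ba <- predict_pre_ba(object, newdata)
  out <- tibble::tibble(
    ca_years = newdata$ca_years,
    pre_ba = pre_ba,
    ba_years = predict_ba(object, pre_ba, newdata$ca_years)
  )
  if ("patient_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(
      tibble::tibble(patient_id = newdata$patient_id), out
    )
  }
  out
}

#' @export
print.ba_pca <- function(x, ...) {
  cat("Principal-component biological age model\n")
  cat("  parameters:", length(x$columns), " patients:", x$n, "\n")
  cat("  components retained (eigenvalue >= 1):", x$m, "\n")
  cat("  calibration B:", signif(x$b, 4),
      " mean(CA):", signif(x$ca_mean, 4),
      " sd(CA):", signif(x$ca_sd, 4), "\n")
  invisible(x)
}

#' Tidy a principal-component biological age model
#'
#' @param x A `"ba_pca"` object.
#' @param ... Unused.
#' @return One row per component-by-parameter loading, with the component's
#'   eigenvalue and weight p_i.
#' @method tidy ba_pca
#' @export
tidy.ba_pca <- function(x, ...) {
  long <- tibble::as_tibble(x$loadings, rownames = "column") |>
    tidyr::pivot_longer(-"column", names_to = "component",
                        values_to = "loading")
  info <- tibble::tibble(
    component = colnames(x$loadings),
    eigenvalue = x$eigenvalues[seq_len(x$m)],
    weight = x$weights
  )
  dplyr::left_join(long, info, by = "component") |>
    dplyr::arrange(.data$component, .data$column)
}

#' Model-level summary of a `"ba_pca"` fit
#'
#' @param x A `"ba_pca"` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_parameters`, `m_components`, `b`,
#'   `ca_mean`, `ca_sd`.
#' @method glance ba_pca
#' @export
glance.ba_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_parameters = length(x$columns),
    m_components = x$m,
    b = x$b,
    ca_mean = x$ca_mean,
    ca_sd = x$ca_sd
  )
}
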