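#' Simulate a synthetic ECG-parameter cohort
#'
#' Generates a cohort with the statistical structure the biological-age
#' pipeline assumes: chronological age (CA) from a truncated normal on
#' \[`age_min`, `age_max`\]; a latent "true" biological age equal to CA plus
#' Gaussian noise; blocks of strongly intercorrelated ECG parameters, each
#' block driven by a shared latent that loads on true biological age with
#' correlation `age_loading`; uniform follow-up; and sparse mortality from an
#' exponential hazard whose log increases by `accel_log_hazard` per year of
#' biological-age acceleration (true biological age minus CA). Death causes
#' are split cardiovascular / non-cardiovascular with probability
#' `cv_fraction`.
#'
#' Within a block every parameter has correlation `sqrt(within_block_corr)`
#' with the block driver, so pairwise within-block correlations equal
#' `within_block_corr` in expectation — the regime the collinearity-pruning
#' step is designed for. Parameters are mapped to native units by fixed
#' per-parameter affine transforms with alternating sign, so roughly half the
#' parameters decrease with age (as R-wave amplitudes do). Parameter columns
#' take the first `n_blocks * block_size` names of the modelling catalogue.
#'
#' Each logical stage (ages, latent noise, sex, block drivers, measurement
#' noise, follow-up, deaths, causes) draws from its own stream seeded from
#' `seed`, so generation is reproducible and stages do not interleave.
#'
#' @param n_patients Number of patients.
#' @param seed Integer master seed.
#' @param age_mean,age_sd Target mean and SD in years of the realized
#'   (truncated) CA distribution (defaults 55.5 and 15.0); the parent normal
#'   is solved internally by moment matching.
#' @param age_min,age_max CA truncation bounds (defaults 20 and 90).
#' @param male_fraction Probability of male sex (default 0.537).
#' @param n_blocks,block_size Number of collinear parameter blocks and
#'   parameters per block (defaults 10 and 5; the product must not exceed
#'   the 438-parameter catalogue).
#' @param within_block_corr Expected pairwise correlation inside a block,
#'   in \[0, 1\] (default 0.95).
#' @param age_loading Correlation of each block driver with true biological
#'   age, in \[0, 1\] (default 0.7).
#' @param latent_noise_sd SD in years of the biological-age deviation from
#'   CA (default 5; 0 gives the noise-free degenerate cohort).
#' @param followup_max_days Upper bound of the uniform follow-up draw
#'   (default 1095.75, three 365.25-day years).
#' @param hazard_per_100py Baseline all-cause death rate per 100
#'   patient-years (default 0.5).
#' @param cv_fraction Fraction of deaths that are cardiovascular
#'   (default 23/55).
#' @param accel_log_hazard Log-hazard increment per year of biological-age
#'   acceleration (default 0.25; the baseline hazard is deliberately flat in
#'   chronological age so that discrimination isolates the biological-aging
#'   signal, and this per-year effect sizes that signal to be detectable in
#'   cohorts of a few thousand patients over a three-year window).
#' @return A tibble in the [read_cohort()] schema plus the generated ECG
#'   parameter columns. The latent truth (never consumed by the pipeline) is
#'   attached as attributes: retrieve per-patient true biological age with
#'   [latent_truth()] and the per-parameter generating loadings via
#'   `attr(x, "generator")`.
#' @export
simulate_cohort <- function(n_patients,
                            seed,
                            age_mean = 55.5, age_sd = 15.0,
                            age_min = 20, age_max = 90,
                            male_fraction = 0.537,
                            n_blocks = 10, block_size = 5,
                            within_block_corr = 0.95,
                            age_loading = 0.7,
                            latent_noise_sd = 5,
                            followup_max_days = 1095.75,
                            hazard_per_100py = 0.5,
                            cv_fraction = 23 / 55,
                            accel_log_hazard = 0.25) {
  stopifnot(n_patients >= 1, age_sd > 0, latent_noise_sd >= 0,
            male_fraction >= 0, male_fraction <= 1,
            within_block_corr >= 0, within_block_corr <= 1,
            age_loading >= 0, age_loading <= 1,
            cv_fraction >= 0, cv_fraction <= 1,
            hazard_per_100py > 0, followup_max_days > 0,
            n_blocks >= 1, block_size >= 1)
  if (n_blocks * block_size > 438) {
    stop("n_blocks * block_size exceeds the 438-parameter catalogue",
         call. = FALSE)
  }
  if (block_size < 2 && within_block_corr > 0) {
    stop("within_block_corr > 0 requires block_size >= 2", call. = FALSE)
  }

  n <- n_patients
  seeds <- stage_seeds(seed, 8)

  # chronological age: truncated normal whose realized moments match the
  # configured mean/sd (parent parameters solved by moment matching)
  parent <- trunc_norm_parent(age_mean, age_sd, age_min, age_max)
  set.seed(seeds[1])
  lo <- stats::pnorm((age_min - parent[1]) / parent[2])
  hi <- stats::pnorm((age_max - parent[1]) / parent[2])
  ca <- parent[1] + parent[2] * stats::qnorm(stats::runif(n, lo, hi))

  set.seed(seeds[2])
  true_ba <- ca + stats::rnorm(n, 0, latent_noise_sd)

  set.seed(seeds[3])
  sex <- ifelse(stats::runif(n) < male_fraction, "male", "female")

  # latent standardized biological age (theoretical scale; truncation only
  # mildly shrinks the realized SD and correlations are scale-free)
  z_sd <- sqrt(age_sd^2 + latent_noise_sd^2)
  z_true <- (true_ba - age_mean) / z_sd

  set.seed(seeds[4])
  drivers <- vapply(seq_len(n_blocks), function(b) {
    age_loading * z_true + sqrt(1 - age_loading^2) * stats::rnorm(n)
  }, numeric(n))
  drivers <- matrix(drivers, nrow = n)

  n_params <- n_blocks * block_size
  columns <- ecg_parameter_catalogue()$column[seq_len(n_params)]
  lambda <- sqrt(within_block_corr)
  set.seed(seeds[5])
  params <- matrix(NA_real_, nrow = n, ncol = n_params,
                   dimnames = list(NULL, columns))
  meta <- vector("list", n_params)
  for (p in seq_len(n_params)) {
    b <- ((p - 1) %/% block_size) + 1
    raw <- lambda * drivers[, b] +
      (if (within_block_corr < 1) sqrt(1 - lambda^2) * stats::rnorm(n) else 0)
    sgn <- if (p %% 2 == 0) -1 else 1
    scale_p <- c(2, 5, 10, 25, 50, 120, 0.5)[((p - 1) %% 7) + 1]
    offset_p <- 10 * (((p - 1) %% 11) + 1)
    params[, p] <- offset_p + sgn * scale_p * raw
    meta[[p]] <- tibble::tibble(column = columns[p], block = b,
                                loading = lambda, sign = sgn,
                                scale = scale_p, offset = offset_p)
  }

  set.seed(seeds[6])
  followup <- stats::runif(n, 0, followup_max_days)

  set.seed(seeds[7])
  rate_per_day <- hazard_per_100py / 100 / 365.25 *
    exp(accel_log_hazard * (true_ba - ca))
  t_death <- stats::rexp(n, rate = rate_per_day)
  died <- t_death <= followup

  set.seed(seeds[8])
  cv <- stats::runif(n) < cv_fraction

  out <- tibble::tibble(
    patient_id = sprintf("S%06d", seq_len(n)),
    sex = sex,
    ca_years = ca,
    followup_days = ifelse(died, t_death, followup),
    status = ifelse(died, "all_cause_death", "alive"),
    death_cause = dplyr::case_when(
      died & cv ~ "cardiovascular",
      died ~ "non_cardiovascular",
      .default = "none"
    ),
    flag_structural_heart_disease = FALSE,
    flag_pacing = FALSE,
    flag_tachyarrhythmia = FALSE,
    flag_indeterminate_axis = FALSE
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(params))
  attr(out, "latent_truth") <- tibble::tibble(
    patient_id = out$patient_id, true_ba_years = true_ba
  )
  attr(out, "generator") <- dplyr::bind_rows(meta)
  out
}

# Mean and sd of a normal(mu, sig) truncated to [a, b].
trunc_norm_moments <- function(mu, sig, a, b) {
  al <- (a - mu) / sig
  be <- (b - mu) / sig
  z <- stats::pnorm(be) - stats::pnorm(al)
  dm <- (stats::dnorm(al) - stats::dnorm(be)) / z
  v <- sig^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z - dm^2)
  c(mu + sig * dm, sqrt(v))
}

# Parent (mu, sig) such that the [a, b]-truncated normal has the target
# mean and sd; truncation otherwise shrinks the realized sd below the
# configured value.
trunc_norm_parent <- function(target_mean, target_sd, a, b) {
  stopifnot(target_mean > a, target_mean < b, target_sd < (b - a) / 2)
  obj <- function(par) {
    m <- trunc_norm_moments(par[1], exp(par[2]), a, b)
    sum((m - c(target_mean, target_sd))^2)
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(fit$par[1], exp(fit$par[2]))
}

# Independent per-stage seeds derived from one master seed.
stage_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

#' Latent truth of a simulated cohort
#'
#' @param data A tibble from [simulate_cohort()].
#' @return Tibble with `patient_id` and `true_ba_years` (the latent true
#'   biological age used to generate parameters and mortality).
#' @export
latent_truth <- function(data) {
  truth <- attr(data, "latent_truth", exact = TRUE)
  if (is.null(truth)) stop("no latent truth attached; not a simulated cohort?",
                           call. = FALSE)
  truth
}

#' Within-block correlation summary of a simulated cohort
#'
#' Summarises realized pairwise correlations inside each generated parameter
#' block — the diagnostic used to confirm that the generator produces the
#' strong-collinearity regime the pruning step of parameter selection is
#' meant to handle.
#'
#' @param data A tibble from [simulate_cohort()].
#' @return Tibble with one row per block: `block`, `n_pairs`, `min_corr`,
#'   `median_corr`, `mean_corr`.
#' @export
empirical_block_correlation <- function(data) {
  meta <- attr(data, "generator", exact = TRUE)
  if (is.null(meta)) stop("no generator metadata; not a simulated cohort?",
                          call. = FALSE)
  meta |>
    dplyr::group_by(.data$block) |>
    dplyr::group_modify(function(rows, key) {
      cols <- rows$column
      if (length(cols) < 2) {
        return(tibble::tibble(n_pairs = 0L, min_corr = NA_real_,
                              median_corr = NA_real_, mean_corr = NA_real_))
      }
      cm <- abs(stats::cor(as.matrix(data[, cols])))
      vals <- cm[upper.tri(cm)]
      tibble::tibble(n_pairs = length(vals), min_corr = min(vals),
                     median_corr = stats::median(vals),
                     mean_corr = mean(vals))
    }) |>
    dplyr::ungroup()
}
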