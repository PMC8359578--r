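#' Stratified AUC evaluation of age predictors for mortality
#'
#' Evaluates how well chronological age and the biological age estimates
#' discriminate death over the (truncated) follow-up window, overall and
#' within chronological-age categories. For each outcome and stratum it
#' reports each predictor's Mann-Whitney AUC with a normal-approximation 95%
#' confidence interval (truncated to \[0, 1\]) and a DeLong z-test against
#' chance (AUC = 0.5); all pairwise paired DeLong comparisons between
#' predictors within a stratum; and unpaired DeLong comparisons of each
#' predictor across pairs of strata. Outcomes are binary end-of-follow-up
#' status: all-cause death, and cardiovascular death with non-cardiovascular
#' deaths kept in the control group. Strata in which either class is absent
#' (e.g. no deaths among the youngest patients) are marked not evaluable.
#'
#' @param data Tibble containing the predictor columns plus `ca_years`,
#'   `status` and `death_cause` (e.g. a cohort joined with [predict.ba_pca()]
#'   and [predict.ba_kdm()] output).
#' @param predictors Named character vector mapping predictor labels to
#'   column names. Default: CA, BA (principal-component), BA_E and BA_EC
#'   (Klemera-Doubal).
#' @param age_breaks Increasing interior cut points of the
#'   chronological-age categories (default `c(40, 60, 75)`, giving 20-39,
#'   40-59, 60-74 and >=75).
#' @param conf_level Confidence level for AUC intervals (default 0.95).
#' @return An object of class `"ba_roc_eval"`: a list of tibbles `auc`
#'   (per outcome/stratum/predictor), `paired` (within-stratum predictor
#'   comparisons) and `unpaired` (cross-stratum comparisons, total
#'   excluded). `tidy()` returns the `auc` table.
#' @export
evaluate_discrimination <- function(data,
                                    predictors = c(
                                      ca = "ca_years",
                                      ba = "ba_years",
                                      ba_e = "ba_e_years",
                                      ba_ec = "ba_ec_years"
                                    ),
                                    age_breaks = c(40, 60, 75),
                                    conf_level = 0.95) {
  stopifnot(all(predictors %in% names(data)),
            all(c("ca_years", "status", "death_cause") %in% names(data)),
            all(diff(age_breaks) > 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  strata <- age_strata(data$ca_years, age_breaks)
  stratum_levels <- c("total", levels(strata))
  outcomes <- list(
    all_cause_death = data$status == "all_cause_death",
    cardiovascular_death = data$death_cause == "cardiovascular"
  )

  auc_rows <- list()
  paired_rows <- list()
  unpaired_rows <- list()
  for (oc in names(outcomes)) {
    y <- outcomes[[oc]]
    for (st in stratum_levels) {
      in_st <- if (st == "total") rep(TRUE, nrow(data)) else strata == st
      y_st <- y[in_st]
      n_ev <- sum(y_st)
      n_ct <- sum(!y_st)
      evaluable <- n_ev >= 1 && n_ct >= 1
      for (pr in names(predictors)) {
        if (!evaluable) {
          auc_rows[[length(auc_rows) + 1]] <- tibble::tibble(
            outcome = oc, stratum = st, predictor = pr,
            n_events = n_ev, n_controls = n_ct, auc = NA_real_,
            se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
            p_vs_chance = NA_real_, evaluable = FALSE
          )
          next
        }
        res <- auc_mann_whitney(data[[predictors[pr]]][in_st], y_st)
        se <- sqrt(res$var)
        p_chance <- if (!is.na(se) && se > 0) {
          2 * stats::pnorm(-abs((res$auc - 0.5) / se))
        } else {
          NA_real_
        }
        auc_rows[[length(auc_rows) + 1]] <- tibble::tibble(
          outcome = oc, stratum = st, predictor = pr,
          n_events = n_ev, n_controls = n_ct, auc = res$auc, se = se,
          ci_lo = max(0, res$auc - zq * se),
          ci_hi = min(1, res$auc + zq * se),
          p_vs_chance = p_chance, evaluable = TRUE
        )
      }
      if (evaluable && n_ev >= 2 && n_ct >= 2) {
        combos <- utils::combn(names(predictors), 2)
        for (k in seq_len(ncol(combos))) {
          pa <- combos[1, k]
          pb <- combos[2, k]
          cmp <- delong_paired(data[[predictors[pa]]][in_st],
                               data[[predictors[pb]]][in_st], y_st)
          paired_rows[[length(paired_rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(outcome = oc, stratum = st,
                           predictor_a = pa, predictor_b = pb),
            cmp
          )
        }
      }
    }
    # cross-stratum comparisons of each predictor (unpaired; total excluded)
    ok <- vapply(levels(strata), function(st) {
      y_st <- y[strata == st]
      sum(y_st) >= 2 && sum(!y_st) >= 2
    }, logical(1))
    eval_strata <- levels(strata)[ok]
    skipped <- setdiff(levels(strata), eval_strata)
    if (length(skipped) > 0) {
      warning("stratum ", paste(skipped, collapse = ", "),
              " skipped for cross-stratum tests (fewer than 2 events or ",
              "2 non-events; outcome ", oc, ")", call. = FALSE)
    }
    if (length(eval_strata) >= 2) {
      combos <- utils::combn(eval_strata, 2)
      for (pr in names(predictors)) {
        for (k in seq_len(ncol(combos))) {
          s1 <- combos[1, k]
          s2 <- combos[2, k]
          cmp <- delong_unpaired(
            data[[predictors[pr]]][strata == s1], y[strata == s1],
            data[[predictors[pr]]][strata == s2], y[strata == s2]
          )
          unpaired_rows[[length(unpaired_rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(outcome = oc, predictor = pr,
                           stratum_1 = s1, stratum_2 = s2),
            cmp
          )
        }
      }
    }
  }

  structure(list(
    auc = dplyr::bind_rows(auc_rows),
    paired = dplyr::bind_rows(paired_rows),
    unpaired = dplyr::bind_rows(unpaired_rows),
    predictors = predictors,
    age_breaks = age_breaks,
    conf_level = conf_level
  ), class = "ba_roc_eval")
}

age_strata <- function(ca, breaks = c(40, 60, 75)) {
  lo <- c(-Inf, breaks)
  hi <- c(breaks, Inf)
  labels <- mapply(function(l, h) {
    if (is.infinite(l)) paste0(floor(min(ca, na.rm = TRUE)), "-", h - 1)
    else if (is.infinite(h)) paste0(">=", l)
    else paste0(l, "-", h - 1)
  }, lo, hi)
  cut(ca, breaks = c(lo, Inf)[seq_len(length(lo) + 1)],
      labels = labels, right = FALSE)
}

#' @export
print.ba_roc_eval <- function(x, ...) {
  cat("Stratified AUC evaluation (DeLong inference)\n")
  cat("  predictors:", paste(names(x$predictors), collapse = ", "), "\n")
  tot <- dplyr::filter(x$auc, .data$stratum == "total")
  for (oc in unique(tot$outcome)) {
    sub <- dplyr::filter(tot, .data$outcome == oc)
    cat("  ", oc, " (", sub$n_events[1], " events): ",
        paste(sprintf("%s=%.3f", sub$predictor, sub$auc), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a stratified AUC evaluation
#'
#' @param x A `"ba_roc_eval"` object.
#' @param ... Unused.
#' @return The per-outcome/stratum/predictor AUC tibble.
#' @method tidy ba_roc_eval
#' @export
tidy.ba_roc_eval <- function(x, ...) {
  x$auc
}

#' Plot a stratified AUC evaluation
#'
#' Dot-and-interval plot of AUCs with confidence intervals, faceted by
#' outcome, with a dashed chance line at 0.5.
#'
#' @param object A `"ba_roc_eval"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_roc_eval
#' @export
autoplot.ba_roc_eval <- function(object, ...) {
  df <- dplyr::filter(object$auc, .data$evaluable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$auc,
                                   colour = .data$predictor)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::labs(x = "chronological-age category", y = "AUC",
                  colour = "predictor") +
    ggplot2::theme_minimal()
}
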