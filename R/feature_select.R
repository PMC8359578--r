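#' Fit a per-column standardization model
#'
#' Records each column's sample mean and standard deviation (denominator
#' n - 1) on the modelling cohort, so the same transform can be applied to
#' new data.
#'
#' @param data Cohort tibble.
#' @param columns Character vector of parameter columns.
#' @return An object of class `"ba_standardization"`: a tibble with `column`,
#'   `mean`, `sd`.
#' @export
fit_standardization <- function(data, columns) {
  stopifnot(all(columns %in% names(data)))
  sds <- vapply(columns, function(cl) stats::sd(data[[cl]]), numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    bad <- columns[sds == 0 | is.na(sds)][1]
    stop("constant or degenerate column: '", bad, "'", call. = FALSE)
  }
  model <- tibble::tibble(
    column = columns,
    mean = vapply(columns, function(cl) mean(data[[cl]]), numeric(1)),
    sd = sds
  )
  structure(model, class = c("ba_standardization", class(model)))
}

#' Apply a standardization model
#'
#' @param data Cohort tibble containing every column of `model`.
#' @param model A `"ba_standardization"` object from [fit_standardization()].
#' @return `data` with the modelled columns replaced by their standardized
#'   values (x - mean) / sd.
#' @export
apply_standardization <- function(data, model) {
  missing <- setdiff(model$column, names(data))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(model))) {
    cl <- model$column[i]
    data[[cl]] <- (data[[cl]] - model$mean[i]) / model$sd[i]
  }
  data
}

#' Standardize parameter columns in place
#'
#' Convenience wrapper fitting and applying a standardization model on the
#' same data; the model is attached as the `"standardization"` attribute.
#'
#' @inheritParams fit_standardization
#' @return `data` with standardized columns.
#' @export
standardize_parameters <- function(data, columns) {
  model <- fit_standardization(data, columns)
  out <- apply_standardization(data, model)
  attr(out, "standardization") <- model
  out
}

#' Step 1: screen parameters by correlation with chronological age
#'
#' Computes, separately within each sex, the Pearson correlation of every
#' candidate parameter with chronological age and keeps those with
#' `|r| >= threshold`. The screen is applied to the absolute correlation
#' because parameters that decline with age (e.g. R-wave amplitudes) carry
#' as much aging signal as those that increase.
#'
#' @param data Cohort tibble with `sex` and `ca_years`.
#' @param columns Candidate parameter columns.
#' @param threshold Absolute age-correlation cut-off (default 0.2).
#' @return A `"ba_selection"` object: a list with one element per sex, each
#'   holding `age_correlations` (tibble of `column`, `r_age`), `step1_selected`
#'   and the threshold used. Pass to [prune_collinear()] to complete step 2.
#' @export
select_by_age_correlation <- function(data, columns, threshold = 0.2) {
  stopifnot(threshold >= 0, all(columns %in% names(data)))
  sexes <- sort(unique(data$sex))
  per_sex <- lapply(sexes, function(sx) {
    sub <- data[data$sex == sx, , drop = FALSE]
    if (nrow(sub) < 3) {
      stop("fewer than 3 patients of sex '", sx, "'", call. = FALSE)
    }
    if (stats::sd(sub$ca_years) == 0) {
      stop("chronological age is constant within sex '", sx, "'",
           call. = FALSE)
    }
    r <- vapply(columns, function(cl) {
      if (stats::sd(sub[[cl]]) == 0) {
        stop("column '", cl, "' is constant within sex '", sx,
             "'; correlation undefined", call. = FALSE)
      }
      stats::cor(sub[[cl]], sub$ca_years)
    }, numeric(1))
    corr <- tibble::tibble(column = columns, r_age = unname(r))
    list(
      sex = sx,
      age_correlations = corr,
      step1_selected = corr$column[abs(corr$r_age) >= threshold],
      age_threshold = threshold
    )
  })
  names(per_sex) <- sexes
  structure(list(per_sex = per_sex, age_threshold = threshold),
            class = "ba_selection")
}

#' Step 2: prune strongly correlated parameter pairs
#'
#' Within each sex, evaluates pairwise correlations among the step-1
#' survivors and flags pairs with `|r| >= threshold` as strong correlations.
#' A parameter is retained iff it belongs to no strong pair, or its step-1
#' absolute age-correlation strictly exceeds that of every strong-pair
#' partner. Exact ties are broken toward the lexicographically first column
#' name (deterministic; recorded in the report). The scan is over unordered
#' pairs; the ordered-pair count X(X-1) conventionally quoted for such scans
#' is reported alongside.
#'
#' @param data Cohort tibble (same one used for step 1).
#' @param selection A `"ba_selection"` from [select_by_age_correlation()].
#' @param threshold Absolute pairwise-correlation cut-off defining a strong
#'   correlation (default 0.9).
#' @return The completed `"ba_selection"`: per sex adds `strong_pairs`
#'   (tibble `col_a`, `col_b`, `r_pair`), `step2_selected`, `drop_reasons`
#'   and `n_ordered_pairs`.
#' @export
prune_collinear <- function(data, selection, threshold = 0.9) {
  stopifnot(inherits(selection, "ba_selection"), threshold > 0)
  selection$collinearity_threshold <- threshold
  selection$per_sex <- lapply(selection$per_sex, function(sel) {
    sub <- data[data$sex == sel$sex, , drop = FALSE]
    cand <- sel$step1_selected
    r_age <- stats::setNames(abs(sel$age_correlations$r_age),
                             sel$age_correlations$column)[cand]
    if (length(cand) < 2) {
      sel$strong_pairs <- tibble::tibble(col_a = character(),
                                         col_b = character(),
                                         r_pair = numeric())
      sel$step2_selected <- cand
      sel$drop_reasons <- tibble::tibble(column = character(),
                                         reason = character())
      sel$n_ordered_pairs <- ordered_pair_count(length(cand))
      return(sel)
    }
    cm <- stats::cor(as.matrix(sub[, cand]))
    pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
    strong <- tibble::tibble(
      col_a = cand[pairs[, 1]],
      col_b = cand[pairs[, 2]],
      r_pair = cm[pairs]
    )
    partners <- lapply(cand, function(cl) {
      c(strong$col_b[strong$col_a == cl], strong$col_a[strong$col_b == cl])
    })
    names(partners) <- cand
    keep <- vapply(cand, function(cl) {
      ps <- partners[[cl]]
      if (length(ps) == 0) return(TRUE)
      # strict dominance over every partner; lexicographic tie-break
      all(r_age[cl] > r_age[ps] |
            (r_age[cl] == r_age[ps] & cl < ps))
    }, logical(1))
    sel$strong_pairs <- strong
    sel$step2_selected <- cand[keep]
    sel$drop_reasons <- tibble::tibble(
      column = cand[!keep],
      reason = "outranked_by_partner"
    )
    sel$n_ordered_pairs <- ordered_pair_count(length(cand))
    sel
  })
  selection
}

#' Ordered pair count of a step-2 collinearity scan
#'
#' Number of ordered pairs X(X-1) evaluated when all pairwise correlations
#' among X step-1 survivors are scanned excluding self-pairs; the unordered
#' scan the implementation performs covers X(X-1)/2 distinct pairs.
#'
#' @param x Number of step-1 selected parameters.
#' @return `x * (x - 1)`.
#' @examples
#' ordered_pair_count(71)  # 4970
#' ordered_pair_count(99)  # 9702
#' @export
ordered_pair_count <- function(x) {
  stopifnot(all(x >= 0))
  x * (x - 1)
}

#' Two-step parameter selection
#'
#' Runs the age-correlation screen and the collinearity pruning in one call.
#'
#' @inheritParams select_by_age_correlation
#' @param age_threshold Step-1 absolute age-correlation cut-off (default 0.2).
#' @param collinearity_threshold Step-2 strong-correlation cut-off
#'   (default 0.9).
#' @return A completed `"ba_selection"` object.
#' @export
select_parameters <- function(data, columns, age_threshold = 0.2,
                              collinearity_threshold = 0.9) {
  sel <- select_by_age_correlation(data, columns, threshold = age_threshold)
  prune_collinear(data, sel, threshold = collinearity_threshold)
}

#' Final parameter list from a selection
#'
#' Combines the per-sex step-2 selections into the column list used for
#' model fitting. `"union"` (the default) keeps every parameter selected in
#' at least one sex: under strong within-block collinearity the per-sex
#' pruning keeps an essentially arbitrary member of each block, so the
#' intersection of per-sex survivor sets can lose whole blocks even when
#' both sexes carry the signal; the union preserves block coverage at the
#' cost of possibly retaining near-duplicates across sexes.
#'
#' @param selection A completed `"ba_selection"`.
#' @param mode `"union"`, `"intersection"`, or one of the sexes present.
#' @return Character vector of column names.
#' @export
selected_parameters <- function(selection,
                                mode = c("union", "intersection",
                                         "male", "female")) {
  mode <- match.arg(mode)
  lists <- lapply(selection$per_sex, `[[`, "step2_selected")
  if (mode %in% names(lists)) return(lists[[mode]])
  if (mode == "intersection") return(Reduce(intersect, lists))
  sort(unique(unlist(lists)))
}

#' @export
print.ba_selection <- function(x, ...) {
  cat("Two-step ECG parameter selection\n")
  cat("  step-1 |r(age)| threshold:", x$age_threshold, "\n")
  if (!is.null(x$collinearity_threshold)) {
    cat("  step-2 strong-correlation threshold:",
        x$collinearity_threshold, "\n")
  }
  for (sel in x$per_sex) {
    cat("  ", sel$sex, ": ", length(sel$step1_selected), " after step 1",
        sep = "")
    if (!is.null(sel$step2_selected)) {
      cat(" -> ", length(sel$step2_selected), " after step 2 (",
          sel$n_ordered_pairs, " ordered pairs scanned)", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Tidy a parameter selection
#'
#' @param x A `"ba_selection"` object.
#' @param ... Unused.
#' @return One row per sex-by-parameter combination with the age
#'   correlation, selection outcome at each step, and drop reason.
#' @method tidy ba_selection
#' @export
tidy.ba_selection <- function(x, ...) {
  purrr::map_dfr(x$per_sex, function(sel) {
    sel$age_correlations |>
      dplyr::mutate(
        sex = sel$sex,
        step1_selected = .data$column %in% sel$step1_selected,
        step2_selected = if (!is.null(sel$step2_selected)) {
          .data$column %in% sel$step2_selected
        } else {
          NA
        },
        reason = dplyr::case_when(
          !step1_selected ~ "below_age_threshold",
          !step2_selected ~ "outranked_by_partner",
          .default = NA_character_
        ),
        .before = 1
      ) |>
      dplyr::relocate("sex")
  })
}
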