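test_that("the Mann-Whitney AUC agrees with brute force and trapezoid oracles", {
  # worked example: events {3, 1}, non-events {2, 0}
  expect_equal(auc_mann_whitney(c(3, 1, 2, 0),
                                c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  # all ties -> 0.5; perfect separation -> 1
  expect_equal(auc_mann_whitney(rep(2, 6), c(1, 1, 0, 0, 0, 1))$auc, 0.5)
  expect_equal(auc_mann_whitney(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1)

  set.seed(11)
  for (trial in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    res <- auc_mann_whitney(scores, labels)
    expect_equal(res$auc, auc_brute_force(scores, labels))
    expect_equal(res$auc, auc_trapezoid(scores, labels))
    # placement means reproduce the AUC from both directions
    expect_equal(mean(res$v_events), res$auc)
    expect_equal(mean(res$v_controls), res$auc)
  }
  expect_error(auc_mann_whitney(1:4, c(1, 1, 1, 1)), "both")
})

test_that("AUC complementarity holds on tie-free data", {
  set.seed(12)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.3)
  expect_equal(auc_mann_whitney(scores, labels)$auc +
                 auc_mann_whitney(-scores, labels)$auc, 1)
})

test_that("the paired DeLong test matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (trial in 1:10) {
    n <- 60
    z <- rnorm(n)
    a <- z + rnorm(n)
    b <- 0.5 * z + rnorm(n)
    labels <- rbinom(n, 1, 0.35)
    if (sum(labels) < 2 || sum(labels) > n - 2) next
    ours <- delong_paired(a, b, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, a, quiet = TRUE, direction = "<"),
      pROC::roc(labels, b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE
    )
    expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-8)
    expect_equal(ours$delta,
                 as.numeric(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-10)
  }
})

test_that("paired DeLong degenerate and symmetry cases behave", {
  set.seed(14)
  s <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  self <- delong_paired(s, s, labels)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)
  # swapping the arguments negates z and keeps p
  a <- rnorm(40); b <- rnorm(40)
  f <- delong_paired(a, b, labels)
  g <- delong_paired(b, a, labels)
  expect_equal(f$z, -g$z)
  expect_equal(f$p, g$p)
})

test_that("the unpaired DeLong test matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  n1 <- 70; n2 <- 50
  s1 <- rnorm(n1); y1 <- rbinom(n1, 1, 0.4)
  y2 <- rbinom(n2, 1, 0.4)
  s2 <- rnorm(n2) + 0.8 * y2
  ours <- delong_unpaired(s1, y1, s2, y2)
  ref <- pROC::roc.test(
    pROC::roc(y1, s1, quiet = TRUE, direction = "<"),
    pROC::roc(y2, s2, quiet = TRUE, direction = "<"),
    method = "delong", paired = FALSE
  )
  # same statistic; the reference p uses a t approximation, ours the normal
  expect_equal(ours$z, as.numeric(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$delta,
               as.numeric(ref$estimate[1] - ref$estimate[2]),
               tolerance = 1e-10)

  # identical distributions: z near 0; separated vs chance: |z| large
  set.seed(16)
  null <- delong_unpaired(rnorm(500), rbinom(500, 1, 0.3),
                          rnorm(500), rbinom(500, 1, 0.3))
  expect_lt(abs(null$z), 3)
  y_a <- rbinom(200, 1, 0.5)
  sep <- delong_unpaired(rnorm(200), rbinom(200, 1, 0.5),
                         y_a + 0L, y_a)
  expect_gt(abs(sep$z), 5)
})

test_that("incidence rates use 365.25-day patient-years", {
  expect_equal(incidence_rate(10, 1000, 365.25), 1.0)
  expect_equal(incidence_rate(0, 1000, 365.25), 0)
  expect_equal(round(incidence_rate(55, 12837, 320.4), 1), 0.5)
  expect_error(incidence_rate(5, 0, 100), "denominator")
})

test_that("stratified evaluation reports AUCs, skips empty strata, and nests totals", {
  set.seed(17)
  n <- 1200
  ca <- runif(n, 20, 90)
  risk <- scale(ca)[, 1] + rnorm(n)
  death <- rbinom(n, 1, plogis(-4 + 1.2 * risk))
  death[ca < 40] <- 0  # mirror the empty youngest stratum
  d <- tibble::tibble(
    ca_years = ca,
    ba_years = risk * 15 + 55,
    ba_e_years = risk * 20 + 50 + rnorm(n, 0, 5),
    ba_ec_years = risk * 18 + 52 + rnorm(n, 0, 3),
    status = ifelse(death == 1, "all_cause_death", "alive"),
    death_cause = ifelse(death == 1,
                         ifelse(runif(n) < 0.4, "cardiovascular",
                                "non_cardiovascular"), "none")
  )
  ev <- suppressWarnings(evaluate_discrimination(d))
  aucs <- tidy(ev)
  young <- dplyr::filter(aucs, .data$stratum == "20-39")
  expect_true(all(!young$evaluable))
  expect_true(all(is.na(young$auc)))
  tot <- dplyr::filter(aucs, .data$stratum == "total",
                       .data$outcome == "all_cause_death")
  expect_equal(nrow(tot), 4)
  expect_true(all(tot$ci_lo <= tot$auc & tot$auc <= tot$ci_hi))
  expect_true(all(tot$auc >= 0 & tot$auc <= 1))
  # total AUC equals a direct pooled computation
  direct <- auc_mann_whitney(d$ba_years, d$status == "all_cause_death")$auc
  expect_equal(tot$auc[tot$predictor == "ba"], direct)
  # CV outcome keeps non-CV deaths as controls
  cv <- dplyr::filter(aucs, .data$stratum == "total",
                      .data$outcome == "cardiovascular_death",
                      .data$predictor == "ba")
  expect_equal(cv$n_controls, sum(d$death_cause != "cardiovascular"))
  # paired comparisons cover all predictor pairs in evaluable strata
  expect_true(all(c("predictor_a", "predictor_b", "p") %in%
                    names(ev$paired)))
  expect_equal(nrow(dplyr::filter(ev$paired, .data$stratum == "total",
                                  .data$outcome == "all_cause_death")), 6)
  # cross-stratum tests exclude the total stratum
  expect_false("total" %in% c(ev$unpaired$stratum_1, ev$unpaired$stratum_2))
})

test_that("paired DeLong holds its nominal type-I error under a correlated null", {
  set.seed(18)
  reps <- 2000
  n <- 200
  rejections <- 0
  for (i in seq_len(reps)) {
    z <- rnorm(n)
    a <- z + rnorm(n)
    b <- z + rnorm(n)  # equally informative about nothing
    labels <- rbinom(n, 1, 0.3)
    p <- delong_paired(a, b, labels)$p
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.07)
})

test_that("a biological-age signal in the hazard is detectable at scale", {
  res <- suppressWarnings(run_pipeline(pipeline_config(n_patients = 10000,
                                                       seed = 42)))
  tot <- dplyr::filter(tidy(res$evaluation), .data$stratum == "total",
                       .data$outcome == "all_cause_death",
                       .data$predictor == "ba_e")
  expect_gt(tot$auc, 0.5)
  expect_gt(tot$ci_lo, 0.5)
})
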