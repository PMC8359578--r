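test_that("per-parameter regressions match hand-computed least squares", {
  cols <- cat_cols(1)
  d <- make_cohort(c(40, 50, 60, 70),
                   params = setNames(list(c(1, 2, 2, 3)), cols))
  model <- fit_kdm(d, cols)
  co <- tidy(model)
  expect_equal(co$k, 0.06)
  expect_equal(co$q, -1.3)
  expect_equal(co$s, sqrt(0.05))  # population RMSE: sqrt(SSE / n)
  expect_equal(co$r, cor(c(1, 2, 2, 3), c(40, 50, 60, 70)))
  expect_equal(model$ca_min, 40)
  expect_equal(model$ca_max, 70)
})

test_that("deterministic parameters are rejected at fit time", {
  cols <- cat_cols(2)
  ca <- c(40, 50, 60, 70)
  d <- make_cohort(ca, params = setNames(list(2 + 0.1 * ca,
                                              c(1, 2, 2, 3)), cols))
  expect_error(fit_kdm(d, cols), "exact linear function")
  d2 <- make_cohort(ca, params = setNames(list(rep(4, 4), c(1, 2, 2, 3)),
                                          cols))
  expect_error(fit_kdm(d2, cols), "constant")
})

test_that("the characteristic correlation follows its closed form", {
  expect_equal(compute_r_char(0.5), 0.5)
  expect_equal(compute_r_char(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(compute_r_char(c(0.3, 0.6)), 0.511372, tolerance = 1e-5)
  # negative correlations contribute through their magnitude
  expect_equal(compute_r_char(c(-0.3, 0.6)), compute_r_char(c(0.3, 0.6)))
  expect_error(compute_r_char(c(0.5, 1)), "< 1")
})

test_that("the age-weighting variance follows its closed form", {
  set.seed(1)
  ba_e <- rnorm(200, 50, 12)
  ca <- rnorm(200, 50, 10)
  d <- ba_e - ca
  var_n <- mean((d - mean(d))^2)
  # r_char -> 1: correction vanishes
  expect_equal(compute_s2_ba(ba_e, ca, 1, c(20, 90), 26), var_n)
  # zero age range: correction vanishes
  expect_equal(compute_s2_ba(ba_e, ca, 0.5, c(60, 60), 26), var_n)
  # worked arithmetic case: Var_n = 100, r_char = 0.5, range 70, m = 26
  x <- c(40, 60)  # population variance exactly 100
  expect_equal(compute_s2_ba(x, c(0, 0), 0.5, c(10, 80), 26),
               100 - 3 * 4900 / 312)
  # non-positive result floors with a warning
  expect_warning(out <- compute_s2_ba(c(50, 50.1), c(50, 50.05), 0.3,
                                      c(20, 90), 5),
                 "floored")
  expect_equal(out, 1e-8)
  expect_error(compute_s2_ba(ba_e, ca, 0, c(20, 90), 26), "positive")
})

test_that("BA_E equals the weighted-least-squares minimiser", {
  # m = 1 and x exactly on the regression line: BA_E = CA
  m1 <- kdm_model(tibble::tibble(column = cat_cols(1), k = 0.06,
                                 q = -1.3, s = 0.5))
  d1 <- make_cohort(55, params = setNames(list(-1.3 + 0.06 * 55),
                                          cat_cols(1)))
  expect_equal(predict_ba_e(m1, d1), 55)

  # random small panels against a numeric 1-D minimisation oracle
  set.seed(99)
  for (trial in 1:100) {
    m <- sample(1:5, 1)
    cols <- cat_cols(m)
    k <- runif(m, 0.2, 2) * sample(c(-1, 1), m, replace = TRUE)
    q <- runif(m, -10, 10)
    s <- runif(m, 0.2, 3)
    x <- runif(m, -20, 20)
    model <- kdm_model(tibble::tibble(column = cols, k = k, q = q, s = s))
    d <- make_cohort(50, params = as.list(setNames(x, cols)))
    expect_equal(predict_ba_e(model, d),
                 ba_e_wls_oracle(x, k, q, s, interval = c(-2000, 2000)),
                 tolerance = 1e-5)
  }
})

test_that("replicating the whole panel leaves BA_E unchanged", {
  # BA_E is a ratio of sums over parameters, so replicating every parameter
  # (same k, q, s, x) scales numerator and denominator alike; duplicating a
  # single parameter instead re-weights its individual estimate upward
  cols <- cat_cols(4)
  model2 <- kdm_model(tibble::tibble(column = cols[1:2],
                                     k = c(0.1, -0.3), q = c(1, 2),
                                     s = c(0.5, 1.2)))
  model4 <- kdm_model(tibble::tibble(column = cols,
                                     k = c(0.1, -0.3, 0.1, -0.3),
                                     q = c(1, 2, 1, 2),
                                     s = c(0.5, 1.2, 0.5, 1.2)))
  d <- make_cohort(40, params = as.list(setNames(c(5, -2, 5, -2), cols)))
  expect_equal(predict_ba_e(model4, d),
               predict_ba_e(model2, d[, c("patient_id", cols[1:2])]))

  # single-parameter duplication moves BA_E toward that parameter's own
  # age estimate (x - q) / k
  model3 <- kdm_model(tibble::tibble(column = cols[1:3],
                                     k = c(0.1, -0.3, -0.3),
                                     q = c(1, 2, 2), s = c(0.5, 1.2, 1.2)))
  d3 <- make_cohort(40, params = as.list(setNames(c(5, -2, -2), cols[1:3])))
  base <- predict_ba_e(model2, d3[, c("patient_id", cols[1:2])])
  dup <- predict_ba_e(model3, d3)
  t2 <- (-2 - 2) / -0.3
  expect_true(abs(dup - t2) < abs(base - t2))
})

test_that("BA_E is equivariant to rescaling a parameter with its coefficients", {
  cols <- cat_cols(2)
  k <- c(0.2, -0.5); q <- c(3, 1); s <- c(0.7, 1.1)
  x <- c(10, -4)
  base <- kdm_model(tibble::tibble(column = cols, k = k, q = q, s = s))
  d <- make_cohort(50, params = as.list(setNames(x, cols)))
  cc <- 7.3
  scaled <- kdm_model(tibble::tibble(column = cols,
                                     k = k * c(cc, 1), q = q * c(cc, 1),
                                     s = s * c(cc, 1)))
  d2 <- make_cohort(50, params = as.list(setNames(x * c(cc, 1), cols)))
  expect_equal(predict_ba_e(scaled, d2), predict_ba_e(base, d))
})

test_that("BA_EC interpolates between BA_E and CA", {
  cols <- cat_cols(2)
  model <- kdm_model(tibble::tibble(column = cols, k = c(0.1, -0.2),
                                    q = c(0, 5), s = c(0.4, 0.9)))
  d <- make_cohort(c(30, 70), params = setNames(list(c(4, 6), c(-8, 2)),
                                                cols))
  ba_e <- predict_ba_e(model, d)
  # s2 -> infinity: BA_EC -> BA_E
  model$s2_ba <- Inf
  expect_equal(predict_ba_ec(model, d, d$ca_years), ba_e)
  model$s2_ba <- 1e12
  expect_equal(predict_ba_ec(model, d, d$ca_years), ba_e, tolerance = 1e-6)
  # s2 -> 0+: BA_EC -> CA
  model$s2_ba <- 1e-12
  expect_equal(predict_ba_ec(model, d, d$ca_years), d$ca_years,
               tolerance = 1e-6)
  # betweenness for any finite positive s2
  for (s2 in c(0.1, 1, 10, 1000)) {
    model$s2_ba <- s2
    ba_ec <- predict_ba_ec(model, d, d$ca_years)
    expect_true(all(ba_ec >= pmin(ba_e, d$ca_years) - 1e-10))
    expect_true(all(ba_ec <= pmax(ba_e, d$ca_years) + 1e-10))
  }
})

test_that("BA_EC betweenness holds on full seeded fits", {
  for (seed in c(2, 14)) {
    d <- simulate_cohort(1000, seed = seed)
    model <- fit_kdm(d, ecg_parameter_columns(d))
    pred <- predict(model, d)
    expect_true(all(pred$ba_ec_years >=
                      pmin(pred$ba_e_years, d$ca_years) - 1e-10))
    expect_true(all(pred$ba_ec_years <=
                      pmax(pred$ba_e_years, d$ca_years) + 1e-10))
    gl <- glance(model)
    expect_gt(gl$r_char, 0)
    expect_lt(gl$r_char, 1)
    expect_gt(gl$s2_ba, 0)
  }
})

test_that("noise-free linear parameters recover the latent age exactly", {
  cols <- cat_cols(3)
  latent <- c(31.5, 47, 62.25, 80)
  k <- c(0.5, -1.2, 2)
  q <- c(10, 90, -30)
  model <- kdm_model(tibble::tibble(column = cols, k = k, q = q,
                                    s = c(1, 1, 1)))
  d <- make_cohort(latent, params = setNames(
    lapply(1:3, function(j) q[j] + k[j] * latent), cols))
  expect_equal(predict_ba_e(model, d), latent, tolerance = 1e-10)
})

test_that("fitted equal-correlation panels collapse r_char to the shared r", {
  # all parameters having the same |r| makes r_char equal it
  set.seed(5)
  n <- 20000
  cols <- cat_cols(2)
  z <- rnorm(n)
  ca <- 55 + 15 * z
  rho <- 0.6
  d <- make_cohort(ca, params = setNames(list(
    rho * z + sqrt(1 - rho^2) * rnorm(n),
    -(rho * z + sqrt(1 - rho^2) * rnorm(n))
  ), cols))
  # a 2-parameter panel is too weak for a positive s2_BA: flooring expected
  expect_warning(model <- fit_kdm(d, cols), "floored")
  expect_equal(model$r_char, rho, tolerance = 0.02)
})
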