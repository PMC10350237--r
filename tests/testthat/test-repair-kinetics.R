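test_that("kinetic model evaluates the closed form exactly", {
  # dose 0 (and omega 0) kills every term
  expect_equal(eval_repair_model(2, 0.3, 1.5, dose = 0, time = 5), 0)
  # at T = 0 only the residual term survives
  expect_equal(eval_repair_model(7, 0.9, 2, dose = 3, time = 0, irradiated = 1), 6)
  # direct substitution
  expect_equal(eval_repair_model(1, 0.5, 0, dose = 3, time = 2), 6 * exp(-1))
  # linear in dose
  expect_equal(eval_repair_model(1.3, 0.4, 0.7, dose = 6, time = 4),
               2 * eval_repair_model(1.3, 0.4, 0.7, dose = 3, time = 4))
  expect_error(eval_repair_model(1, 1, 1, dose = -1, time = 2),
               class = "drc_error_domain")
  expect_error(eval_repair_model(1, 1, 1, dose = 3, time = -2),
               class = "drc_error_domain")
})

test_that("model peaks at T = 1/Kdec and decays to the residual plateau", {
  for (kdec in c(0.2, 0.7, 1.5)) {
    tt <- seq(0.001, 40, by = 0.001)
    yy <- eval_repair_model(2, kdec, 0, dose = 3, time = tt, irradiated = 1)
    expect_equal(tt[which.max(yy)], 1 / kdec, tolerance = 1e-2)
    # asymptote: residual term only
    y_inf <- eval_repair_model(2, kdec, 1.2, dose = 3, time = 1e3 / kdec,
                               irradiated = 1)
    expect_equal(y_inf, 1.2 * 3, tolerance = 1e-6)
  }
})

test_that("normalization applies the control-subtraction rule", {
  series <- tibble::tibble(
    dose_gy = c(3, 3, 3, 3, 3, 0, 0),
    time_hr = c(1, 2, 3, 6, 20, 2, 20),
    signal = c(10, 12, 11, 8, 5, 2, 1))
  norm <- normalize_series(series)
  expect_equal(norm$time_hr, c(1, 2, 3, 6, 20))
  expect_equal(norm$signal_norm, c(8, 10, 9, 6, 4))

  # identical signal everywhere self-subtracts to zero
  flat <- series
  flat$signal <- 7
  expect_true(all(normalize_series(flat)$signal_norm == 0))

  # duplicate tube at one design point is rejected
  dup <- dplyr::bind_rows(series, tibble::tibble(dose_gy = 0, time_hr = 2,
                                                 signal = 2.5))
  expect_error(normalize_series(dup), "duplicate",
               class = "drc_error_incomplete")

  # missing points are listed
  expect_error(normalize_series(series[series$time_hr != 6 | series$dose_gy == 0, ]),
               "6", class = "drc_error_incomplete")
  expect_error(normalize_series(series[-7, ]), "20",
               class = "drc_error_incomplete")
})

test_that("residual parameter is pinned to the 20-hr point", {
  norm <- tibble::tibble(time_hr = c(1, 2, 3, 6, 20),
                         signal_norm = c(8, 10, 9, 6, 4))
  expect_identical(estimate_fres(norm), 4)
  norm$signal_norm[5] <- -0.3
  expect_identical(estimate_fres(norm), -0.3)
  expect_error(estimate_fres(norm[-5, ]), class = "drc_error_incomplete")

  # on model-generated data the 20-hr value is residual plus a vanishing
  # production remnant
  ser <- model_series(kprod = 1, kdec = 1, fres_scaled = 2, dose = 3)
  expect_equal(estimate_fres(ser), 2 + 3 * 20 * exp(-20), tolerance = 1e-12)
})

test_that("fitter recovers noiseless parameters and matches the grid oracle", {
  set.seed(101)
  for (i in 1:10) {
    kprod <- runif(1, 0.5, 3)
    kdec <- runif(1, 0.9, 2)     # residual term dominant at 20 hr
    fresD <- runif(1, 0.5, 3)
    ser <- model_series(kprod, kdec, fresD)
    fit <- fit_repair_params(ser, dose = 3)
    expect_equal(fit$kprod, kprod, tolerance = 1e-4)
    expect_equal(fit$kdec, kdec, tolerance = 1e-4)
    expect_equal(fit$fres_scaled, fresD, tolerance = 1e-4)
    expect_lt(fit$sse_log, 1e-10)
    oracle <- grid_fit_oracle(ser$time_hr, ser$signal_norm, 3, fit$fres_scaled)
    expect_lt(fit$sse_log, oracle$sse + 1e-6)
  }
})

test_that("fit is deterministic, idempotent, and flags degeneracy", {
  ser <- model_series(2, 1.5, 1)  # repair complete by 20 hr: pin self-consistent
  f1 <- fit_repair_params(ser, dose = 3)
  f2 <- fit_repair_params(ser, dose = 3)
  expect_identical(f1, f2)

  # refitting the model's own predictions returns the same parameters
  pred <- tibble::tibble(
    time_hr = ser$time_hr,
    signal_norm = eval_repair_model(f1$kprod, f1$kdec, f1$fres_scaled / 3,
                                    dose = 3, time = ser$time_hr,
                                    irradiated = 1))
  f3 <- fit_repair_params(pred, dose = 3)
  expect_equal(f3$kprod, f1$kprod, tolerance = 1e-6)
  expect_equal(f3$kdec, f1$kdec, tolerance = 1e-6)
  expect_equal(f3$fres_scaled, f1$fres_scaled, tolerance = 1e-6)

  zeros <- tibble::tibble(time_hr = c(1, 2, 3, 6, 20), signal_norm = rep(0, 5))
  expect_error(fit_repair_params(zeros, dose = 3), class = "drc_error_domain")
})

test_that("negative pinned residuals are retained and flagged", {
  ser <- model_series(2, 0.6, 1.5)
  ser$signal_norm[ser$time_hr == 20] <- -0.3
  fit <- fit_repair_params(ser, dose = 3)
  expect_equal(fit$fres_scaled, -0.3)
  expect_true(fit$fres_negative)
  expect_gt(fit$n_clipped, 0)  # negative residual clips the 20-hr log terms
})

test_that("cohort-level fitting keeps a skip list instead of dropping", {
  ch <- generate_cohort(cohort_config(n_pairs = 2, seed = 21))
  drop_row <- which(ch$signals$subtype == "CD56+" &
                      ch$signals$dose_gy > 0 & ch$signals$time_hr == 6 &
                      ch$signals$donor_id == ch$donors$donor_id[1])
  fit <- fit_cohort(ch$donors, ch$signals[-drop_row, ])
  expect_equal(nrow(fit$params), 27)
  expect_equal(nrow(fit$skipped), 1)
  expect_equal(fit$skipped$subtype, "CD56+")
  expect_match(fit$skipped$reason, "6")
})

test_that("parameter recovery is robust to lognormal measurement noise", {
  set.seed(77)
  n <- 200
  rel_err_kdec <- numeric(n)
  rel_err_fres <- numeric(n)
  for (i in seq_len(n)) {
    kprod <- runif(1, 0.7, 2); kdec <- runif(1, 0.25, 0.6)
    fresD <- runif(1, 1, 3)
    mu <- eval_repair_model(kprod, kdec, fresD / 3, dose = 3,
                            time = c(1, 2, 3, 6, 20), irradiated = 1)
    ser <- tibble::tibble(time_hr = c(1, 2, 3, 6, 20),
                          signal_norm = mu * exp(rnorm(5, 0, 0.1)))
    fit <- fit_repair_params(ser, dose = 3)
    rel_err_kdec[i] <- abs(fit$kdec - kdec) / kdec
    rel_err_fres[i] <- abs(fit$fres_scaled - fresD) / fresD
  }
  expect_lt(median(rel_err_kdec), 0.15)
  expect_lt(median(rel_err_fres), 0.15)
})
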