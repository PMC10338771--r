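test_that("nearest-in-time pairing breaks ties toward the earlier sample", {
  log <- make_log(model_si = 1, pred_si = c(10, 20),
                  model_t = 60, pred_t = c(59.98, 60.02))
  ser <- pair_streams(log, "nearest_in_time")
  expect_equal(ser$n_pairs, 1L)
  expect_equal(unname(ser$prediction[1, "SI"]), 10) # t = 59.98 wins the tie

  empty_pred <- fraction_log("P1", 1, "liver", "FTT", "G3_6_2_3", 1,
                             data.frame(time_s = 0, source = "model",
                                        err_si_mm = 0, err_lr_mm = 0,
                                        err_ap_mm = 0))
  expect_error(pair_streams(empty_pred), class = "ptv_insufficient_data")
})

test_that("window_mean pairs each model sample with its interval mean", {
  # predictions constant at c -> every pair is (m_i, c)
  log <- make_log(model_si = c(1, 2, 3), pred_si = rep(0.5, 6),
                  model_t = c(60, 120, 180), pred_t = seq(10, 180, by = 30))
  ser <- pair_streams(log, "window_mean")
  expect_equal(unname(ser$prediction[, "SI"]), rep(0.5, 3))
  # explicit windows: (0,60] -> mean(1,2); (60,120] -> mean(3,4)
  log2 <- make_log(model_si = c(0, 0), pred_si = c(1, 2, 3, 4),
                   model_t = c(60, 120), pred_t = c(10, 50, 70, 110))
  ser2 <- pair_streams(log2, "window_mean")
  expect_equal(unname(ser2$prediction[, "SI"]), c(1.5, 3.5))
})

test_that("pearson matches hand-computed product-moment values", {
  x <- c(0.5, 1.5, 2.5, 4)
  exact <- make_log(model_si = x, pred_si = x, pred_lr = -2 * x,
                    pred_ap = c(0, 1, 0, 1), model_ap = c(0, 1, 2, 4))
  r <- pearson(pair_streams(exact))
  expect_equal(unname(r["SI"]), 1)
  expect_equal(unname(r["LR"]), -1)

  zero <- make_log(model_si = c(0, 1, 2), pred_si = c(0, 1, 0))
  expect_equal(unname(pearson(pair_streams(zero))["SI"]), 0) # hand: cov = 0

  const <- make_log(model_si = c(1, 1, 1), pred_si = c(0, 1, 2),
                    model_lr = c(0, 1, 2), model_ap = c(0, 2, 1))
  expect_warning(rc <- pearson(pair_streams(const)), "constant")
  expect_true(is.na(rc["SI"]))

  two <- make_log(model_si = c(0, 1), pred_si = c(0, 1))
  expect_error(pearson(pair_streams(two)), class = "ptv_insufficient_data")
})

test_that("pearson is affine-invariant with sign flip on negative slope", {
  set.seed(21)
  base <- make_log(model_si = rnorm(20), pred_si = rnorm(20))
  r0 <- pearson(pair_streams(base))
  shifted <- base
  mrows <- shifted$samples$source == "model"
  shifted$samples$err_si_mm[mrows] <- 3 * shifted$samples$err_si_mm[mrows] + 2
  shifted$samples$err_si_mm[!mrows] <- -0.5 * shifted$samples$err_si_mm[!mrows] + 1
  r1 <- pearson(pair_streams(shifted))
  expect_equal(unname(r1["SI"]), -unname(r0["SI"]))
  expect_equal(unname(r1["LR"]), unname(r0["LR"]))
})

test_that("covariance_from_r is the plain product with domain checks", {
  expect_equal(covariance_from_r(2, 3, 0), 0)
  expect_equal(covariance_from_r(1, 1, 1), 1)
  expect_equal(covariance_from_r(0.8, 0.6, -0.5), -0.24)
  expect_error(covariance_from_r(1, 1, 1.2), class = "ptv_domain_error")
  # Cauchy-Schwarz bound holds for any admissible r
  set.seed(5)
  for (i in 1:50) {
    sm <- runif(1, 0, 3); sp <- runif(1, 0, 3); r <- runif(1, -1, 1)
    expect_lte(abs(covariance_from_r(sm, sp, r)), sm * sp + 1e-12)
  }
})

test_that("distance correlation hits its closed-form anchors", {
  x <- c(0.3, 1.1, 2.2, 3.5, 4.1)
  lin <- make_log(model_si = x, pred_si = 3 * x + 1, pred_lr = rep(2, 5))
  dc <- distance_correlation(pair_streams(lin))
  expect_equal(unname(dc["SI"]), 1, tolerance = 1e-12)
  expect_equal(unname(dc["LR"]), 0) # constant marginal -> zero distance variance
})

test_that("distance correlation is translation/positive-scale invariant", {
  set.seed(31)
  log <- make_log(model_si = rnorm(25), pred_si = rnorm(25))
  d0 <- distance_correlation(pair_streams(log))
  tr <- log
  mrows <- tr$samples$source == "model"
  tr$samples$err_si_mm[mrows] <- 5 * tr$samples$err_si_mm[mrows] - 7
  tr$samples$err_si_mm[!mrows] <- 0.2 * tr$samples$err_si_mm[!mrows] + 3
  d1 <- distance_correlation(pair_streams(tr))
  expect_equal(unname(d1["SI"]), unname(d0["SI"]), tolerance = 1e-10)
})

test_that("per-patient maximum is taken by magnitude with sign retained", {
  expect_equal(ptvmargins:::max_by_magnitude(c(0.1, -0.4, 0.2)), -0.4)
  expect_equal(ptvmargins:::max_by_magnitude(c(NA, 0.3)), 0.3)
  expect_true(is.na(ptvmargins:::max_by_magnitude(c(NA_real_, NA_real_))))
})

test_that("cohort aggregation averages per-patient maxima across patients", {
  set.seed(41)
  one <- cohort_log(list(make_log(rnorm(10), rnorm(10))))
  est <- fraction_covariance(one$fractions[[1]])
  agg <- cohort_covariance(one)
  expect_equal(agg$avg_max_cov_mm2, est$cov_mm2)
  expect_equal(agg$avg_max_r, est$pearson_r)

  # two patients with opposite per-patient covariances average toward zero
  x <- rnorm(12)
  pos <- make_log(model_si = x, pred_si = x, patient_id = "A")
  neg <- make_log(model_si = x, pred_si = -x, patient_id = "B")
  agg2 <- cohort_covariance(cohort_log(list(pos, neg)))
  expect_equal(agg2$avg_max_cov_mm2[agg2$direction == "SI"], 0, tolerance = 1e-12)
  expect_equal(agg2$n_patients[1], 2L)
})
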