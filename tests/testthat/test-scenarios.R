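# A fraction whose paired model/prediction samples have exactly zero Pearson
# correlation in every direction: model (0,1,2), prediction (0,1,0).
zero_cov_fraction <- function(fraction_index = 1L, patient_id = "P01") {
  make_log(model_si = c(0, 1, 2), pred_si = c(0, 1, 0),
           patient_id = patient_id, fraction_index = fraction_index)
}

test_that("adaptive plans freeze the fraction-1 covariance", {
  f1 <- zero_cov_fraction(1L)
  f2 <- zero_cov_fraction(2L)
  plan <- adaptive_margins(list(f1, f2))
  expect_s3_class(plan$fraction_1_margin, "margin_result")
  expect_equal(unname(plan$cov_from_fraction_1), rep(0, 3))
  expect_length(plan$later_fraction_margins, 1L)
  # zero fraction-1 covariance: later margins equal the covariance-free recipe
  expect_equal(plan$later_fraction_margins[["2"]]$margin_mm,
               vhf_extended(fraction_components(f2))$margin_mm)

  expect_error(adaptive_margins(list(f1)), class = "ptv_scenario_error")
  expect_error(adaptive_margins(list(f1, zero_cov_fraction(1L))),
               "duplicate", class = "ptv_scenario_error")
})

test_that("built-in positive correlation raises later margins above VHF", {
  cfg <- synth_config(n_patients = 4, fractions_per_patient = 2,
                      fraction_duration_s = 3600, prediction_cadence_s = 60,
                      rho = 0.5, seed = 915L)
  co <- simulate_cohort(cfg)
  signs <- vapply(split_by_patient_logs(co), function(fls) {
    plan <- adaptive_margins(fls)
    later <- plan$later_fraction_margins[[1]]
    vhf <- vhf_extended(fraction_components(fls[[2]]))
    sign(later$margin_mm[1] - vhf$margin_mm[1])
  }, numeric(1))
  expect_true(all(signs > 0))
})

test_that("freezing r instead of cov rescales by later-fraction SDs", {
  set.seed(77)
  x <- rnorm(12)
  f1 <- make_log(model_si = x, pred_si = x) # r = 1 in fraction 1
  f2 <- make_log(model_si = rnorm(12), pred_si = rnorm(12), fraction_index = 2L)
  plan <- adaptive_margins(list(f1, f2), freeze = "r")
  c2 <- fraction_components(f2)
  expect_equal(
    plan$later_fraction_margins[["2"]]$margin_mm,
    mvhf(c2, covariance_from_r(c2$sigma_mod, c2$sigma_pred,
                               plan$r_from_fraction_1))$margin_mm
  )
})

test_that("covariance envelopes are ordered, bracketing and degenerate-safe", {
  set.seed(19)
  fls <- lapply(1:4, function(i) {
    make_log(model_si = rnorm(10), pred_si = rnorm(10), fraction_index = i)
  })
  env <- covariance_envelope(fls)
  expect_true(all(env$cov_min_mm2 <= env$cov_max_mm2))
  expect_true(all(env$margin_at_min_mm <= env$margin_at_max_mm))
  per_fx <- attr(env, "per_fraction")
  for (d in directions()) {
    row <- env[env$direction == d, ]
    margins <- per_fx$margin_mm[per_fx$direction == d]
    expect_true(all(margins >= row$margin_at_min_mm - 1e-12))
    expect_true(all(margins <= row$margin_at_max_mm + 1e-12))
  }

  single <- covariance_envelope(fls[1])
  expect_equal(single$cov_min_mm2, single$cov_max_mm2)
  expect_equal(single$margin_at_min_mm, single$margin_at_max_mm)

  zero <- covariance_envelope(list(zero_cov_fraction()))
  expect_equal(zero$rel_diff_min_pct, rep(0, 3))
  expect_equal(zero$rel_diff_max_pct, rep(0, 3))
})

test_that("margin tables aggregate per site with the cohort covariance", {
  cfg <- synth_config(n_patients = 4, fractions_per_patient = 2,
                      prediction_cadence_s = 30, rho = 0, seed = 33L)
  co <- simulate_cohort(cfg)
  tab <- margin_table(co)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$direction, directions())
  expect_true(all(tab$vhf_mm > 0))
  expect_equal(tab$rel_diff_pct,
               100 * (tab$mvhf_mm - tab$vhf_mm) / tab$vhf_mm)

  # zero-error cohort: margins reduce to the static components exactly
  cfg0 <- synth_config(n_patients = 2, fractions_per_patient = 1,
                       prediction_cadence_s = 60,
                       systematic_sd_model = 0, systematic_sd_pred = 0,
                       random_sd_model = 0, random_sd_pred = 0, seed = 1L)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(abs(co0$fractions[[1]]$samples[, 3:5]) == 0))
  tab0 <- margin_table(co0)
  static <- assign_static(co0$fractions[[1]])
  expect_equal(
    tab0$vhf_mm,
    unname(2.5 * sqrt(static$Sigma_seg^2 + static$Sigma_def^2 + static$Sigma_tar^2))
  )
  expect_equal(tab0$mvhf_mm, tab0$vhf_mm)
})

test_that("per-patient margin tables carry the patient's max-|cov|", {
  cfg <- synth_config(n_patients = 3, fractions_per_patient = 2,
                      prediction_cadence_s = 30, rho = 0.4, seed = 87L)
  co <- simulate_cohort(cfg)
  pm <- patient_margins(co)
  expect_setequal(unique(pm$formalism), c("VHF_EXT", "MVHF"))
  expect_equal(nrow(pm), 3 * 2 * 3) # patients x formalisms x directions
  mv <- pm[pm$formalism == "MVHF", ]
  vh <- pm[pm$formalism == "VHF_EXT", ]
  expect_equal(sign(mv$margin_mm - vh$margin_mm), sign(mv$cov_mm2))
})
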