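test_that("summarize_fraction computes per-stream mean and n-1 SD", {
  log <- make_log(model_si = c(0.3, 0.3, 0.3), pred_si = c(-1, 1))
  s <- summarize_fraction(log)
  m <- s[s$source == "model" & s$direction == "SI", ]
  expect_equal(m$mean_mm, 0.3)
  expect_equal(m$sd_mm, 0)
  expect_equal(m$n, 3L)
  p <- s[s$source == "prediction" & s$direction == "SI", ]
  expect_equal(p$mean_mm, 0)
  expect_equal(p$sd_mm, sqrt(2)) # hand: var = ((-1)^2 + 1^2) / (2 - 1)
})

test_that("streams with fewer than 2 samples are rejected by name", {
  log <- make_log(model_si = c(0.1, 0.2), pred_si = 0.5)
  expect_error(summarize_fraction(log), "prediction",
               class = "ptv_insufficient_data")
})

test_that("population decomposition matches hand-computed Sigma and sigma", {
  # two patients; patient A fraction means 0, patient B fraction means 1 (SI)
  a <- make_log(model_si = c(-1, 1), pred_si = c(-1, 1))
  b <- make_log(model_si = c(0, 2), pred_si = c(0, 2), patient_id = "P02")
  pop <- population_errors(lapply(list(a, b), summarize_fraction))
  expect_equal(unname(pop$Sigma_mod["SI"]), sqrt(0.5)) # hand: sd(c(0, 1))
  expect_equal(unname(pop$sigma_mod["SI"]), sqrt(2))   # RMS of equal SDs
  expect_equal(pop$n_patients, 2L)

  # identical patient means in every fraction -> no systematic spread
  c1 <- make_log(model_si = c(-2, 2), pred_si = c(-2, 2), patient_id = "P03")
  c2 <- make_log(model_si = c(-2, 2), pred_si = c(-2, 2), patient_id = "P04")
  pop0 <- population_errors(lapply(list(c1, c2), summarize_fraction))
  expect_equal(unname(pop0$Sigma_mod), rep(0, 3))
})

test_that("population errors are permutation- and scale-covariant", {
  set.seed(7)
  logs <- lapply(1:6, function(i) {
    make_log(rnorm(4), rnorm(4), patient_id = sprintf("P%02d", (i - 1) %/% 2),
             fraction_index = (i - 1) %% 2 + 1)
  })
  pop <- population_errors(lapply(logs, summarize_fraction))
  pop_perm <- population_errors(lapply(rev(logs), summarize_fraction))
  expect_equal(pop[c("Sigma_mod", "sigma_mod", "Sigma_pred", "sigma_pred")],
               pop_perm[c("Sigma_mod", "sigma_mod", "Sigma_pred", "sigma_pred")])

  scaled <- lapply(logs, function(l) {
    l$samples[, 3:5] <- 3 * l$samples[, 3:5]
    l
  })
  pop3 <- population_errors(lapply(scaled, summarize_fraction))
  expect_equal(pop3$Sigma_mod, 3 * pop$Sigma_mod)
  expect_equal(pop3$sigma_pred, 3 * pop$sigma_pred)

  expect_error(population_errors(list(summarize_fraction(logs[[1]]))),
               class = "ptv_insufficient_cohort")
})

test_that("static assignment follows the motion rule and E2E table", {
  tab <- static_uncertainty_table()
  low <- make_log(c(0, 0), c(0, 0), motion_amplitude_cm = 1.5)
  high <- make_log(c(0, 0), c(0, 0), motion_amplitude_cm = 2.5)
  expect_equal(unname(assign_static(low, tab)$Sigma_def), rep(1.5, 3))
  expect_equal(unname(assign_static(high, tab)$Sigma_def), rep(2.5, 3))

  at <- make_log(c(0, 0), c(0, 0), motion_amplitude_cm = 2.0)
  expect_warning(st <- assign_static(at, tab), "threshold")
  expect_equal(unname(st$Sigma_def), rep(1.5, 3))

  vsi <- assign_static(low, tab)
  expect_equal(unname(vsi$Sigma_tar["SI"]), 0.53)
  expect_equal(unname(vsi$Sigma_seg), rep(0.54, 3))
  g3 <- make_log(c(0, 0), c(0, 0), ck_version = "G3_6_2_3",
                 tracking_mode = "FTT")
  expect_equal(unname(assign_static(g3, tab)$Sigma_tar), rep(0.3, 3))

  no_g3 <- static_uncertainty_table(e2e = list(
    VSI_8_5 = list(mean_mm = 0.3, sd_mm = 0.5)
  ))
  expect_error(assign_static(g3, no_g3), class = "ptv_config_error")
})

test_that("total tracking error combines contributors in quadrature", {
  log <- make_log(model_si = c(0, 0), pred_si = c(0, 0))
  s <- summarize_fraction(log)
  only_e2e <- total_tracking_error(s, list(mean_mm = 0.4, sd_mm = 0.7))
  expect_equal(unname(only_e2e$mean_mm), rep(0.4, 3))
  expect_equal(unname(only_e2e$sd_mm), rep(0.7, 3))

  s2 <- summarize_fraction(make_log(model_si = c(-3, 3) / sqrt(2),
                                    pred_si = c(-4, 4) / sqrt(2)))
  tot <- total_tracking_error(s2, list(mean_mm = 0, sd_mm = 0))
  expect_equal(unname(tot$sd_mm), rep(5, 3)) # 3-4-5 triangle
  s3 <- summarize_fraction(make_log(model_si = c(-1, 1) / sqrt(2),
                                    pred_si = c(-1, 1) / sqrt(2)))
  tot3 <- total_tracking_error(s3, list(mean_mm = 0, sd_mm = 1))
  expect_equal(unname(tot3$sd_mm), rep(sqrt(3), 3)) # hand quadrature (1,1,1)
})

test_that("static table config files round-trip known keys", {
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# custom table",
    "segmentation_sd_mm = 0.6",
    "deformation_high_mm = 3.0",
    "e2e_VSI_8_5_sd_si = 0.60",
    "e2e_G3_6_2_3_mean_ap = 0.45"
  ), p)
  tab <- read_static_table(p)
  expect_equal(tab$segmentation_sd_mm, 0.6)
  expect_equal(tab$deformation_high_mm, 3.0)
  expect_equal(unname(tab$e2e$VSI_8_5$sd_mm["SI"]), 0.6)
  expect_equal(unname(tab$e2e$G3_6_2_3$mean_mm["AP"]), 0.45)
  # untouched keys keep defaults
  expect_equal(tab$deformation_low_mm, 1.5)

  writeLines("segmentation_sd_mm = abc", p)
  expect_error(read_static_table(p), class = "ptv_config_error")
  writeLines("unknown_key = 1", p)
  expect_error(read_static_table(p), class = "ptv_config_error")
})
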