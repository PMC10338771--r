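# Fixture builders and independent oracles used across the suite.

# Build a fraction log from explicit per-stream error vectors (applied to all
# three directions unless lr/ap given). Model samples at 60 s cadence,
# prediction samples at the same timestamps plus optional extras.
make_log <- function(model_si, pred_si,
                     model_lr = model_si, model_ap = model_si,
                     pred_lr = pred_si, pred_ap = pred_si,
                     model_t = 60 * seq_along(model_si),
                     pred_t = 60 * seq_along(pred_si),
                     patient_id = "P01", fraction_index = 1L,
                     site = "upper_left_lung", tracking_mode = "XLT",
                     ck_version = "VSI_8_5", motion_amplitude_cm = 1.5) {
  samples <- rbind(
    data.frame(time_s = model_t, source = "model", err_si_mm = model_si,
               err_lr_mm = model_lr, err_ap_mm = model_ap),
    data.frame(time_s = pred_t, source = "prediction", err_si_mm = pred_si,
               err_lr_mm = pred_lr, err_ap_mm = pred_ap)
  )
  fraction_log(patient_id, fraction_index, site, tracking_mode, ck_version,
               motion_amplitude_cm, samples)
}

# O(n^2) brute-force sample distance correlation: explicit loops, written
# independently of the package implementation.
brute_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n)
  b <- matrix(0, n, n)
  for (j in 1:n) {
    for (k in 1:n) {
      a[j, k] <- abs(x[j] - x[k])
      b[j, k] <- abs(y[j] - y[k])
    }
  }
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (j in 1:n) {
    for (k in 1:n) {
      A[j, k] <- a[j, k] - mean(a[j, ]) - mean(a[, k]) + mean(a)
      B[j, k] <- b[j, k] - mean(b[j, ]) - mean(b[, k]) + mean(b)
    }
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  if (dcov2 <= 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# Textbook one-way ANOVA oracle: between/within mean squares via loops.
brute_anova_f <- function(groups) {
  all_obs <- unlist(groups)
  grand <- mean(all_obs)
  ss_b <- 0
  ss_w <- 0
  for (g in groups) {
    ss_b <- ss_b + length(g) * (mean(g) - grand)^2
    for (v in g) ss_w <- ss_w + (v - mean(g))^2
  }
  df_b <- length(groups) - 1
  df_w <- length(all_obs) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

split_by_patient_logs <- function(cohort) ptvmargins:::split_by_patient(cohort)

# Random admissible error-component set (for margin property sweeps).
random_components <- function() {
  error_components(
    Sigma_seg = runif(3, 0, 2), Sigma_def = runif(3, 0, 3),
    Sigma_mod = runif(3, 0, 2), Sigma_pred = runif(3, 0, 1),
    Sigma_tar = runif(3, 0, 1),
    sigma_mod = runif(3, 0.05, 2), sigma_pred = runif(3, 0.05, 1.5),
    sigma_rho = runif(1, 3, 9), beta = runif(1, 0.3, 1.2)
  )
}
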