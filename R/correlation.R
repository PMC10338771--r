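# Dependence between the correlation-model and prediction error streams.
#
# The two streams have very different cadences (model residuals roughly once
# a minute, prediction residuals on the delivery cadence), so they must be
# paired in time before any correlation can be estimated. The covariance that
# enters the modified margin recipe is formed as r * sd_model * sd_pred from
# the time-paired Pearson r and the per-fraction stream SDs. Distance
# correlation is computed as a nonparametric dependence diagnostic; it does
# not enter the margin recipe.

#' Pair model and prediction error streams in time
#'
#' @param log A [fraction_log] containing both streams.
#' @param rule `"nearest_in_time"`: each model sample is paired with the
#'   prediction sample closest in time (ties broken toward the earlier
#'   sample). `"window_mean"`: each model sample is paired with the mean
#'   prediction error over the interval since the previous model sample
#'   (from time 0 for the first); model samples with an empty window are
#'   dropped.
#' @return Object of class `paired_series`: list with `time` (model sample
#'   times), `model` and `prediction` (n x 3 error matrices, mm), `n_pairs`
#'   and `pairing_rule`.
#' @export
pair_streams <- function(log, rule = c("nearest_in_time", "window_mean")) {
  stopifnot(inherits(log, "fraction_log"))
  rule <- match.arg(rule)
  mod <- stream(log, "model")
  pred <- stream(log, "prediction")
  if (!nrow(mod$err) || !nrow(pred$err)) {
    ptv_error("ptv_insufficient_data",
              "both model and prediction streams must be non-empty for pairing")
  }
  if (rule == "nearest_in_time") {
    idx <- vapply(mod$time, function(tm) {
      d <- abs(pred$time - tm)
      # which.min returns the first (earliest) index on ties
      which.min(d)
    }, integer(1))
    pm <- pred$err[idx, , drop = FALSE]
    keep <- seq_along(mod$time)
  } else {
    lower <- c(-Inf, mod$time[-length(mod$time)])
    pm <- matrix(NA_real_, nrow = length(mod$time), ncol = 3L,
                 dimnames = list(NULL, directions()))
    for (i in seq_along(mod$time)) {
      in_win <- pred$time > lower[i] & pred$time <= mod$time[i]
      if (any(in_win)) pm[i, ] <- colMeans(pred$err[in_win, , drop = FALSE])
    }
    keep <- which(stats::complete.cases(pm))
    pm <- pm[keep, , drop = FALSE]
  }
  structure(
    list(time = mod$time[keep],
         model = mod$err[keep, , drop = FALSE],
         prediction = pm,
         n_pairs = length(keep),
         pairing_rule = rule),
    class = "paired_series"
  )
}

#' Pearson correlation between paired error streams
#'
#' Product-moment correlation per direction. A direction whose model or
#' prediction marginal is constant has no defined correlation and is reported
#' as `NA` (never coerced to 0); downstream cohort averaging excludes such
#' values with a logged count.
#'
#' @param series A [pair_streams()] result with at least 3 pairs.
#' @return Named per-direction numeric vector in `[-1, 1]`, `NA` where
#'   undefined.
#' @export
pearson <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  if (series$n_pairs < 3L) {
    ptv_error("ptv_insufficient_data",
              "correlation needs >= 3 pairs (got %d)", series$n_pairs)
  }
  r <- vapply(directions(), function(d) {
    x <- series$model[, d]
    y <- series$prediction[, d]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("undefined correlation in %s: constant marginal", d),
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  r
}

#' Covariance from a correlation coefficient and stream SDs
#'
#' The covariance between the model and prediction error streams is
#' reconstructed from their correlation coefficient and standard deviations,
#' `cov = r * sd_model * sd_prediction` (mm^2). This is the quantity added
#' (twice) to the combined random-error variance in the modified margin
#' recipe.
#'
#' @param sd_model,sd_prediction Stream SDs, mm (scalars or per-direction
#'   vectors).
#' @param r Correlation coefficient(s) in `[-1, 1]`; `NA` propagates.
#' @return Covariance in mm^2, same shape as the inputs.
#' @export
covariance_from_r <- function(sd_model, sd_prediction, r) {
  if (any(!is.na(r) & abs(r) > 1)) {
    ptv_error("ptv_domain_error", "|r| must be <= 1")
  }
  check_nonneg(sd_model[!is.na(sd_model)], "sd_model")
  check_nonneg(sd_prediction[!is.na(sd_prediction)], "sd_prediction")
  r * sd_model * sd_prediction
}

# Sample distance correlation of two numeric vectors (biased V-statistic
# version with double-centered pairwise-distance matrices). Returns 0 when
# either distance variance vanishes (a constant marginal).
dcor_xy <- function(x, y) {
  n <- length(x)
  A <- as.matrix(stats::dist(x))
  B <- as.matrix(stats::dist(y))
  A <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  B <- B - outer(rowMeans(B), rep(1, n)) - outer(rep(1, n), colMeans(B)) + mean(B)
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) return(0)
  dcov2 <- mean(A * B)
  if (dcov2 <= 0) return(0) # numerically tiny negatives clamp to independence
  sqrt(dcov2 / sqrt(dvar_x * dvar_y))
}

#' Distance correlation between paired error streams
#'
#' Sample distance correlation per direction via double-centered pairwise
#' distance matrices; lies in `[0, 1]`, equals 1 for an exact linear (or any
#' deterministic monotone affine) relation and 0 when a marginal is constant.
#' Diagnostic only: the margin recipes use Pearson-based covariance.
#'
#' @param series A [pair_streams()] result with at least 3 pairs.
#' @return Named per-direction numeric vector in `[0, 1]`.
#' @export
distance_correlation <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  if (series$n_pairs < 3L) {
    ptv_error("ptv_insufficient_data",
              "distance correlation needs >= 3 pairs (got %d)", series$n_pairs)
  }
  vapply(directions(), function(d) {
    dcor_xy(series$model[, d], series$prediction[, d])
  }, numeric(1))
}

#' Per-fraction covariance estimate
#'
#' Pairs the two streams, computes the Pearson r and distance correlation per
#' direction, and forms the covariance via [covariance_from_r()] using the
#' full per-fraction stream SDs.
#'
#' @param log A [fraction_log].
#' @param pairing Pairing rule, see [pair_streams()].
#' @return Object of class `covariance_estimate`: data.frame with columns
#'   `direction`, `pearson_r`, `cov_mm2`, `dcorr`, `n_pairs`, `sd_model_mm`,
#'   `sd_pred_mm`, and metadata attributes.
#' @export
fraction_covariance <- function(log, pairing = "nearest_in_time") {
  stopifnot(inherits(log, "fraction_log"))
  ser <- pair_streams(log, pairing)
  summ <- summarize_fraction(log)
  r <- withCallingHandlers(pearson(ser),
                           warning = function(w) invokeRestart("muffleWarning"))
  dc <- distance_correlation(ser)
  sd_m <- stats::setNames(summ$sd_mm[summ$source == "model"],
                          summ$direction[summ$source == "model"])[directions()]
  sd_p <- stats::setNames(summ$sd_mm[summ$source == "prediction"],
                          summ$direction[summ$source == "prediction"])[directions()]
  est <- data.frame(
    direction = directions(),
    pearson_r = r,
    cov_mm2 = covariance_from_r(sd_m, sd_p, r),
    dcorr = dc,
    n_pairs = ser$n_pairs,
    sd_model_mm = sd_m,
    sd_pred_mm = sd_p,
    stringsAsFactors = FALSE
  )
  rownames(est) <- NULL
  structure(est,
            patient_id = log$patient_id,
            fraction_index = log$fraction_index,
            site = log$site,
            class = c("covariance_estimate", "data.frame"))
}

# Signed extremum by absolute value: the element of x with the largest |x|,
# sign retained. Ties keep the earlier element.
max_by_magnitude <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  x[which.max(abs(x))]
}

#' Cohort-level covariance aggregation
#'
#' For each patient the maximum correlation and covariance over that
#' patient's fractions are extracted first ("maximum" taken by absolute
#' value with the sign retained, so that positively and negatively
#' correlated patients can cancel when averaged); the cohort value per
#' (site, direction) is then the arithmetic mean of the per-patient maxima.
#' Signed per-patient minimum/maximum covariances are reported alongside for
#' envelope analyses. Fractions with undefined correlation are excluded and
#' counted.
#'
#' @param cohort A [cohort_log].
#' @param pairing Pairing rule, see [pair_streams()].
#' @return data.frame with columns `site`, `direction`, `n_patients`,
#'   `avg_max_r`, `avg_max_cov_mm2`, `min_cov_mm2`, `max_cov_mm2`,
#'   `n_undefined` (count of excluded fraction-direction estimates).
#' @export
cohort_covariance <- function(cohort, pairing = "nearest_in_time") {
  stopifnot(inherits(cohort, "cohort_log"))
  ests <- lapply(cohort$fractions, function(fl) {
    tryCatch(fraction_covariance(fl, pairing),
             ptv_insufficient_data = function(e) NULL)
  })
  keep <- !vapply(ests, is.null, logical(1))
  if (!any(keep)) {
    ptv_error("ptv_insufficient_data", "no fraction yields a covariance estimate")
  }
  ests <- ests[keep]
  meta <- data.frame(
    patient = vapply(ests, attr, character(1), "patient_id"),
    site = vapply(ests, attr, character(1), "site"),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (st in unique(meta$site)) {
    in_site <- which(meta$site == st)
    for (d in directions()) {
      per_pat <- lapply(split(in_site, meta$patient[in_site]), function(ix) {
        covs <- vapply(ests[ix], function(e) e$cov_mm2[e$direction == d], numeric(1))
        rs <- vapply(ests[ix], function(e) e$pearson_r[e$direction == d], numeric(1))
        c(max_r = max_by_magnitude(rs),
          max_cov = max_by_magnitude(covs),
          min_cov = if (all(is.na(covs))) NA_real_ else min(covs, na.rm = TRUE),
          max_cov_signed = if (all(is.na(covs))) NA_real_ else max(covs, na.rm = TRUE),
          n_na = sum(is.na(covs)))
      })
      m <- do.call(rbind, per_pat)
      ok <- !is.na(m[, "max_cov"])
      rows[[length(rows) + 1L]] <- data.frame(
        site = st, direction = d, n_patients = sum(ok),
        avg_max_r = mean(m[ok, "max_r"]),
        avg_max_cov_mm2 = mean(m[ok, "max_cov"]),
        min_cov_mm2 = suppressWarnings(min(m[ok, "min_cov"])),
        max_cov_mm2 = suppressWarnings(max(m[ok, "max_cov_signed"])),
        n_undefined = sum(m[, "n_na"]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_na <- sum(out$n_undefined)
  if (n_na > 0) {
    message(sprintf("cohort_covariance: %d undefined fraction-direction estimate(s) excluded", n_na))
  }
  out
}
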