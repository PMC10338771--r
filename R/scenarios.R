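# Validation scenarios: adaptive first-fraction margins and covariance
# envelopes, plus the cohort-level margin table.
#
# Per-fraction margin evaluation needs a systematic SD even though one
# fraction contributes a single mean: the fraction's mean error magnitude is
# used as that fraction's systematic component and its stream SD as the
# random component. At the patient level the systematic component is the
# magnitude of the mean of fraction means and the random component the RMS of
# fraction SDs, consistent with the population decomposition.

take_dir <- function(summary, src, col) {
  x <- summary[summary$source == src, ]
  stats::setNames(x[[col]], x$direction)[directions()]
}

#' Error components of a single fraction
#'
#' Static components from the uncertainty table; model/prediction systematic
#' components as the magnitude of the fraction's mean errors; random
#' components as the fraction's stream SDs.
#'
#' @param log A [fraction_log].
#' @param static A [static_uncertainty_table()].
#' @param sigma_rho,beta Penumbra parameters, see [vhf_recipe()].
#' @return An [error_components()] object.
#' @export
fraction_components <- function(log, static = static_uncertainty_table(),
                                sigma_rho = 6.4, beta = 0.84) {
  summ <- summarize_fraction(log)
  st <- assign_static(log, static)
  error_components(
    Sigma_seg = st$Sigma_seg, Sigma_def = st$Sigma_def, Sigma_tar = st$Sigma_tar,
    Sigma_mod = abs(take_dir(summ, "model", "mean_mm")),
    Sigma_pred = abs(take_dir(summ, "prediction", "mean_mm")),
    sigma_mod = take_dir(summ, "model", "sd_mm"),
    sigma_pred = take_dir(summ, "prediction", "sd_mm"),
    sigma_rho = sigma_rho, beta = beta
  )
}

#' Error components pooled over one patient's fractions
#'
#' @param fractions List of [fraction_log]s, all from one patient.
#' @inheritParams fraction_components
#' @return An [error_components()] object.
#' @export
patient_components <- function(fractions, static = static_uncertainty_table(),
                               sigma_rho = 6.4, beta = 0.84) {
  stopifnot(length(fractions) >= 1L)
  summs <- lapply(fractions, summarize_fraction)
  st <- assign_static(fractions[[1L]], static)
  mean_of_means <- function(src) {
    m <- t(vapply(summs, take_dir, numeric(3), src, "mean_mm"))
    abs(colMeans(m))
  }
  rms_of_sds <- function(src) {
    s <- t(vapply(summs, take_dir, numeric(3), src, "sd_mm"))
    sqrt(colMeans(s^2))
  }
  error_components(
    Sigma_seg = st$Sigma_seg, Sigma_def = st$Sigma_def, Sigma_tar = st$Sigma_tar,
    Sigma_mod = mean_of_means("model"),
    Sigma_pred = mean_of_means("prediction"),
    sigma_mod = rms_of_sds("model"),
    sigma_pred = rms_of_sds("prediction"),
    sigma_rho = sigma_rho, beta = beta
  )
}

# Project cov onto the admissible Cauchy-Schwarz range for the given SDs.
clip_cov <- function(cov, sigma_mod, sigma_pred, context) {
  bound <- sigma_mod * sigma_pred
  clipped <- pmin(pmax(cov, -bound), bound)
  moved <- !is.na(cov) & abs(clipped - cov) > COV_TOL
  if (any(moved)) {
    warning(sprintf(
      "%s: covariance clipped to the Cauchy-Schwarz bound in %s",
      context, paste(directions()[moved], collapse = ", ")), call. = FALSE)
  }
  clipped
}

#' Adaptive first-fraction margin plan
#'
#' Scenario: the first treatment fraction is planned with the covariance-free
#' extended van Herk margin; the covariance observed in that fraction is then
#' carried into the covariance-modified margin of every later fraction.
#' Error components are re-estimated per fraction from that fraction's own
#' streams; only the covariance (default) or the correlation coefficient
#' (`freeze = "r"`) is frozen at the fraction-1 value.
#'
#' @param patient_fractions List of [fraction_log]s of one patient, >= 2
#'   fractions with unique indices.
#' @param static A [static_uncertainty_table()].
#' @param sigma_rho,beta Penumbra parameters.
#' @param pairing Pairing rule for covariance estimation.
#' @param freeze `"cov"` to reuse the fraction-1 covariance as-is; `"r"` to
#'   reuse the fraction-1 correlation and rescale by each later fraction's
#'   own stream SDs.
#' @return Object of class `adaptive_plan`: list with `patient_id`,
#'   `fraction_1_margin` (a `margin_result`), `cov_from_fraction_1`,
#'   `r_from_fraction_1`, and `later_fraction_margins` (named list of
#'   `margin_result`s keyed by fraction index).
#' @export
adaptive_margins <- function(patient_fractions,
                             static = static_uncertainty_table(),
                             sigma_rho = 6.4, beta = 0.84,
                             pairing = "nearest_in_time",
                             freeze = c("cov", "r")) {
  freeze <- match.arg(freeze)
  if (length(patient_fractions) < 2L) {
    ptv_error("ptv_scenario_error",
              "adaptive margins need >= 2 fractions (got %d)",
              length(patient_fractions))
  }
  pid <- unique(vapply(patient_fractions, `[[`, character(1), "patient_id"))
  if (length(pid) != 1L) {
    ptv_error("ptv_scenario_error", "fractions span multiple patients")
  }
  idx <- vapply(patient_fractions, `[[`, integer(1), "fraction_index")
  if (anyDuplicated(idx)) {
    ptv_error("ptv_scenario_error", "duplicate fraction indices for patient %s", pid)
  }
  ord <- order(idx)
  patient_fractions <- patient_fractions[ord]
  idx <- idx[ord]

  f1 <- patient_fractions[[1L]]
  est1 <- fraction_covariance(f1, pairing)
  cov1 <- stats::setNames(est1$cov_mm2, est1$direction)[directions()]
  r1 <- stats::setNames(est1$pearson_r, est1$direction)[directions()]
  comps1 <- fraction_components(f1, static, sigma_rho, beta)
  m1 <- vhf_extended(comps1)

  later <- list()
  for (k in seq_along(patient_fractions)[-1L]) {
    fk <- patient_fractions[[k]]
    ck <- fraction_components(fk, static, sigma_rho, beta)
    cov_k <- if (freeze == "cov") {
      cov1
    } else {
      covariance_from_r(ck$sigma_mod, ck$sigma_pred, r1)
    }
    cov_k[is.na(cov_k)] <- 0 # undefined fraction-1 correlation: no adjustment
    cov_k <- clip_cov(cov_k, ck$sigma_mod, ck$sigma_pred,
                      sprintf("%s fraction %d", pid, idx[k]))
    later[[as.character(idx[k])]] <- mvhf(ck, cov_k)
  }
  structure(
    list(patient_id = pid,
         fraction_1_margin = m1,
         cov_from_fraction_1 = cov1,
         r_from_fraction_1 = r1,
         freeze = freeze,
         later_fraction_margins = later),
    class = "adaptive_plan"
  )
}

#' @export
print.adaptive_plan <- function(x, ...) {
  cat(sprintf("<adaptive_plan> patient %s (%d later fraction(s), freeze = %s)\n",
              x$patient_id, length(x$later_fraction_margins), x$freeze))
  cat("  fraction-1 VHF margin (mm):",
      paste(sprintf("%s %.2f", x$fraction_1_margin$direction,
                    x$fraction_1_margin$margin_mm), collapse = ", "), "\n")
  cat("  fraction-1 covariance (mm^2):",
      paste(sprintf("%s %.3f", names(x$cov_from_fraction_1),
                    x$cov_from_fraction_1), collapse = ", "), "\n")
  invisible(x)
}

#' Covariance envelope for one patient
#'
#' Estimates the per-fraction model-prediction covariance across a patient's
#' fractions, takes the signed minimum and maximum per direction, and
#' evaluates the covariance-modified margin at both extremes using
#' patient-level pooled error components. The covariance-free margin on the
#' same components anchors the relative differences. Per-fraction covariances
#' are projected onto the admissible range of the pooled SDs when necessary.
#'
#' @inheritParams adaptive_margins
#' @return Object of class `covariance_envelope`: data.frame with one row per
#'   direction (`cov_min_mm2`, `cov_max_mm2`, `margin_at_min_mm`,
#'   `margin_at_max_mm`, `vhf_margin_mm`, `rel_diff_min_pct`,
#'   `rel_diff_max_pct`) with attributes `per_fraction` (long data.frame of
#'   per-fraction covariances and margins on the pooled components),
#'   `patient_id`, `site`, and `components`.
#' @export
covariance_envelope <- function(patient_fractions,
                                static = static_uncertainty_table(),
                                sigma_rho = 6.4, beta = 0.84,
                                pairing = "nearest_in_time") {
  if (!length(patient_fractions)) {
    ptv_error("ptv_scenario_error", "covariance envelope needs >= 1 fraction")
  }
  pid <- unique(vapply(patient_fractions, `[[`, character(1), "patient_id"))
  if (length(pid) != 1L) {
    ptv_error("ptv_scenario_error", "fractions span multiple patients")
  }
  comps <- patient_components(patient_fractions, static, sigma_rho, beta)
  ests <- lapply(patient_fractions, fraction_covariance, pairing = pairing)
  idx <- vapply(patient_fractions, `[[`, integer(1), "fraction_index")
  covs <- t(vapply(ests, function(e) {
    stats::setNames(e$cov_mm2, e$direction)[directions()]
  }, numeric(3)))
  covs <- t(apply(covs, 1L, clip_cov, comps$sigma_mod, comps$sigma_pred,
                  sprintf("patient %s envelope", pid)))
  if (all(is.na(covs))) {
    ptv_error("ptv_insufficient_data",
              "no defined covariance estimate in any fraction")
  }
  cov_min <- apply(covs, 2L, function(v) min(v, na.rm = TRUE))
  cov_max <- apply(covs, 2L, function(v) max(v, na.rm = TRUE))
  m_vhf <- vhf_extended(comps)
  m_min <- mvhf(comps, cov_min)
  m_max <- mvhf(comps, cov_max)
  per_fraction <- do.call(rbind, lapply(seq_along(idx), function(i) {
    mi <- mvhf(comps, ifelse(is.na(covs[i, ]), 0, covs[i, ]))
    data.frame(fraction_index = idx[i], direction = directions(),
               cov_mm2 = covs[i, ], margin_mm = mi$margin_mm,
               stringsAsFactors = FALSE)
  }))
  rownames(per_fraction) <- NULL
  out <- data.frame(
    direction = directions(),
    cov_min_mm2 = cov_min,
    cov_max_mm2 = cov_max,
    margin_at_min_mm = m_min$margin_mm,
    margin_at_max_mm = m_max$margin_mm,
    vhf_margin_mm = m_vhf$margin_mm,
    rel_diff_min_pct = relative_difference(m_min, m_vhf),
    rel_diff_max_pct = relative_difference(m_max, m_vhf),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            per_fraction = per_fraction,
            patient_id = pid,
            site = patient_fractions[[1L]]$site,
            components = comps,
            class = c("covariance_envelope", "data.frame"))
}

#' Per-patient margin table
#'
#' Evaluates the covariance-free and/or covariance-modified margin for each
#' patient from that patient's pooled error components; the modified margin
#' uses the patient's maximum-by-magnitude covariance over fractions (the
#' per-patient extraction strategy behind cohort averaging).
#'
#' @param cohort A [cohort_log].
#' @param method `"vhf"`, `"mvhf"` or `"both"`.
#' @param static A [static_uncertainty_table()].
#' @param sigma_rho,beta Penumbra parameters.
#' @param pairing Pairing rule.
#' @return data.frame with columns `patient_id`, `site`, `direction`,
#'   `formalism`, `margin_mm`, `cov_mm2`.
#' @export
patient_margins <- function(cohort, method = c("both", "vhf", "mvhf"),
                            static = static_uncertainty_table(),
                            sigma_rho = 6.4, beta = 0.84,
                            pairing = "nearest_in_time") {
  stopifnot(inherits(cohort, "cohort_log"))
  method <- match.arg(method)
  rows <- list()
  for (fls in split_by_patient(cohort)) {
    pid <- fls[[1L]]$patient_id
    comps <- patient_components(fls, static, sigma_rho, beta)
    covs <- t(vapply(fls, function(fl) {
      e <- fraction_covariance(fl, pairing)
      stats::setNames(e$cov_mm2, e$direction)[directions()]
    }, numeric(3)))
    cov <- apply(covs, 2L, max_by_magnitude)
    cov[is.na(cov)] <- 0
    cov <- clip_cov(cov, comps$sigma_mod, comps$sigma_pred,
                    sprintf("patient %s", pid))
    res <- list()
    if (method %in% c("both", "vhf")) res$VHF_EXT <- vhf_extended(comps)
    if (method %in% c("both", "mvhf")) res$MVHF <- mvhf(comps, cov)
    for (m in res) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, site = fls[[1L]]$site, direction = m$direction,
        formalism = m$formalism, margin_mm = m$margin_mm,
        cov_mm2 = if (m$formalism[1] == "MVHF") cov else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort margin table
#'
#' Per (site, direction): population systematic/random errors from the
#' site's patients, static components from the site's metadata (modal system
#' version, median motion amplitude), the cohort-aggregated covariance, and
#' the resulting covariance-free and covariance-modified margins with their
#' relative difference.
#'
#' @param cohort A [cohort_log] with >= 2 patients per site of interest.
#' @param static A [static_uncertainty_table()].
#' @param sigma_rho,beta Penumbra parameters.
#' @param pairing Pairing rule.
#' @return data.frame with columns `site`, `direction`, `n_patients`,
#'   `vhf_mm`, `mvhf_mm`, `rel_diff_pct`, `cov_mm2`, and the underlying
#'   component columns.
#' @export
margin_table <- function(cohort, static = static_uncertainty_table(),
                         sigma_rho = 6.4, beta = 0.84,
                         pairing = "nearest_in_time") {
  stopifnot(inherits(cohort, "cohort_log"))
  diags <- validate_cohort(cohort)
  if (length(diags)) {
    ptv_error("ptv_schema_error", "invalid cohort:\n%s",
              paste(diags, collapse = "\n"))
  }
  sites <- vapply(cohort$fractions, `[[`, character(1), "site")
  covtab <- suppressMessages(cohort_covariance(cohort, pairing))
  rows <- list()
  for (st in unique(sites)) {
    fls <- cohort$fractions[sites == st]
    summs <- lapply(fls, summarize_fraction)
    pop <- tryCatch(population_errors(summs), ptv_insufficient_cohort = function(e) NULL)
    if (is.null(pop)) {
      message(sprintf("margin_table: skipping site %s (fewer than 2 patients)", st))
      next
    }
    versions <- vapply(fls, `[[`, character(1), "ck_version")
    modal_version <- names(sort(table(versions), decreasing = TRUE))[1L]
    motion <- stats::median(vapply(fls, `[[`, numeric(1), "motion_amplitude_cm"))
    proto <- fls[[1L]]
    proto$ck_version <- modal_version
    proto$motion_amplitude_cm <- motion
    stat <- assign_static(proto, static)
    comps <- error_components(
      Sigma_seg = stat$Sigma_seg, Sigma_def = stat$Sigma_def,
      Sigma_tar = stat$Sigma_tar,
      Sigma_mod = pop$Sigma_mod, Sigma_pred = pop$Sigma_pred,
      sigma_mod = pop$sigma_mod, sigma_pred = pop$sigma_pred,
      sigma_rho = sigma_rho, beta = beta
    )
    ct <- covtab[covtab$site == st, ]
    cov <- stats::setNames(ct$avg_max_cov_mm2, ct$direction)[directions()]
    cov[is.na(cov)] <- 0
    cov <- clip_cov(cov, comps$sigma_mod, comps$sigma_pred,
                    sprintf("site %s", st))
    m_vhf <- vhf_extended(comps)
    m_mvhf <- mvhf(comps, cov)
    rows[[st]] <- data.frame(
      site = st, direction = directions(),
      n_patients = pop$n_patients,
      vhf_mm = m_vhf$margin_mm,
      mvhf_mm = m_mvhf$margin_mm,
      rel_diff_pct = relative_difference(m_mvhf, m_vhf),
      cov_mm2 = cov,
      Sigma_mod = comps$Sigma_mod, Sigma_pred = comps$Sigma_pred,
      sigma_mod = comps$sigma_mod, sigma_pred = comps$sigma_pred,
      Sigma_seg = comps$Sigma_seg, Sigma_def = comps$Sigma_def,
      Sigma_tar = comps$Sigma_tar,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
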