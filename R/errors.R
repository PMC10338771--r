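# Systematic/random error decomposition and static uncertainty assignment.
#
# The margin recipes consume five error sources per direction: segmentation,
# deformation, correlation-model, prediction and robot-targeting errors. The
# model and prediction components are estimated from tracking logs; the other
# three come from a static table (phantom studies and end-to-end tests).
# Conventions: the systematic SD (Sigma) of a log-derived source is the SD of
# per-patient mean errors; the random SD (sigma) is the RMS of per-fraction
# SDs. Sample SDs use the n-1 denominator throughout.

#' Per-fraction stream summary
#'
#' Mean, sample SD (denominator n-1) and sample count of each error stream
#' (model, prediction) in each direction of one fraction.
#'
#' @param log A [fraction_log] with at least 2 samples per stream.
#' @return Object of class `fraction_summary`: a data.frame with columns
#'   `source`, `direction`, `mean_mm`, `sd_mm`, `n`, plus the identifying
#'   metadata as attributes (`patient_id`, `fraction_index`, `site`).
#' @export
summarize_fraction <- function(log) {
  stopifnot(inherits(log, "fraction_log"))
  out <- list()
  for (src in .sources) {
    st <- stream(log, src)
    n <- nrow(st$err)
    if (n < 2L) {
      ptv_error("ptv_insufficient_data",
                "stream '%s' of %s fraction %d has %d sample(s); need >= 2",
                src, log$patient_id, log$fraction_index, n)
    }
    out[[src]] <- data.frame(
      source = src,
      direction = directions(),
      mean_mm = colMeans(st$err),
      sd_mm = apply(st$err, 2L, stats::sd),
      n = n,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res,
            patient_id = log$patient_id,
            fraction_index = log$fraction_index,
            site = log$site,
            class = c("fraction_summary", "data.frame"))
}

#' Population systematic and random errors from fraction summaries
#'
#' Implements the classical decomposition: per source and direction, each
#' patient's systematic error is the mean of its fraction means; the
#' population systematic SD (Sigma) is the SD over patient means; the random
#' SD (sigma) is the root mean square of all per-fraction SDs.
#'
#' @param summaries List of [summarize_fraction()] outputs, or a list of lists
#'   grouped by patient. Grouping is taken from each summary's `patient_id`
#'   attribute, so a flat list is fine.
#' @return A list with elements `Sigma_mod`, `Sigma_pred`, `sigma_mod`,
#'   `sigma_pred`, each a named per-direction numeric vector (mm), plus
#'   `n_patients` and `n_fractions`.
#' @export
population_errors <- function(summaries) {
  if (inherits(summaries, "fraction_summary")) summaries <- list(summaries)
  summaries <- unlist_summaries(summaries)
  pats <- vapply(summaries, attr, character(1), "patient_id")
  if (length(unique(pats)) < 2L) {
    ptv_error("ptv_insufficient_cohort",
              "population errors need >= 2 patients (got %d)",
              length(unique(pats)))
  }
  res <- list(n_patients = length(unique(pats)), n_fractions = length(summaries))
  for (src in .sources) {
    means <- t(vapply(summaries, function(s) {
      x <- s[s$source == src, ]
      stats::setNames(x$mean_mm, x$direction)[directions()]
    }, numeric(3)))
    sds <- t(vapply(summaries, function(s) {
      x <- s[s$source == src, ]
      stats::setNames(x$sd_mm, x$direction)[directions()]
    }, numeric(3)))
    patient_means <- apply(means, 2L, function(v) tapply(v, pats, mean))
    Sigma <- apply(patient_means, 2L, stats::sd)
    sigma <- sqrt(colMeans(sds^2))
    key <- if (src == "model") "mod" else "pred"
    res[[paste0("Sigma_", key)]] <- stats::setNames(Sigma, directions())
    res[[paste0("sigma_", key)]] <- stats::setNames(sigma, directions())
  }
  res
}

unlist_summaries <- function(x) {
  flat <- list()
  for (el in x) {
    if (inherits(el, "fraction_summary")) flat[[length(flat) + 1L]] <- el
    else if (is.list(el)) flat <- c(flat, unlist_summaries(el))
    else stop("summaries must be fraction_summary objects", call. = FALSE)
  }
  flat
}

#' Static uncertainty table
#'
#' Uncertainties not estimable from tracking logs: the segmentation SD from
#' phantom studies (0.54 mm, isotropic), the motion-amplitude rule for the
#' deformation SD (1.5 mm below 2 cm peak-to-peak motion, 2.5 mm above), and
#' per-system-version end-to-end (E2E) targeting test results (mean and SD
#' per direction).
#'
#' @param segmentation_sd_mm Isotropic segmentation SD, mm.
#' @param deformation_threshold_cm Motion amplitude separating the two
#'   deformation branches, cm.
#' @param deformation_low_mm,deformation_high_mm Deformation SD below/above
#'   the threshold, mm.
#' @param e2e Named list, one entry per system version, each a list with
#'   per-direction numeric vectors `mean_mm` and `sd_mm`.
#' @return Object of class `static_uncertainty_table`.
#' @export
static_uncertainty_table <- function(
    segmentation_sd_mm = 0.54,
    deformation_threshold_cm = 2.0,
    deformation_low_mm = 1.5,
    deformation_high_mm = 2.5,
    e2e = list(
      G3_6_2_3 = list(mean_mm = c(SI = 0.5, LR = 0.5, AP = 0.5),
                      sd_mm = c(SI = 0.3, LR = 0.3, AP = 0.3)),
      VSI_8_5 = list(mean_mm = c(SI = 0.37, LR = 0.12, AP = 0.15),
                     sd_mm = c(SI = 0.53, LR = 0.19, AP = 0.36)),
      VSI_9_5 = list(mean_mm = c(SI = 0.37, LR = 0.12, AP = 0.15),
                     sd_mm = c(SI = 0.53, LR = 0.19, AP = 0.36))
    )) {
  check_nonneg(c(segmentation_sd_mm, deformation_threshold_cm,
                 deformation_low_mm, deformation_high_mm),
               "static uncertainties")
  e2e <- lapply(e2e, function(v) {
    list(mean_mm = check_nonneg(as_direction_vector(v$mean_mm, "e2e mean"), "e2e mean"),
         sd_mm = check_nonneg(as_direction_vector(v$sd_mm, "e2e sd"), "e2e sd"))
  })
  structure(
    list(segmentation_sd_mm = segmentation_sd_mm,
         deformation_threshold_cm = deformation_threshold_cm,
         deformation_low_mm = deformation_low_mm,
         deformation_high_mm = deformation_high_mm,
         e2e = e2e),
    class = "static_uncertainty_table"
  )
}

#' Assign static uncertainty components for a fraction
#'
#' Segmentation SD is the table value, isotropic. The deformation SD follows
#' the motion-amplitude rule: `low_mm` when the center-of-mass peak-to-peak
#' motion is below the threshold, `high_mm` above it; motion exactly at the
#' threshold takes the lower branch with a warning (the rule does not cover
#' the boundary). The targeting SD is the end-to-end test SD for the log's
#' system version; the E2E mean offset is returned for reporting but does not
#' enter the margin recipes, which consume SDs only.
#'
#' @param log A [fraction_log] (supplies motion amplitude and version).
#' @param table A [static_uncertainty_table()].
#' @return List with per-direction vectors `Sigma_seg`, `Sigma_def`,
#'   `Sigma_tar` and `e2e_mean` (all mm).
#' @export
assign_static <- function(log, table = static_uncertainty_table()) {
  stopifnot(inherits(log, "fraction_log"),
            inherits(table, "static_uncertainty_table"))
  if (!log$ck_version %in% names(table$e2e)) {
    ptv_error("ptv_config_error", "no E2E entry for system version '%s'",
              log$ck_version)
  }
  motion <- log$motion_amplitude_cm
  thr <- table$deformation_threshold_cm
  if (motion == thr) {
    warning(sprintf(
      "motion amplitude exactly at %.1f cm threshold: assigning lower deformation branch",
      thr), call. = FALSE)
  }
  def <- if (motion > thr) table$deformation_high_mm else table$deformation_low_mm
  e2e <- table$e2e[[log$ck_version]]
  list(
    Sigma_seg = as_direction_vector(table$segmentation_sd_mm),
    Sigma_def = as_direction_vector(def),
    Sigma_tar = e2e$sd_mm,
    e2e_mean = e2e$mean_mm
  )
}

#' Read a static uncertainty table from a key-value config file
#'
#' Plain-text `key = value` lines (comments with `#`). Recognized keys:
#' `segmentation_sd_mm`, `deformation_threshold_cm`, `deformation_low_mm`,
#' `deformation_high_mm`, and per-version E2E entries of the form
#' `e2e_<VERSION>_<mean|sd>_<si|lr|ap>` (e.g. `e2e_VSI_8_5_sd_si = 0.53`).
#' Unspecified keys keep the defaults of [static_uncertainty_table()].
#'
#' @param path Config file path.
#' @return A [static_uncertainty_table()].
#' @export
read_static_table <- function(path) {
  if (!file.exists(path)) ptv_error("ptv_io_error", "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tab <- static_uncertainty_table()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      ptv_error("ptv_config_error", "%s: malformed line '%s'", path, ln)
    }
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) {
      ptv_error("ptv_config_error", "%s: non-numeric value for %s", path, key)
    }
    if (key %in% c("segmentation_sd_mm", "deformation_threshold_cm",
                   "deformation_low_mm", "deformation_high_mm")) {
      tab[[key]] <- val
    } else if (grepl("^e2e_", key)) {
      m <- regmatches(key, regexec("^e2e_(.+)_(mean|sd)_(si|lr|ap)$", key))[[1]]
      if (length(m) != 4L || !m[2] %in% .ck_versions) {
        ptv_error("ptv_config_error", "%s: unrecognized key '%s'", path, key)
      }
      slot <- paste0(m[3], "_mm")
      dir <- toupper(m[4])
      tab$e2e[[m[2]]][[slot]][[dir]] <- val
    } else {
      ptv_error("ptv_config_error", "%s: unrecognized key '%s'", path, key)
    }
  }
  do.call(static_uncertainty_table, unclass(tab))
}

#' Total tracking error
#'
#' Combines model, prediction and end-to-end targeting errors in quadrature,
#' separately for the means and for the SDs, per direction.
#'
#' @param summary A [summarize_fraction()] result.
#' @param e2e List with per-direction `mean_mm` and `sd_mm` vectors (as in the
#'   entries of [static_uncertainty_table()]).
#' @return List with per-direction vectors `mean_mm` and `sd_mm`.
#' @export
total_tracking_error <- function(summary, e2e) {
  stopifnot(inherits(summary, "fraction_summary"))
  e2e_mean <- as_direction_vector(e2e$mean_mm, "e2e mean")
  e2e_sd <- as_direction_vector(e2e$sd_mm, "e2e sd")
  take <- function(src, col) {
    x <- summary[summary$source == src, ]
    stats::setNames(x[[col]], x$direction)[directions()]
  }
  list(
    mean_mm = sqrt(take("model", "mean_mm")^2 + take("prediction", "mean_mm")^2 +
                     e2e_mean^2),
    sd_mm = sqrt(take("model", "sd_mm")^2 + take("prediction", "sd_mm")^2 +
                   e2e_sd^2)
  )
}
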