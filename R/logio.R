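# Tracking-log data model and CSV interchange.
#
# One file per treatment fraction. Line 1 is a '#'-prefixed metadata header,
# line 2 the column header, then one row per timestamped error sample:
#
#   # patient_id=P01 fraction=1 site=upper_left_lung tracking=XLT version=VSI_8_5 motion_cm=1.2
#   time_s,source,err_si_mm,err_lr_mm,err_ap_mm
#   0,model,0.12,-0.03,0.05
#
# Errors are millimetres along (SI, LR, AP); time is seconds from fraction
# start; source is "model" (correlation-model residual, available roughly once
# a minute at each x-ray acquisition) or "prediction" (latency-compensation
# residual, available on the beam-delivery cadence of tens of milliseconds).

#' Construct a per-fraction tracking log
#'
#' A fraction log couples the metadata of one treatment fraction (patient,
#' fraction number, tumor site, tracking mode, delivery-system version,
#' center-of-mass motion amplitude) with its timestamped tracking-error
#' samples. Two error streams coexist in one log: correlation-model residuals
#' (`source = "model"`) and prediction residuals (`source = "prediction"`),
#' each a 3-vector in mm along (SI, LR, AP).
#'
#' @param patient_id Opaque patient identifier string.
#' @param fraction_index Positive integer fraction number (1 = first).
#' @param site Tumor site, one of [tumor_sites()].
#' @param tracking_mode `"FTT"` (fiducial-based) or `"XLT"` (fiducial-free
#'   lung tracking).
#' @param ck_version Delivery-system version: `"G3_6_2_3"`, `"VSI_8_5"` or
#'   `"VSI_9_5"`.
#' @param motion_amplitude_cm Peak-to-peak center-of-mass tumor motion in cm
#'   (drives the deformation-uncertainty rule, see [assign_static()]).
#' @param samples `data.frame` with columns `time_s`, `source`, `err_si_mm`,
#'   `err_lr_mm`, `err_ap_mm`. Rows are sorted by time on construction.
#'
#' @return An object of class `fraction_log`.
#' @seealso [read_fraction_log()], [write_fraction_log()], [cohort_log()]
#' @export
#' @examples
#' s <- data.frame(time_s = c(0, 60), source = "model",
#'                 err_si_mm = c(0.1, -0.2), err_lr_mm = 0, err_ap_mm = 0)
#' fraction_log("P01", 1, "upper_left_lung", "XLT", "VSI_8_5", 1.2, s)
fraction_log <- function(patient_id, fraction_index, site, tracking_mode,
                         ck_version, motion_amplitude_cm, samples) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  fraction_index <- as.integer(fraction_index)
  if (is.na(fraction_index) || fraction_index < 1L) {
    ptv_error("ptv_schema_error", "fraction_index must be a positive integer")
  }
  site <- match.arg(site, .sites)
  tracking_mode <- match.arg(tracking_mode, .tracking_modes)
  ck_version <- match.arg(ck_version, .ck_versions)
  motion_amplitude_cm <- as.numeric(motion_amplitude_cm)
  if (!is.finite(motion_amplitude_cm) || motion_amplitude_cm < 0) {
    ptv_error("ptv_schema_error", "motion_amplitude_cm must be finite and >= 0")
  }
  samples <- validate_samples(samples)
  structure(
    list(
      patient_id = patient_id,
      fraction_index = fraction_index,
      site = site,
      tracking_mode = tracking_mode,
      ck_version = ck_version,
      motion_amplitude_cm = motion_amplitude_cm,
      samples = samples
    ),
    class = "fraction_log"
  )
}

validate_samples <- function(samples) {
  cols <- c("time_s", "source", "err_si_mm", "err_lr_mm", "err_ap_mm")
  if (!is.data.frame(samples) || !all(cols %in% names(samples))) {
    ptv_error("ptv_schema_error",
              "samples must be a data.frame with columns %s",
              paste(cols, collapse = ", "))
  }
  samples <- samples[, cols, drop = FALSE]
  samples$source <- as.character(samples$source)
  bad_src <- which(!samples$source %in% .sources)
  if (length(bad_src)) {
    ptv_error("ptv_schema_error",
              "row %d: unknown source '%s' (must be model or prediction)",
              bad_src[1L], samples$source[bad_src[1L]])
  }
  num_cols <- setdiff(cols, "source")
  for (cc in num_cols) {
    v <- samples[[cc]]
    if (!is.numeric(v)) {
      ptv_error("ptv_schema_error", "column %s must be numeric", cc)
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      ptv_error("ptv_schema_error", "row %d: non-finite value in %s", bad[1L], cc)
    }
  }
  if (any(samples$time_s < 0)) {
    ptv_error("ptv_schema_error", "row %d: negative time_s",
              which(samples$time_s < 0)[1L])
  }
  ord <- order(samples$time_s)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  samples
}

#' @export
print.fraction_log <- function(x, ...) {
  n_mod <- sum(x$samples$source == "model")
  n_pred <- sum(x$samples$source == "prediction")
  cat(sprintf(
    "<fraction_log> patient %s fraction %d | %s, %s, %s | motion %.2f cm\n",
    x$patient_id, x$fraction_index, x$site, x$tracking_mode, x$ck_version,
    x$motion_amplitude_cm
  ))
  cat(sprintf("  %d model + %d prediction samples over %.1f s\n",
              n_mod, n_pred,
              if (nrow(x$samples)) max(x$samples$time_s) else 0))
  invisible(x)
}

#' Bundle fraction logs into a cohort
#'
#' @param fractions List of [fraction_log] objects.
#' @return An object of class `cohort_log` (a list with element `fractions`).
#' @seealso [validate_cohort()]
#' @export
cohort_log <- function(fractions) {
  if (inherits(fractions, "fraction_log")) fractions <- list(fractions)
  stopifnot(is.list(fractions))
  ok <- vapply(fractions, inherits, logical(1), "fraction_log")
  if (!all(ok)) {
    ptv_error("ptv_schema_error", "all elements must be fraction_log objects")
  }
  structure(list(fractions = fractions), class = "cohort_log")
}

#' @export
print.cohort_log <- function(x, ...) {
  pats <- unique(vapply(x$fractions, `[[`, character(1), "patient_id"))
  cat(sprintf("<cohort_log> %d fractions from %d patients\n",
              length(x$fractions), length(pats)))
  invisible(x)
}

# %.17g guarantees lossless double round-trip through text.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a fraction log to the per-fraction CSV schema
#'
#' Values are serialized with 17 significant digits so that
#' `read_fraction_log(write_fraction_log(log))` reproduces the log exactly.
#'
#' @param log A [fraction_log].
#' @param path Output file path (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_fraction_log <- function(log, path) {
  stopifnot(inherits(log, "fraction_log"))
  meta <- sprintf(
    "# patient_id=%s fraction=%d site=%s tracking=%s version=%s motion_cm=%s",
    log$patient_id, log$fraction_index, log$site, log$tracking_mode,
    log$ck_version, fmt_num(log$motion_amplitude_cm)
  )
  header <- "time_s,source,err_si_mm,err_lr_mm,err_ap_mm"
  s <- log$samples
  rows <- if (nrow(s)) {
    paste(fmt_num(s$time_s), s$source, fmt_num(s$err_si_mm),
          fmt_num(s$err_lr_mm), fmt_num(s$err_ap_mm), sep = ",")
  } else {
    character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

parse_meta_line <- function(line, path) {
  if (!startsWith(line, "# ")) {
    ptv_error("ptv_schema_error", "%s: line 1 must be a '# key=value ...' header", path)
  }
  fields <- strsplit(sub("^# ", "", line), " ", fixed = TRUE)[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    ptv_error("ptv_schema_error", "%s: malformed header field '%s'", path,
              fields[bad][1L])
  }
  vals <- vapply(kv, `[[`, character(1), 2L)
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  need <- c("patient_id", "fraction", "site", "tracking", "version", "motion_cm")
  miss <- setdiff(need, names(vals))
  if (length(miss)) {
    ptv_error("ptv_schema_error", "%s: header missing key(s) %s", path,
              paste(miss, collapse = ", "))
  }
  vals
}

#' Read a fraction log from the per-fraction CSV schema
#'
#' Rows may appear in any time order in the file; samples are sorted by time
#' on read. Malformed headers, non-numeric fields and unknown enum values
#' raise a schema error naming the offending row.
#'
#' @param path Path to a CSV file following the schema written by
#'   [write_fraction_log()].
#' @return A validated [fraction_log].
#' @export
read_fraction_log <- function(path) {
  if (!file.exists(path)) {
    ptv_error("ptv_io_error", "file not found: %s", path)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    ptv_error("ptv_schema_error", "%s: expected metadata + column header lines", path)
  }
  meta <- parse_meta_line(lines[1L], path)
  expected_hdr <- "time_s,source,err_si_mm,err_lr_mm,err_ap_mm"
  if (trimws(lines[2L]) != expected_hdr) {
    ptv_error("ptv_schema_error", "%s: line 2 must be '%s'", path, expected_hdr)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    nf <- vapply(parts, length, integer(1))
    if (any(nf != 5L)) {
      ptv_error("ptv_schema_error", "%s: row %d has %d fields (expected 5)",
                path, which(nf != 5L)[1L], nf[nf != 5L][1L])
    }
    m <- do.call(rbind, parts)
    to_num <- function(col, name) {
      v <- suppressWarnings(as.numeric(m[, col]))
      bad <- which(is.na(v))
      if (length(bad)) {
        ptv_error("ptv_schema_error", "%s: row %d: non-numeric %s '%s'",
                  path, bad[1L], name, m[bad[1L], col])
      }
      v
    }
    src <- m[, 2L]
    bad_src <- which(!src %in% .sources)
    if (length(bad_src)) {
      ptv_error("ptv_schema_error", "%s: row %d: unknown source '%s'",
                path, bad_src[1L], src[bad_src[1L]])
    }
    samples <- data.frame(
      time_s = to_num(1L, "time_s"),
      source = src,
      err_si_mm = to_num(3L, "err_si_mm"),
      err_lr_mm = to_num(4L, "err_lr_mm"),
      err_ap_mm = to_num(5L, "err_ap_mm"),
      stringsAsFactors = FALSE
    )
  } else {
    samples <- data.frame(
      time_s = numeric(0), source = character(0), err_si_mm = numeric(0),
      err_lr_mm = numeric(0), err_ap_mm = numeric(0), stringsAsFactors = FALSE
    )
  }
  fr <- suppressWarnings(as.integer(meta[["fraction"]]))
  if (is.na(fr)) {
    ptv_error("ptv_schema_error", "%s: non-integer fraction '%s'",
              path, meta[["fraction"]])
  }
  motion <- suppressWarnings(as.numeric(meta[["motion_cm"]]))
  if (is.na(motion)) {
    ptv_error("ptv_schema_error", "%s: non-numeric motion_cm '%s'",
              path, meta[["motion_cm"]])
  }
  for (chk in list(c("site", meta[["site"]]), c("tracking", meta[["tracking"]]),
                   c("version", meta[["version"]]))) {
    pool <- switch(chk[1], site = .sites, tracking = .tracking_modes,
                   version = .ck_versions)
    if (!chk[2] %in% pool) {
      ptv_error("ptv_schema_error", "%s: unknown %s '%s'", path, chk[1], chk[2])
    }
  }
  fraction_log(
    patient_id = meta[["patient_id"]],
    fraction_index = fr,
    site = meta[["site"]],
    tracking_mode = meta[["tracking"]],
    ck_version = meta[["version"]],
    motion_amplitude_cm = motion,
    samples = samples
  )
}

#' Read every fraction log in a directory into a cohort
#'
#' @param dir Directory containing `*.csv` fraction logs.
#' @return A [cohort_log].
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) ptv_error("ptv_io_error", "directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) ptv_error("ptv_io_error", "no .csv fraction logs in %s", dir)
  cohort_log(lapply(files, read_fraction_log))
}

#' Write a cohort as one CSV per fraction
#'
#' @param cohort A [cohort_log].
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$fractions, function(fl) {
    p <- file.path(dir, sprintf("%s_fx%03d.csv", fl$patient_id, fl$fraction_index))
    write_fraction_log(fl, p)
    p
  }, character(1))
  invisible(paths)
}

#' Validate a cohort of fraction logs
#'
#' Checks cohort-level invariants and per-fraction data sufficiency without
#' raising: unique (patient, fraction) pairs, time-sorted samples, and the
#' presence of both error streams needed for covariance estimation.
#'
#' @param cohort A [cohort_log].
#' @return Character vector of diagnostics; empty when all invariants hold.
#'   The input is never modified.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_log"))
  diags <- character(0)
  keys <- vapply(cohort$fractions, function(fl) {
    sprintf("%s/%d", fl$patient_id, fl$fraction_index)
  }, character(1))
  dup <- unique(keys[duplicated(keys)])
  for (d in dup) {
    diags <- c(diags, sprintf("duplicate (patient, fraction) pair: %s", d))
  }
  for (fl in cohort$fractions) {
    tag <- sprintf("%s fraction %d", fl$patient_id, fl$fraction_index)
    if (is.unsorted(fl$samples$time_s)) {
      diags <- c(diags, sprintf("%s: samples not sorted by time", tag))
    }
    n_mod <- sum(fl$samples$source == "model")
    n_pred <- sum(fl$samples$source == "prediction")
    if (n_mod == 0L) {
      diags <- c(diags, sprintf("%s: insufficient model samples (0)", tag))
    }
    if (n_pred == 0L) {
      diags <- c(diags, sprintf("%s: insufficient prediction samples (0)", tag))
    }
    if (fl$motion_amplitude_cm < 0) {
      diags <- c(diags, sprintf("%s: negative motion amplitude", tag))
    }
  }
  diags
}

# Split a cohort into per-patient lists of fraction logs, preserving order.
split_by_patient <- function(cohort) {
  ids <- vapply(cohort$fractions, `[[`, character(1), "patient_id")
  split(cohort$fractions, factor(ids, levels = unique(ids)))
}

# Extract the (model|prediction) error matrix (n x 3) and times of one stream.
stream <- function(log, source) {
  s <- log$samples[log$samples$source == source, , drop = FALSE]
  list(
    time = s$time_s,
    err = matrix(c(s$err_si_mm, s$err_lr_mm, s$err_ap_mm), ncol = 3L,
                 dimnames = list(NULL, directions()))
  )
}
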