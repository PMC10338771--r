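# Cohort-level statistical comparison of margin methods.

# Lean one-way fixed-effects ANOVA core on a list of numeric vectors.
# Returns F, df1, df2, p. Used both by compare_methods and by calibration
# loops, so it avoids model-matrix machinery.
f_oneway <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  n <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / n
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- n - k
  if (ss_within <= 0) {
    if (ss_between <= 0) {
      ptv_error("ptv_zero_variance",
                "all observations identical across groups: F undefined")
    }
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Compare margin methods with a one-way F test
#'
#' One-way fixed-effects ANOVA across per-patient margins grouped by method
#' (the conventional reading of an F-test comparison of three margin
#' formalisms). Degenerate input in which every observation is identical
#' across all groups raises a zero-variance error; groups with zero
#' between-group spread but positive within-group spread return `F = 0`,
#' `p = 1`.
#'
#' @param per_patient_margins Named list mapping method name to a numeric
#'   vector of per-patient margins (mm); >= 2 methods with >= 2 values each.
#' @param alpha Significance level (default 0.05).
#' @param site,direction Optional labels carried into the result.
#' @return Object of class `method_comparison`: one-row data.frame with
#'   columns `site`, `direction`, `methods`, `F_statistic`, `df1`, `df2`,
#'   `p_value`, `significant`, `n_per_group`.
#' @export
compare_methods <- function(per_patient_margins, alpha = 0.05,
                            site = NA_character_, direction = NA_character_) {
  if (!is.list(per_patient_margins) || length(per_patient_margins) < 2L) {
    ptv_error("ptv_insufficient_data", "need >= 2 methods to compare")
  }
  if (is.null(names(per_patient_margins)) ||
      any(!nzchar(names(per_patient_margins)))) {
    ptv_error("ptv_config_error", "methods must be named")
  }
  ok <- vapply(per_patient_margins, function(g) {
    is.numeric(g) && length(g) >= 2L && all(is.finite(g))
  }, logical(1))
  if (!all(ok)) {
    ptv_error("ptv_insufficient_data",
              "each method needs >= 2 finite margins (violated by: %s)",
              paste(names(per_patient_margins)[!ok], collapse = ", "))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    ptv_error("ptv_domain_error", "alpha must lie in (0, 1)")
  }
  res <- f_oneway(per_patient_margins)
  out <- data.frame(
    site = site, direction = direction,
    methods = paste(names(per_patient_margins), collapse = "+"),
    F_statistic = res$F, df1 = res$df1, df2 = res$df2,
    p_value = res$p, significant = res$p <= alpha,
    n_per_group = paste(lengths(per_patient_margins), collapse = ","),
    stringsAsFactors = FALSE
  )
  class(out) <- c("method_comparison", "data.frame")
  out
}

#' Two-sample variance-ratio F test
#'
#' Pairwise companion to [compare_methods()]: tests equality of variances of
#' two methods' per-patient margins via the ratio of sample variances (larger
#' over smaller, two-sided p).
#'
#' @param x,y Numeric vectors with >= 2 finite values and positive variance.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
variance_ratio_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    ptv_error("ptv_insufficient_data", "need >= 2 values per sample")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx <= 0 || vy <= 0) {
    ptv_error("ptv_zero_variance", "zero variance sample: F undefined")
  }
  if (vx >= vy) {
    f <- vx / vy; df1 <- length(x) - 1L; df2 <- length(y) - 1L
  } else {
    f <- vy / vx; df1 <- length(y) - 1L; df2 <- length(x) - 1L
  }
  p <- 2 * stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p_value = min(p, 1))
}
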