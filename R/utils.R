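# Internal constants and shared validators.

#' Anatomical direction labels
#'
#' Margins, errors and correlations are always reported per direction in the
#' fixed order superior-inferior, left-right, anterior-posterior.
#'
#' @return Character vector `c("SI", "LR", "AP")`.
#' @export
directions <- function() c("SI", "LR", "AP")

# Tumor sites handled by the cohort machinery (lung, abdomen, chest wall).
.sites <- c(
  "lung_apex_left", "lower_left_lung", "upper_left_lung", "lower_right_lung",
  "central_right_lung", "upper_right_lung", "central_left_lung",
  "liver", "central_liver", "lower_liver", "upper_liver",
  "pancreas", "chest_wall"
)

.tracking_modes <- c("FTT", "XLT")
.ck_versions <- c("G3_6_2_3", "VSI_8_5", "VSI_9_5")
.sources <- c("model", "prediction")

#' Known tumor site labels
#' @return Character vector of site identifiers.
#' @export
tumor_sites <- function() .sites

# Coerce x to a named per-direction numeric vector (scalar recycled).
as_direction_vector <- function(x, what = "value") {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what), call. = FALSE)
  if (length(x) == 1L) x <- rep(as.numeric(x), 3L)
  if (length(x) != 3L) {
    stop(sprintf("%s must have length 1 or 3 (SI, LR, AP)", what), call. = FALSE)
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), directions())) {
      stop(sprintf("%s names must be SI, LR, AP", what), call. = FALSE)
    }
    x <- x[directions()]
  }
  x <- as.numeric(x)
  names(x) <- directions()
  x
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be finite and >= 0", what), call. = FALSE)
  }
  invisible(x)
}

# Condition helpers: errors carry classes so callers/tests can discriminate.
ptv_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ptv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}
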