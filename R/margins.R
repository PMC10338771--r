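# CTV-to-PTV margin recipes.
#
# All recipes follow the van Herk coverage criterion (>= 95% CTV dose for 90%
# of patients): margin = 2.5 * Sigma + (random-error term). For SBRT with its
# broad effective penumbra the random term is beta*sqrt(sigma^2 + sigma_p^2)
# - beta*sigma_p with penumbra width sigma_p = 6.4 mm and dose-level
# coefficient beta = 0.84 (80% prescription isodose). The five-component
# extension combines segmentation, deformation, model, prediction and
# targeting systematic SDs in quadrature; the covariance-augmented variant
# additionally propagates the model-prediction covariance into the combined
# random SD: sigma_new^2 = sigma_mod^2 + sigma_pred^2 + 2*cov.

COV_TOL <- 1e-12 # absolute slack on the Cauchy-Schwarz admissibility bound

#' Basic van Herk margin
#'
#' `2.5 * Sigma + 0.7 * sigma`: the classical linearized recipe for
#' conventionally fractionated photon fields.
#'
#' @param Sigma Systematic SD, mm (scalar or per-direction vector).
#' @param sigma Random SD, mm.
#' @return Margin in mm, same shape as the inputs.
#' @export
vhf_basic <- function(Sigma, sigma) {
  check_nonneg(Sigma, "Sigma")
  check_nonneg(sigma, "sigma")
  2.5 * Sigma + 0.7 * sigma
}

#' SBRT van Herk margin with explicit penumbra term
#'
#' `2.5 * Sigma + beta * sqrt(sigma^2 + sigma_rho^2) - beta * sigma_rho`.
#' Reduces to `2.5 * Sigma` exactly when `sigma = 0`.
#'
#' @param Sigma Systematic SD, mm.
#' @param sigma Random SD, mm.
#' @param sigma_rho Effective penumbra width, mm (default 6.4 for lung/abdomen
#'   SBRT).
#' @param beta Dose-level coefficient (default 0.84, 80% isodose
#'   prescription).
#' @return Margin in mm.
#' @export
vhf_recipe <- function(Sigma, sigma, sigma_rho = 6.4, beta = 0.84) {
  check_nonneg(Sigma, "Sigma")
  check_nonneg(sigma, "sigma")
  if (any(sigma_rho <= 0)) ptv_error("ptv_domain_error", "sigma_rho must be > 0")
  if (any(beta <= 0 | beta > 2.5)) {
    ptv_error("ptv_domain_error", "beta must be in (0, 2.5]")
  }
  2.5 * Sigma + beta * sqrt(sigma^2 + sigma_rho^2) - beta * sigma_rho
}

#' Combined random SD of model and prediction errors
#'
#' Without a covariance the two random errors combine independently in
#' quadrature; with one, error propagation gives
#' `sigma_new^2 = sigma_mod^2 + sigma_pred^2 + 2*cov`, which is non-negative
#' whenever `|cov| <= sigma_mod * sigma_pred` (Cauchy-Schwarz).
#'
#' @param sigma_mod,sigma_pred Random SDs, mm.
#' @param cov Covariance in mm^2, or `NULL` for the independence assumption.
#' @return Combined SD in mm.
#' @export
combined_sd <- function(sigma_mod, sigma_pred, cov = NULL) {
  check_nonneg(sigma_mod, "sigma_mod")
  check_nonneg(sigma_pred, "sigma_pred")
  if (is.null(cov)) return(sqrt(sigma_mod^2 + sigma_pred^2))
  if (any(abs(cov) > sigma_mod * sigma_pred + COV_TOL)) {
    ptv_error("ptv_domain_error",
              "inadmissible covariance: |cov| exceeds sigma_mod * sigma_pred (Cauchy-Schwarz bound)")
  }
  v <- sigma_mod^2 + sigma_pred^2 + 2 * cov
  sqrt(pmax(v, 0))
}

#' Error-component set for the extended margin recipes
#'
#' Bundles the five systematic SDs (segmentation, deformation, model,
#' prediction, targeting), the two log-derived random SDs, and the penumbra
#' parameters. Scalars are recycled across the three directions.
#'
#' @param Sigma_seg,Sigma_def,Sigma_mod,Sigma_pred,Sigma_tar Systematic SDs,
#'   mm.
#' @param sigma_mod,sigma_pred Random SDs, mm.
#' @param sigma_rho Penumbra width, mm (> 0, default 6.4).
#' @param beta Dose-level coefficient in (0, 2.5] (default 0.84).
#' @return Object of class `error_components`.
#' @export
error_components <- function(Sigma_seg = 0, Sigma_def = 0, Sigma_mod = 0,
                             Sigma_pred = 0, Sigma_tar = 0,
                             sigma_mod = 0, sigma_pred = 0,
                             sigma_rho = 6.4, beta = 0.84) {
  nm <- c("Sigma_seg", "Sigma_def", "Sigma_mod", "Sigma_pred", "Sigma_tar",
          "sigma_mod", "sigma_pred")
  vals <- mget(nm)
  missing_syms <- nm[vapply(vals, function(v) is.null(v) || any(is.na(v)), logical(1))]
  if (length(missing_syms)) {
    ptv_error("ptv_config_error", "incomplete error components: %s",
              paste(missing_syms, collapse = ", "))
  }
  vals <- lapply(nm, function(k) check_nonneg(as_direction_vector(vals[[k]], k), k))
  names(vals) <- nm
  if (any(sigma_rho <= 0)) ptv_error("ptv_domain_error", "sigma_rho must be > 0")
  if (any(beta <= 0 | beta > 2.5)) {
    ptv_error("ptv_domain_error", "beta must be in (0, 2.5]")
  }
  structure(c(vals, list(sigma_rho = sigma_rho, beta = beta)),
            class = "error_components")
}

#' @export
print.error_components <- function(x, ...) {
  cat("<error_components> (mm; columns SI, LR, AP)\n")
  m <- rbind(Sigma_seg = x$Sigma_seg, Sigma_def = x$Sigma_def,
             Sigma_mod = x$Sigma_mod, Sigma_pred = x$Sigma_pred,
             Sigma_tar = x$Sigma_tar, sigma_mod = x$sigma_mod,
             sigma_pred = x$sigma_pred)
  print(round(m, 4))
  cat(sprintf("  sigma_rho = %.2f mm, beta = %.2f\n", x$sigma_rho, x$beta))
  invisible(x)
}

new_margin_result <- function(margin, formalism, components, cov = NULL) {
  structure(
    data.frame(direction = directions(), margin_mm = as.numeric(margin),
               formalism = formalism, stringsAsFactors = FALSE),
    inputs = list(components = components, cov_mm2 = cov),
    class = c("margin_result", "data.frame")
  )
}

quad_Sigma <- function(c) {
  sqrt(c$Sigma_seg^2 + c$Sigma_def^2 + c$Sigma_mod^2 + c$Sigma_pred^2 +
         c$Sigma_tar^2)
}

#' Five-component extended van Herk margin
#'
#' Combines the five systematic SDs in quadrature and the model/prediction
#' random SDs independently in quadrature, then applies the SBRT penumbra
#' recipe per direction.
#'
#' @param components An [error_components()] object.
#' @return A `margin_result` data.frame (direction, margin_mm, formalism) with
#'   the inputs recorded in the `inputs` attribute.
#' @export
vhf_extended <- function(components) {
  stopifnot(inherits(components, "error_components"))
  Sigma <- quad_Sigma(components)
  sig <- combined_sd(components$sigma_mod, components$sigma_pred)
  m <- vhf_recipe(Sigma, sig, components$sigma_rho, components$beta)
  new_margin_result(m, "VHF_EXT", components)
}

#' Covariance-modified van Herk margin
#'
#' Identical to [vhf_extended()] except that the combined random SD carries
#' the model-prediction covariance:
#' `sigma_new^2 = sigma_mod^2 + sigma_pred^2 + 2*cov`. With `cov = 0` the two
#' recipes agree exactly; the margin is non-decreasing in `cov` over the
#' admissible range `|cov| <= sigma_mod * sigma_pred`.
#'
#' @param components An [error_components()] object.
#' @param cov Model-prediction covariance per direction, mm^2 (scalar
#'   recycled).
#' @return A `margin_result` data.frame.
#' @export
mvhf <- function(components, cov) {
  stopifnot(inherits(components, "error_components"))
  cov <- as_direction_vector(cov, "cov")
  Sigma <- quad_Sigma(components)
  sig <- combined_sd(components$sigma_mod, components$sigma_pred, cov)
  m <- vhf_recipe(Sigma, sig, components$sigma_rho, components$beta)
  new_margin_result(m, "MVHF", components, cov)
}

#' Relative margin difference
#'
#' `100 * (m_mvhf - m_vhf) / m_vhf`, the percent change introduced by the
#' covariance term relative to the covariance-free margin.
#'
#' @param m_mvhf,m_vhf Margins in mm (`m_vhf > 0`); `margin_result` objects
#'   are accepted and compared per direction.
#' @return Relative difference in percent.
#' @export
relative_difference <- function(m_mvhf, m_vhf) {
  if (inherits(m_mvhf, "margin_result")) m_mvhf <- m_mvhf$margin_mm
  if (inherits(m_vhf, "margin_result")) m_vhf <- m_vhf$margin_mm
  if (any(m_vhf <= 0)) {
    ptv_error("ptv_domain_error",
              "relative difference undefined for reference margin <= 0")
  }
  100 * (m_mvhf - m_vhf) / m_vhf
}
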