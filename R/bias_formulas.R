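#' Attenuation of a polygenic score effect by measurement error
#'
#' In the standardized measurement-error model the fitted simple regression
#' coefficient of the observed outcome on the polygenic score is the true
#' effect attenuated by both loadings:
#' \deqn{b_{GY} = l_Y\, l_G\, \beta_{G^*Y^*}}
#' and the bias (fitted minus true) is \eqn{\beta_{G^*Y^*}(l_Y l_G - 1)}.
#' With perfect measurement (\eqn{l_Y = l_G = 1}) the bias is zero; when
#' either indicator is pure noise the fitted coefficient is zero and the bias
#' is \eqn{-\beta_{G^*Y^*}}.
#'
#' @param beta_gy_star true standardized effect of the genetic factor on the
#'   outcome.
#' @param l_g,l_y loadings of the polygenic score and of the measured outcome
#'   (reliability = loading squared; pass `sqrt(0.10)` for a score of
#'   reliability 0.10).
#' @return list with `fitted` (b_GY), `bias`, and `variance_explained`
#'   (fitted squared: the R-squared of the simple regression).
#' @examples
#' attenuated_pgs_effect(0.9, l_g = sqrt(0.10), l_y = sqrt(0.80))
#' @export
attenuated_pgs_effect <- function(beta_gy_star, l_g, l_y = 1) {
  check_loading(l_g, "l_g"); check_loading(l_y, "l_y")
  stopifnot(abs(beta_gy_star) <= 1)
  fitted <- l_y * l_g * beta_gy_star
  list(fitted = fitted,
       bias = fitted - beta_gy_star,
       variance_explained = fitted^2)
}

check_loading <- function(l, what) {
  if (!is.finite(l) || l < 0 || l > 1) stop(what, " must be a loading in [0, 1]")
  invisible(l)
}

#' Reliability of a polygenic score from external heritability
#'
#' The reliability of a polygenic score as an indicator of the full additive
#' (SNP-tagged) genetic factor is approximated by the ratio of the variance
#' it explains in the phenotype to the SNP-heritability:
#' \deqn{l_G^2 = r_{GY}^2 / h^2_{SNP}}
#'
#' @param r2_pgs variance in the phenotype explained by the score, in `[0, 1]`.
#' @param h2 SNP-heritability (or twin heritability) of the phenotype, in
#'   `(0, 1]`.
#' @return list with `l_g_squared` (the reliability), `l_g` (its square
#'   root), the inputs, and `consistent` — `FALSE` when the ratio exceeds 1,
#'   i.e. the score explains more than the heritability and the inputs
#'   contradict each other.
#' @examples
#' pgs_reliability(0.114, 0.147)$l_g_squared  # educational attainment: 0.776
#' @export
pgs_reliability <- function(r2_pgs, h2) {
  if (!is.finite(h2) || h2 <= 0) stop("h2 must be positive")
  if (!is.finite(r2_pgs) || r2_pgs < 0) stop("r2_pgs must be non-negative")
  ratio <- r2_pgs / h2
  list(r2_pgs = r2_pgs, h2 = h2,
       l_g_squared = ratio, l_g = sqrt(ratio),
       consistent = ratio <= 1)
}

#' Residual genetic confounding after adjusting for an unreliable score
#'
#' In the exposure model, regressing the (perfectly measured) outcome on the
#' exposure and the observed polygenic score leaves part of the genetic
#' confounding unadjusted because the score is a noisy measure of the genetic
#' factor:
#' \deqn{b_{X^*Y^*} = \beta_{X^*Y^*} +
#'   \frac{\beta_{G^*X^*}\beta_{G^*Y^*}(1 - l_G^2)}{1 - l_G^2\beta_{G^*X^*}^2}}
#' The second term is the bias; it vanishes as the score becomes perfectly
#' reliable and approaches the full confounding effect
#' \eqn{\beta_{G^*X^*}\beta_{G^*Y^*}} as reliability goes to zero.
#'
#' @param beta_xy_star true standardized exposure effect.
#' @param beta_gx_star,beta_gy_star standardized genetic effects on exposure
#'   and outcome (coefficients, i.e. square roots of variance fractions).
#' @param l_g polygenic score loading (`sqrt` of its reliability).
#' @return list with `fitted` (the adjusted exposure coefficient) and `bias`.
#' @examples
#' # null exposure effect, genes explain 15% of X* and 30% of Y*, score
#' # reliability 0.10: the adjusted coefficient still prints as 0.19
#' adjusted_exposure_effect(0, sqrt(0.15), sqrt(0.30), sqrt(0.10))
#' @export
adjusted_exposure_effect <- function(beta_xy_star, beta_gx_star,
                                     beta_gy_star, l_g) {
  check_loading(l_g, "l_g")
  denom <- 1 - l_g^2 * beta_gx_star^2
  if (denom <= 0) stop("degenerate model: 1 - l_g^2 * beta_gx_star^2 <= 0")
  bias <- beta_gx_star * beta_gy_star * (1 - l_g^2) / denom
  list(fitted = beta_xy_star + bias, bias = bias)
}

#' Fitted mediated effect and proportion mediated with an unreliable score
#'
#' The true mediated (indirect) effect along the genetic path through the
#' exposure is \eqn{\beta_M = \beta_{G^*X^*}\beta_{X^*Y^*}}. Using an
#' unreliable polygenic score, the fitted mediated effect is
#' \deqn{b_M = l_G\beta_M + l_G\beta_{G^*X^*}\,\mathrm{Bias}_{X^*Y^*}}
#' where the bias term is the residual genetic confounding of
#' [adjusted_exposure_effect()]. The fitted proportion mediated is inflated:
#' \deqn{p_M = \pi_M + \mathrm{Bias}_{X^*Y^*}\, r_{G^*X^*} / r_{G^*Y^*}}
#' so a nonzero fitted mediation can arise when the true mediation is null.
#'
#' @inheritParams adjusted_exposure_effect
#' @return list with true values `beta_m`, `pi_m`, fitted values `b_m`,
#'   `p_m`, the `bias` term, and `proportions_defined` (`FALSE` when the
#'   total genetic association \eqn{r_{G^*Y^*}} is numerically zero, in which
#'   case both proportions are `NA`).
#' @export
fitted_mediated_effect <- function(beta_xy_star, beta_gx_star,
                                   beta_gy_star, l_g) {
  adj <- adjusted_exposure_effect(beta_xy_star, beta_gx_star, beta_gy_star, l_g)
  beta_m <- beta_gx_star * beta_xy_star
  b_m <- l_g * beta_m + l_g * beta_gx_star * adj$bias
  r_gy <- beta_gy_star + beta_gx_star * beta_xy_star
  defined <- abs(r_gy) >= 1e-12
  pi_m <- if (defined) beta_m / r_gy else NA_real_
  p_m <- if (defined) pi_m + adj$bias * beta_gx_star / r_gy else NA_real_
  list(beta_m = beta_m, b_m = b_m, pi_m = pi_m, p_m = p_m,
       bias = adj$bias, proportions_defined = defined)
}

#' Bias amplification from adjusting for a collider
#'
#' In the collider model with perfectly measured variables, the genetic
#' factor affects only the exposure, so the exposure is a collider for the
#' genetic factor and the unmeasured confounder. Regressing the outcome on
#' both opens the path through the confounder:
#' \deqn{b_{G^*Y^*} = \beta_{G^*Y^*} -
#'   \frac{\beta_{G^*X^*}\beta_{U^*X^*}\beta_{U^*Y^*}}{1 - \beta_{G^*X^*}^2}}
#' \deqn{b_{X^*Y^*} = \beta_{X^*Y^*} +
#'   \frac{\beta_{U^*X^*}\beta_{U^*Y^*}}{1 - \beta_{G^*X^*}^2}}
#' The denominator shrinks as the genetic factor explains more exposure
#' variance, so the adjustment amplifies rather than removes the confounding
#' bias. With all paths positive the adjusted genetic effect is
#' underestimated.
#'
#' @inheritParams adjusted_exposure_effect
#' @param beta_ux_star,beta_uy_star standardized effects of the unmeasured
#'   confounder on exposure and outcome.
#' @return list with `b_g_star`, `b_x_star`, and the two bias terms
#'   `bias_g`, `bias_x`.
#' @export
collider_adjusted_effects <- function(beta_xy_star, beta_gx_star,
                                      beta_gy_star, beta_ux_star,
                                      beta_uy_star) {
  denom <- 1 - beta_gx_star^2
  if (denom <= 0) stop("beta_gx_star^2 must be < 1")
  bias_x <- beta_ux_star * beta_uy_star / denom
  bias_g <- -beta_gx_star * beta_ux_star * beta_uy_star / denom
  list(b_g_star = beta_gy_star + bias_g,
       b_x_star = beta_xy_star + bias_x,
       bias_g = bias_g, bias_x = bias_x)
}

#' Fitted exposure effect under collider bias with measurement error
#'
#' The general fitted coefficient of the observed outcome on the observed
#' exposure, adjusting for the observed polygenic score, when the exposure is
#' a collider and all three indicators carry measurement error:
#' \deqn{b_{XY} = \frac{l_X l_Y\left[\beta_{X^*Y^*}(1 - l_G^2\beta_{G^*X^*}^2)
#'   + \beta_{U^*X^*}\beta_{U^*Y^*}
#'   + \beta_{G^*X^*}\beta_{G^*Y^*}(1 - l_G^2)\right]}
#'   {1 - l_G^2 l_X^2 \beta_{G^*X^*}^2}}
#' The three numerator terms separate the (attenuated) causal effect, the
#' collider bias through the unmeasured confounder, and the genetic
#' confounding left unadjusted by an unreliable score. With
#' \eqn{l_G = l_X = l_Y = 1} the expression reduces to the
#' [collider_adjusted_effects()] exposure coefficient. As the score becomes
#' more reliable the confounding term shrinks while the collider term
#' persists.
#'
#' @inheritParams collider_adjusted_effects
#' @param l_g,l_x,l_y loadings of the polygenic score, exposure, and outcome.
#' @return list with `fitted` (b_XY) and the decomposition `causal_term`,
#'   `collider_term`, `confounding_term` (each already divided by the common
#'   denominator, so they sum to `fitted`).
#' @export
full_collider_fitted_bxy <- function(beta_xy_star, beta_gx_star,
                                     beta_gy_star, beta_ux_star,
                                     beta_uy_star, l_g = 1, l_x = 1, l_y = 1) {
  check_loading(l_g, "l_g"); check_loading(l_x, "l_x"); check_loading(l_y, "l_y")
  denom <- 1 - l_g^2 * l_x^2 * beta_gx_star^2
  if (denom <= 0) stop("degenerate model: 1 - l_g^2 * l_x^2 * beta_gx_star^2 <= 0")
  causal <- l_x * l_y * beta_xy_star * (1 - l_g^2 * beta_gx_star^2) / denom
  collider <- l_x * l_y * beta_ux_star * beta_uy_star / denom
  confounding <- l_x * l_y * beta_gx_star * beta_gy_star * (1 - l_g^2) / denom
  list(fitted = causal + collider + confounding,
       causal_term = causal, collider_term = collider,
       confounding_term = confounding)
}
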