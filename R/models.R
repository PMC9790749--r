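#' Canonical figure models
#'
#' Builders for the standardized path models the bias formulas refer to.
#' All coefficients and loadings are standardized; reliabilities are the
#' squared loadings (e.g. a polygenic score of reliability 0.10 has loading
#' `sqrt(0.10)` on the true genetic factor).
#'
#' * `measurement_error_model()`: a true genetic factor `G*` affects a true
#'   outcome `Y*`; the polygenic score `G` and the measured outcome `Y` are
#'   unreliable indicators with loadings `l_g` and `l_y`.
#' * `exposure_model()`: `G*` affects an exposure `X*` and the outcome `Y*`;
#'   `X*` affects `Y*`; only the polygenic score `G` (loading `l_g`) is an
#'   imperfect indicator, `X*` and `Y*` being taken as perfectly measured
#'   unless loadings `l_x`, `l_y` below 1 are supplied (then observed `X`,
#'   `Y` are added).
#' * `collider_model()`: adds a non-genetic confounder `U*` of the
#'   `X*`-`Y*` association, with `G*` affecting only `X*` (so `X*` is a
#'   collider for `G*` and `U*`); loadings below 1 add observed indicators
#'   `G`, `X`, `Y`.
#'
#' @param beta_gy_star standardized effect of `G*` on `Y*`.
#' @param beta_gx_star standardized effect of `G*` on `X*`.
#' @param beta_xy_star standardized effect of `X*` on `Y*`.
#' @param beta_ux_star,beta_uy_star standardized effects of the unmeasured
#'   confounder `U*` on `X*` and `Y*`.
#' @param l_g,l_x,l_y loadings of the observed indicators on their latent
#'   true variables (reliability is the squared loading).
#' @return a `pgsbias_model`.
#' @examples
#' m <- measurement_error_model(0.9, l_g = sqrt(0.10), l_y = sqrt(0.80))
#' round(implied_correlations(m)["G", "Y"], 2)
#' @export
measurement_error_model <- function(beta_gy_star, l_g = 1, l_y = 1) {
  path_model(data.frame(
    source = c("G*", "G*", "Y*"),
    target = c("Y*", "G", "Y"),
    coefficient = c(beta_gy_star, l_g, l_y)))
}

#' @rdname measurement_error_model
#' @export
exposure_model <- function(beta_xy_star, beta_gx_star, beta_gy_star,
                           l_g = 1, l_x = 1, l_y = 1) {
  paths <- data.frame(
    source = c("G*", "X*", "G*", "G*"),
    target = c("X*", "Y*", "Y*", "G"),
    coefficient = c(beta_gx_star, beta_xy_star, beta_gy_star, l_g))
  if (l_x < 1) paths <- rbind(paths, data.frame(source = "X*", target = "X",
                                                coefficient = l_x))
  if (l_y < 1) paths <- rbind(paths, data.frame(source = "Y*", target = "Y",
                                                coefficient = l_y))
  path_model(paths)
}

#' @rdname measurement_error_model
#' @export
collider_model <- function(beta_xy_star, beta_gx_star, beta_gy_star,
                           beta_ux_star, beta_uy_star,
                           l_g = 1, l_x = 1, l_y = 1) {
  paths <- data.frame(
    source = c("G*", "U*", "X*", "U*", "G*"),
    target = c("X*", "X*", "Y*", "Y*", "Y*"),
    coefficient = c(beta_gx_star, beta_ux_star, beta_xy_star,
                    beta_uy_star, beta_gy_star))
  paths <- rbind(paths,
                 data.frame(source = "G*", target = "G", coefficient = l_g),
                 data.frame(source = "X*", target = "X", coefficient = l_x),
                 data.frame(source = "Y*", target = "Y", coefficient = l_y))
  path_model(paths)
}
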