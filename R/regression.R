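#' Standardized partial regression coefficients from a correlation matrix
#'
#' Solves the normal equations on a correlation (sub)matrix to obtain the
#' standardized coefficients of the least-squares regression of `outcome` on
#' `predictors`. With a single predictor the coefficient equals the
#' correlation. This is the "fitted model" side of every path diagram: what a
#' researcher would estimate by OLS in an infinite sample.
#'
#' @param corr correlation matrix with dimnames covering outcome and
#'   predictors.
#' @param outcome name of the outcome variable.
#' @param predictors character vector of predictor names.
#' @return list of class `pgsbias_regression` with elements `outcome`,
#'   `predictors`, `coefficients` (named numeric) and `r_squared`.
#' @examples
#' m <- exposure_model(0, sqrt(0.15), sqrt(0.30), l_g = sqrt(0.10))
#' fit <- partial_coefficients(implied_correlations(m), "Y*", c("X*", "G"))
#' round(fit$coefficients[["X*"]], 2)  # 0.19: residual genetic confounding
#' @export
partial_coefficients <- function(corr, outcome, predictors) {
  stopifnot(is.matrix(corr), !is.null(rownames(corr)))
  missing <- setdiff(c(outcome, predictors), rownames(corr))
  if (length(missing)) stop("variables not in correlation matrix: ",
                            paste(missing, collapse = ", "))
  Rxx <- corr[predictors, predictors, drop = FALSE]
  rxy <- corr[predictors, outcome]
  beta <- tryCatch(solve(Rxx, rxy), error = function(e) {
    stop("singular predictor correlation submatrix (",
         conditionMessage(e), ")", call. = FALSE)
  })
  r2 <- drop(crossprod(rxy, beta))
  structure(list(outcome = outcome, predictors = predictors,
                 coefficients = stats::setNames(as.numeric(beta), predictors),
                 r_squared = as.numeric(r2)),
            class = "pgsbias_regression")
}

#' @export
print.pgsbias_regression <- function(x, ...) {
  cat("Standardized OLS:", x$outcome, "~",
      paste(x$predictors, collapse = " + "), "\n")
  print(round(x$coefficients, 6))
  cat("R-squared:", format(x$r_squared, digits = 6), "\n")
  invisible(x)
}

#' Standardized OLS on individual-level data
#'
#' Z-scores all columns and fits ordinary least squares; the returned
#' coefficients equal [partial_coefficients()] applied to the sample
#' correlation matrix (up to numerical tolerance). No intercept is reported:
#' standardization makes it zero.
#'
#' @param data data frame or matrix with named numeric columns.
#' @param outcome,predictors column names.
#' @return a `pgsbias_regression` (see [partial_coefficients()]).
#' @export
fit_ols <- function(data, outcome, predictors) {
  data <- as.data.frame(data)
  missing <- setdiff(c(outcome, predictors), names(data))
  if (length(missing)) stop("columns not in data: ",
                            paste(missing, collapse = ", "))
  n <- nrow(data)
  if (n <= length(predictors) + 1) stop("need n > number of predictors + 1")
  cols <- data[, c(outcome, predictors), drop = FALSE]
  sds <- vapply(cols, stats::sd, numeric(1))
  if (any(sds == 0)) stop("constant column: ",
                          paste(names(sds)[sds == 0], collapse = ", "))
  corr <- stats::cor(as.matrix(cols))
  partial_coefficients(corr, outcome, predictors)
}

#' Mediation of a polygenic-score effect through a risk factor
#'
#' Product-of-coefficients mediation: `a_hat` is the simple standardized
#' coefficient of the mediator on the score, `b_hat` the partial coefficient
#' of the mediator in the outcome regression adjusting for the score,
#' `total` the simple coefficient of the outcome on the score, and the
#' indirect effect is `a_hat * b_hat`. The proportion mediated is
#' `indirect / total`, reported as `NA` (with `proportion_defined = FALSE`)
#' when the total association is numerically zero.
#'
#' @param x a correlation matrix with dimnames, or an individual-level data
#'   frame (columns are then z-scored).
#' @param g,mediator,outcome variable names.
#' @return list of class `pgsbias_mediation` with elements `a_hat`, `b_hat`,
#'   `indirect`, `total`, `direct`, `proportion_mediated`,
#'   `proportion_defined`.
#' @export
mediation_estimate <- function(x, g, mediator, outcome) {
  corr <- if (is.matrix(x) && isTRUE(all.equal(unname(diag(x)),
                                               rep(1, nrow(x))))) {
    x
  } else {
    stats::cor(as.matrix(as.data.frame(x)[, c(g, mediator, outcome)]))
  }
  a_hat <- corr[g, mediator]
  fit <- partial_coefficients(corr, outcome, c(mediator, g))
  b_hat <- fit$coefficients[[mediator]]
  total <- corr[g, outcome]
  indirect <- a_hat * b_hat
  defined <- abs(total) >= 1e-12
  structure(list(a_hat = a_hat, b_hat = b_hat, indirect = indirect,
                 total = total, direct = fit$coefficients[[g]],
                 proportion_mediated = if (defined) indirect / total else NA_real_,
                 proportion_defined = defined),
            class = "pgsbias_mediation")
}

#' @export
print.pgsbias_mediation <- function(x, ...) {
  cat("Mediation (product of coefficients):\n")
  cat("  a =", format(x$a_hat, digits = 6),
      " b =", format(x$b_hat, digits = 6), "\n")
  cat("  indirect =", format(x$indirect, digits = 6),
      " total =", format(x$total, digits = 6), "\n")
  cat("  proportion mediated =",
      if (x$proportion_defined) format(x$proportion_mediated, digits = 6)
      else "undefined (total ~ 0)", "\n")
  invisible(x)
}

#' Write a regression result as TSV rows
#'
#' One row per predictor: outcome, predictor, coefficient.
#'
#' @param fit a `pgsbias_regression`.
#' @param file output path.
#' @export
write_regression_tsv <- function(fit, file) {
  df <- data.frame(outcome = fit$outcome, predictor = fit$predictors,
                   coefficient = as.numeric(fit$coefficients))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
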