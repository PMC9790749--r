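test_that("attenuation formula: worked example, no-error and pure-noise limits", {
  res <- attenuated_pgs_effect(0.9, l_g = sqrt(0.10), l_y = sqrt(0.80))
  expect_equal(res$fitted, sqrt(0.8) * sqrt(0.1) * 0.9, tolerance = 1e-12)
  expect_equal(round(res$fitted, 2), 0.25)
  expect_equal(res$bias, res$fitted - 0.9)

  perfect <- attenuated_pgs_effect(0.7, 1, 1)
  expect_equal(perfect$fitted, 0.7)
  expect_equal(perfect$bias, 0)

  noise <- attenuated_pgs_effect(0.7, 0, 1)
  expect_equal(noise$fitted, 0)
  expect_equal(noise$bias, -0.7)

  expect_error(attenuated_pgs_effect(0.5, l_g = 1.2), "loading")
})

test_that("score reliability is the ratio of explained variance to heritability", {
  expect_equal(pgs_reliability(0.03, 0.30)$l_g_squared, 0.10)
  expect_equal(round(pgs_reliability(0.114, 0.147)$l_g_squared, 3), 0.776)
  r <- pgs_reliability(0.3, 0.3)
  expect_equal(r$l_g_squared, 1)
  expect_true(r$consistent)
  expect_false(pgs_reliability(0.4, 0.3)$consistent)
  expect_error(pgs_reliability(0.1, 0), "positive")
})

test_that("residual confounding after score adjustment: 0.19 example, exact adjustment at full reliability", {
  res <- adjusted_exposure_effect(0, sqrt(0.15), sqrt(0.30), sqrt(0.10))
  expect_equal(round(res$fitted, 2), 0.19)
  expect_equal(res$bias,
               sqrt(0.15) * sqrt(0.30) * 0.9 / (1 - 0.1 * 0.15),
               tolerance = 1e-12)

  full <- adjusted_exposure_effect(0.25, 0.5, 0.4, l_g = 1)
  expect_equal(full$fitted, 0.25)
  expect_equal(full$bias, 0)
})

test_that("fitted mediation: unbiased at full reliability, false positive under the null", {
  p <- list(beta_xy_star = 0.3, beta_gx_star = 0.5, beta_gy_star = 0.2)
  res <- fitted_mediated_effect(p$beta_xy_star, p$beta_gx_star,
                                p$beta_gy_star, l_g = 1)
  expect_equal(res$b_m, res$beta_m, tolerance = 1e-12)
  expect_equal(res$p_m, res$pi_m, tolerance = 1e-12)

  null <- fitted_mediated_effect(0, sqrt(0.15), sqrt(0.30), sqrt(0.10))
  expect_equal(null$beta_m, 0)
  expect_equal(null$b_m, sqrt(0.10) * sqrt(0.15) * null$bias, tolerance = 1e-12)
  expect_lt(abs(null$b_m - 0.0237), 5e-4)

  undef <- fitted_mediated_effect(0.5, 0, 0, sqrt(0.5))
  expect_false(undef$proportions_defined)
})

test_that("collider adjustment: worked values, no bias without confounder paths, underestimation with positive paths", {
  res <- collider_adjusted_effects(0.2, 0.6, 0, 0.5, 0.5)
  expect_equal(res$b_g_star, -0.234375, tolerance = 1e-12)
  expect_equal(res$b_x_star, 0.590625, tolerance = 1e-12)

  clean <- collider_adjusted_effects(0.2, 0.6, 0.1, 0, 0.5)
  expect_equal(clean$b_x_star, 0.2)
  expect_equal(clean$b_g_star, 0.1)

  set.seed(31)
  for (i in 1:50) {
    p <- random_collider_params(with_loadings = FALSE)
    p$beta_gx_star <- abs(p$beta_gx_star)
    p$beta_ux_star <- abs(p$beta_ux_star)
    p$beta_uy_star <- abs(p$beta_uy_star)
    r <- collider_adjusted_effects(p$beta_xy_star, p$beta_gx_star,
                                   p$beta_gy_star, p$beta_ux_star,
                                   p$beta_uy_star)
    if (p$beta_gx_star * p$beta_ux_star * p$beta_uy_star > 0) {
      expect_lt(r$b_g_star, p$beta_gy_star)
    }
  }
  expect_error(collider_adjusted_effects(0, 1, 0, 0.5, 0.5), "< 1")
})

test_that("full collider expression reduces at unit loadings and decomposes into causal, collider, confounding terms", {
  set.seed(32)
  for (i in 1:25) {
    p <- random_collider_params(with_loadings = FALSE)
    full <- do.call(full_collider_fitted_bxy, p)
    simple <- collider_adjusted_effects(p$beta_xy_star, p$beta_gx_star,
                                        p$beta_gy_star, p$beta_ux_star,
                                        p$beta_uy_star)
    expect_equal(full$fitted, simple$b_x_star, tolerance = 1e-12)
    expect_equal(full$confounding_term, 0, tolerance = 1e-12)
    expect_equal(full$causal_term + full$collider_term + full$confounding_term,
                 full$fitted, tolerance = 1e-12)
  }
})

test_that("closed forms equal OLS on implied correlations over random parameter draws", {
  set.seed(33)
  for (i in 1:100) {
    p <- random_fig2_params()
    m <- exposure_model(p$beta_xy_star, p$beta_gx_star, p$beta_gy_star, p$l_g)
    corr <- implied_correlations(m)
    fit <- partial_coefficients(corr, "Y*", c("X*", "G"))
    an <- adjusted_exposure_effect(p$beta_xy_star, p$beta_gx_star,
                                   p$beta_gy_star, p$l_g)
    expect_equal(fit$coefficients[["X*"]], an$fitted, tolerance = 1e-10)

    med_an <- fitted_mediated_effect(p$beta_xy_star, p$beta_gx_star,
                                     p$beta_gy_star, p$l_g)
    med_fit <- mediation_estimate(corr, "G", "X*", "Y*")
    expect_equal(med_fit$indirect, med_an$b_m, tolerance = 1e-10)
    if (med_an$proportions_defined) {
      expect_equal(med_fit$proportion_mediated, med_an$p_m, tolerance = 1e-8)
    }

    q <- random_collider_params()
    mc <- do.call(collider_model, q)
    cfit <- partial_coefficients(implied_correlations(mc), "Y", c("X", "G"))
    cfull <- do.call(full_collider_fitted_bxy, q)
    expect_equal(cfit$coefficients[["X"]], cfull$fitted, tolerance = 1e-10)
  }
})

test_that("attenuation grows with each loading; adjustment bias falls with reliability; confounding term shrinks as the score improves", {
  lg <- seq(0.1, 1, by = 0.1)
  att <- sapply(lg, function(l) attenuated_pgs_effect(0.8, l, 0.9)$fitted)
  expect_true(all(diff(att) > 0))
  bias <- sapply(lg, function(l)
    adjusted_exposure_effect(0, 0.4, 0.5, l)$bias)
  expect_true(all(diff(bias) < 0))
  expect_equal(bias[length(bias)], 0, tolerance = 1e-12)

  conf <- sapply(lg, function(l)
    full_collider_fitted_bxy(0.2, 0.5, 0.4, 0.4, 0.4, l_g = l)$confounding_term)
  coll <- sapply(lg, function(l)
    full_collider_fitted_bxy(0.2, 0.5, 0.4, 0.4, 0.4, l_g = l)$collider_term)
  expect_true(all(diff(conf) < 0))
  expect_true(all(coll > 0))
})

test_that("bias amplification: with a null genetic outcome path, adjusting moves the estimate further from the causal effect than not adjusting", {
  set.seed(34)
  for (i in 1:200) {
    p <- random_collider_params(with_loadings = FALSE)
    p$beta_gy_star <- 0
    p$beta_ux_star <- abs(p$beta_ux_star)
    p$beta_uy_star <- abs(p$beta_uy_star)
    m <- do.call(collider_model, p)
    if (!validate_model(m)$valid) next
    corr <- implied_correlations(m)
    r_xy <- corr["X*", "Y*"]
    b_adj <- collider_adjusted_effects(p$beta_xy_star, p$beta_gx_star, 0,
                                       p$beta_ux_star, p$beta_uy_star)$b_x_star
    expect_gte(abs(b_adj - p$beta_xy_star) + 1e-12,
               abs(r_xy - p$beta_xy_star))
  }
})
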