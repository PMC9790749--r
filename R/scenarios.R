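# standard error of a standardized OLS coefficient from the correlation
# matrix: sqrt((1 - R^2) * [Rxx^-1]_jj / (n - p - 1))
ols_coef_se <- function(corr, outcome, predictors, n) {
  fit <- partial_coefficients(corr, outcome, predictors)
  Rinv <- solve(corr[predictors, predictors, drop = FALSE])
  sqrt((1 - fit$r_squared) * diag(Rinv) / (n - length(predictors) - 1))
}

cor_se <- function(r, n) (1 - r^2) / sqrt(n)

report_row <- function(label, analytic, estimate, mc_se) {
  z <- if (is.na(analytic) || is.na(mc_se) || mc_se == 0) NA_real_
       else abs(estimate - analytic) / mc_se
  data.frame(label = label, analytic = analytic, estimate = estimate,
             mc_se = mc_se, z = z,
             pass = is.na(z) || z <= 4,
             stringsAsFactors = FALSE)
}

#' Scenario configuration
#'
#' @param name registered scenario name (see [list_scenarios()]).
#' @param n simulated sample size.
#' @param seed integer seed.
#' @param params named list of scenario-specific parameter overrides;
#'   unknown keys are an error, not a warning.
#' @return list of class `pgsbias_scenario_config`.
#' @export
scenario_config <- function(name, n = 1e5, seed = 1, params = list()) {
  structure(list(name = name, n = as.numeric(n), seed = as.integer(seed),
                 params = params),
            class = "pgsbias_scenario_config")
}

merge_params <- function(defaults, params, scenario) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s) for scenario '", scenario, "': ",
         paste(unknown, collapse = ", "),
         " (known: ", paste(names(defaults), collapse = ", "), ")")
  }
  utils::modifyList(defaults, params)
}

# --- individual scenarios ---------------------------------------------------

scenario_fig1 <- function(n, seed, params) {
  p <- merge_params(list(beta_gy_star = 0.9, l_g = sqrt(0.10),
                         l_y = sqrt(0.80)), params, "measurement_error")
  m <- measurement_error_model(p$beta_gy_star, p$l_g, p$l_y)
  d <- simulate_model(m, n, seed)
  analytic <- attenuated_pgs_effect(p$beta_gy_star, p$l_g, p$l_y)$fitted
  est <- stats::cor(d$G, d$Y)
  report_row("r(G, Y)", analytic, est, cor_se(analytic, n))
}

scenario_fig2 <- function(n, seed, params) {
  p <- merge_params(list(beta_xy_star = 0, beta_gx_star = sqrt(0.15),
                         beta_gy_star = sqrt(0.30), l_g = sqrt(0.10)),
                    params, "confounding_mediation")
  m <- exposure_model(p$beta_xy_star, p$beta_gx_star, p$beta_gy_star, p$l_g)
  d <- simulate_model(m, n, seed)
  corr <- implied_correlations(m)
  adj <- adjusted_exposure_effect(p$beta_xy_star, p$beta_gx_star,
                                  p$beta_gy_star, p$l_g)
  med <- fitted_mediated_effect(p$beta_xy_star, p$beta_gx_star,
                                p$beta_gy_star, p$l_g)
  fit <- fit_ols(d, "Y*", c("X*", "G"))
  se <- ols_coef_se(corr, "Y*", c("X*", "G"), n)
  med_hat <- mediation_estimate(d, "G", "X*", "Y*")
  rbind(
    report_row("b_XstarYstar | G", adj$fitted, fit$coefficients[["X*"]],
               se[["X*"]]),
    report_row("fitted mediated effect b_M", med$b_m, med_hat$indirect,
               2 / sqrt(n)))
}

scenario_fig3 <- function(n, seed, params) {
  p <- merge_params(list(beta_xy_star = 0.2, beta_gx_star = 0.6,
                         beta_gy_star = 0, beta_ux_star = 0.5,
                         beta_uy_star = 0.5), params, "collider")
  m <- collider_model(p$beta_xy_star, p$beta_gx_star, p$beta_gy_star,
                      p$beta_ux_star, p$beta_uy_star)
  d <- simulate_model(m, n, seed)
  corr <- implied_correlations(m)
  an <- collider_adjusted_effects(p$beta_xy_star, p$beta_gx_star,
                                  p$beta_gy_star, p$beta_ux_star,
                                  p$beta_uy_star)
  fit <- fit_ols(d, "Y*", c("X*", "G*"))
  se <- ols_coef_se(corr, "Y*", c("X*", "G*"), n)
  rbind(
    report_row("b_XstarYstar (collider-adjusted)", an$b_x_star,
               fit$coefficients[["X*"]], se[["X*"]]),
    report_row("b_GstarYstar (collider-adjusted)", an$b_g_star,
               fit$coefficients[["G*"]], se[["G*"]]))
}

scenario_figS2 <- function(n, seed, params) {
  p <- merge_params(list(beta_xy_star = 0.2, beta_gx_star = 0.6,
                         beta_gy_star = 0.3, beta_ux_star = 0.5,
                         beta_uy_star = 0.4, l_g = sqrt(0.10),
                         l_x = sqrt(0.80), l_y = sqrt(0.80)),
                    params, "full_collider")
  m <- collider_model(p$beta_xy_star, p$beta_gx_star, p$beta_gy_star,
                      p$beta_ux_star, p$beta_uy_star, p$l_g, p$l_x, p$l_y)
  d <- simulate_model(m, n, seed)
  corr <- implied_correlations(m)
  an <- full_collider_fitted_bxy(p$beta_xy_star, p$beta_gx_star,
                                 p$beta_gy_star, p$beta_ux_star,
                                 p$beta_uy_star, p$l_g, p$l_x, p$l_y)
  fit <- fit_ols(d, "Y", c("X", "G"))
  se <- ols_coef_se(corr, "Y", c("X", "G"), n)
  report_row("b_XY (observed, adjusted for G)", an$fitted,
             fit$coefficients[["X"]], se[["X"]])
}

scenario_fig4_reverse <- function(n, seed, params) {
  p <- merge_params(list(beta_gy_star = 0.5, beta_yx_star = 0.4,
                         l_g = sqrt(0.10)), params, "reverse_causation")
  m <- path_model(data.frame(
    source = c("G*", "Y*", "G*"),
    target = c("Y*", "X*", "G"),
    coefficient = c(p$beta_gy_star, p$beta_yx_star, p$l_g)))
  d <- simulate_model(m, n, seed)
  analytic <- p$l_g * p$beta_gy_star * p$beta_yx_star
  report_row("r(G, X*) under reverse causation", analytic,
             stats::cor(d$G, d$"X*"), cor_se(analytic, n))
}

scenario_fig4_nonheritable <- function(n, seed, params) {
  p <- merge_params(list(beta_xy_star = 0.4, beta_gy_star = 0.5,
                         l_g = sqrt(0.10)), params, "nonheritable_exposure")
  m <- path_model(data.frame(
    source = c("X*", "G*", "G*"),
    target = c("Y*", "Y*", "G"),
    coefficient = c(p$beta_xy_star, p$beta_gy_star, p$l_g)))
  d <- simulate_model(m, n, seed)
  report_row("r(G, X*) for a non-heritable exposure", 0,
             stats::cor(d$G, d$"X*"), 1 / sqrt(n))
}

scenario_fig6_strat <- function(n, seed, params) {
  p <- merge_params(list(delta_freq = 0.1, outcome_offset = 0.5, L = 500,
                         true_effect = 0), params, "stratification")
  res <- stratification_scenario(p$delta_freq, p$outcome_offset,
                                 n_per_pop = floor(n / 2), seed = seed,
                                 L = p$L, true_effect = p$true_effect)
  rbind(
    report_row("score-outcome association (unadjusted)", NA_real_,
               res$unadjusted, NA_real_),
    report_row("score-outcome association (ancestry-adjusted)",
               p$true_effect, res$adjusted, 2 / sqrt(n)))
}

scenario_fig6_am <- function(n, seed, params) {
  p <- merge_params(list(L = 1000, spousal_corr = 0.4), params,
                    "assortative_mating")
  n_trio <- max(floor(n / 20), 500)  # genotype-level cost per trio is high
  par <- simulate_parents(p$L, n_trio, stats::runif(p$L, 0.1, 0.9),
                          spousal_corr = p$spousal_corr, seed = seed)
  tr <- mate_and_transmit(par, seed = seed + 1)
  sc <- tr$scores
  rbind(
    report_row("spousal score correlation", p$spousal_corr,
               stats::cor(sc$G_M, sc$G_F), 0.02 + cor_se(p$spousal_corr, n_trio)),
    report_row("parent-child score correlation", NA_real_,
               stats::cor(sc$G_M, sc$G_C), NA_real_))
}

scenario_fig7_nurture <- function(n, seed, params) {
  p <- merge_params(list(L = 500, individual_effect = 0.3, nurture_m = 0.3,
                         nurture_f = 0.3, parent_env_m = 0.5,
                         parent_env_f = 0.5, evocative_m = 0.2,
                         evocative_f = 0), params, "genetic_nurture")
  n_trio <- max(floor(n / 20), 500)
  par <- simulate_parents(p$L, n_trio, stats::runif(p$L, 0.1, 0.9), seed = seed)
  tr <- mate_and_transmit(par, seed = seed + 1)
  cfg <- family_effect_config(p$individual_effect, p$nurture_m, p$nurture_f,
                              p$parent_env_m, p$parent_env_f,
                              p$evocative_m, p$evocative_f)
  tr <- simulate_family_phenotypes(tr, cfg, seed = seed + 2)
  est <- estimate_nurture(tr, n_boot = 100, seed = seed + 3)
  nt <- est$non_transmitted
  marg <- est$child_only
  rbind(
    report_row("non-transmitted maternal coefficient (nurture > 0)",
               NA_real_, nt$estimate[nt$term == "G_Mnt"],
               nt$se[nt$term == "G_Mnt"]),
    report_row("child-score marginal coefficient", NA_real_,
               marg$estimate[1], marg$se[1]))
}

scenario_referral <- function(n, seed, params) {
  p <- merge_params(list(p_high_g = 0.2, p_high_e = 0.2), params,
                    "referral_selection")
  m <- path_model(NULL, variables = c("Gscore", "Erisk"))
  d <- simulate_model(m, n, seed)
  d <- dichotomize(d, "Gscore", p$p_high_g)
  d <- dichotomize(d, "Erisk", p$p_high_e)
  sel <- apply_selection(d, keep_any = c("Gscore_high", "Erisk_high"))
  exact <- selection_phi_exact(p$p_high_g, p$p_high_e)
  rbind(
    report_row("within-referral phi", exact, sel$phi, 3 / sqrt(sel$n_selected)),
    report_row("both-low cell count", 0, sel$table[1, 1], NA_real_))
}

scenario_perception <- function(n, seed, params) {
  perception_scenario(scenario_config("perception", n = n, seed = seed,
                                      params = params))$rows
}

# Exact within-stratum phi when two independent binary risks with the given
# high-risk probabilities are selected on "either high": enumeration over the
# three admissible cells of the multinomial.
selection_phi_exact <- function(p1, p2) {
  keep <- p1 * p2 + p1 * (1 - p2) + (1 - p1) * p2
  p11 <- p1 * p2 / keep
  p10 <- p1 * (1 - p2) / keep
  p01 <- (1 - p1) * p2 / keep
  p00 <- 0
  (p11 * p00 - p10 * p01) /
    sqrt((p11 + p10) * (p01 + p00) * (p11 + p01) * (p10 + p00))
}

scenario_registry <- function() {
  list(
    fig1_measurement_error = scenario_fig1,
    fig2_confounding_mediation = scenario_fig2,
    fig3_collider = scenario_fig3,
    figS2_full_collider = scenario_figS2,
    fig4_reverse_causation = scenario_fig4_reverse,
    fig4_nonheritable_exposure = scenario_fig4_nonheritable,
    fig5_perception = scenario_perception,
    fig6_stratification = scenario_fig6_strat,
    fig6_assortative_mating = scenario_fig6_am,
    fig7_genetic_nurture = scenario_fig7_nurture,
    referral_selection = scenario_referral
  )
}

#' List the registered demonstration scenarios
#'
#' Each scenario realizes one of the canonical bias mechanisms (measurement
#' error, genetic confounding, collider bias, reverse causation,
#' non-heritable exposure, risk perception, stratification, assortative
#' mating, genetic nurture, referral selection) by simulation and compares
#' the estimates with their closed-form values where one exists.
#'
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() names(scenario_registry())

#' Run a registered scenario
#'
#' Simulates the scenario at the configured size and seed, runs its
#' estimators, and compares each estimate with its analytic value. A row
#' whose estimate sits more than 4 Monte-Carlo standard errors from the
#' analytic value marks the scenario as failed; rows without an analytic
#' value are descriptive.
#'
#' @param config a [scenario_config()].
#' @return list of class `pgsbias_report` with elements `scenario`, `rows`
#'   (data frame: label, analytic, estimate, mc_se, z, pass), `passed`,
#'   `n`, `seed`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "pgsbias_scenario_config"))
  reg <- scenario_registry()
  if (!config$name %in% names(reg)) {
    stop("unknown scenario '", config$name, "'; known scenarios: ",
         paste(names(reg), collapse = ", "))
  }
  rows <- reg[[config$name]](config$n, config$seed, config$params)
  structure(list(scenario = config$name, rows = rows,
                 passed = all(rows$pass), n = config$n, seed = config$seed),
            class = "pgsbias_report")
}

#' @export
print.pgsbias_report <- function(x, ...) {
  cat("Scenario '", x$scenario, "' (n = ", format(x$n, big.mark = ","),
      ", seed = ", x$seed, "): ",
      if (x$passed) "PASS" else "FAIL", "\n", sep = "")
  print(x$rows, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Genetically influenced perception of environmental risk
#'
#' Simulates the risk-perception model: an objective exposure informs its
#' perceived counterpart, but perception is also shaped by a genetically
#' influenced phenotype. In the base variant the report shows a nonzero
#' correlation between the polygenic score and *perceived* risk (a false
#' positive gene-environment correlation) alongside null correlations of the
#' score with the objective risk and of the objective risk with the
#' phenotype. With `p_y2 != 0` a later outcome influenced by perception is
#' added and the simulated score-outcome correlation is checked against the
#' implied path product.
#'
#' @param config a [scenario_config()]; recognized params: `beta_gy1`
#'   (genetic effect on the phenotype), `l_g` (score loading), `w_obj`
#'   (objective-risk weight in perception), `w_phen` (phenotype weight in
#'   perception), `p_y2` (perception effect on the later outcome; 0 omits
#'   the second outcome).
#' @return a `pgsbias_report` (see [run_scenario()]).
#' @export
perception_scenario <- function(config) {
  p <- merge_params(list(beta_gy1 = 0.5, l_g = sqrt(0.10), w_obj = 0.5,
                         w_phen = 0.4, p_y2 = 0), config$params, "perception")
  paths <- data.frame(
    source = c("G*", "G*", "O*", "Y1*"),
    target = c("Y1*", "G", "P*", "P*"),
    coefficient = c(p$beta_gy1, p$l_g, p$w_obj, p$w_phen))
  if (p$p_y2 != 0) {
    paths <- rbind(paths, data.frame(source = "P*", target = "Y2*",
                                     coefficient = p$p_y2))
  }
  m <- path_model(paths)
  n <- config$n
  d <- simulate_model(m, n, config$seed)
  corr <- implied_correlations(m)
  rows <- rbind(
    report_row("r(G, perceived risk)", corr["G", "P*"],
               stats::cor(d$G, d$"P*"), cor_se(corr["G", "P*"], n)),
    report_row("r(G, objective risk)", 0, stats::cor(d$G, d$"O*"),
               1 / sqrt(n)),
    report_row("r(objective risk, phenotype)", 0,
               stats::cor(d$"O*", d$"Y1*"), 1 / sqrt(n)))
  if (p$p_y2 != 0) {
    rows <- rbind(rows, report_row(
      "r(G, later outcome Y2)", corr["G", "Y2*"],
      stats::cor(d$G, d$"Y2*"), cor_se(corr["G", "Y2*"], n)))
  }
  structure(list(scenario = "fig5_perception", rows = rows,
                 passed = all(rows$pass), n = n, seed = config$seed),
            class = "pgsbias_report")
}

#' Combine scenario reports into a summary table
#'
#' @param reports list of `pgsbias_report` objects.
#' @param file optional path; when given, the summary is written as TSV.
#' @return list of class `pgsbias_summary` with `table` (one row per
#'   quantity, scenario column first) and `exit_status` (0 when every
#'   scenario passed, 1 otherwise).
#' @export
make_report <- function(reports, file = NULL) {
  stopifnot(length(reports) >= 1)
  tab <- do.call(rbind, lapply(reports, function(r) {
    cbind(data.frame(scenario = r$scenario, stringsAsFactors = FALSE), r$rows)
  }))
  rownames(tab) <- NULL
  status <- if (all(tab$pass)) 0L else 1L
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(table = tab, exit_status = status), class = "pgsbias_summary")
}

#' @export
print.pgsbias_summary <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat("exit status:", x$exit_status, "\n")
  invisible(x)
}
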