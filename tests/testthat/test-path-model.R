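test_that("validation flags cycles, impossible variances, and accepts the measurement-error model", {
  cyc <- path_model(data.frame(source = c("A", "B"), target = c("B", "A"),
                               coefficient = c(0.6, 0.5)))
  v <- validate_model(cyc)
  expect_false(v$valid)
  expect_match(paste(v$issues, collapse = " "), "cycle")

  over <- path_model(data.frame(source = c("A", "B"), target = c("C", "C"),
                                coefficient = c(0.9, 0.9)))
  v <- validate_model(over)
  expect_false(v$valid)
  expect_match(paste(v$issues, collapse = " "), "C")

  fig1 <- measurement_error_model(0.9, sqrt(0.10), sqrt(0.80))
  expect_true(validate_model(fig1)$valid)

  dup <- path_model(data.frame(source = c("A", "A"), target = c("B", "B"),
                               coefficient = c(0.2, 0.3)))
  expect_false(validate_model(dup)$valid)
  loop <- path_model(data.frame(source = "A", target = "A", coefficient = 0.5))
  expect_false(validate_model(loop)$valid)
})

test_that("implied correlations reproduce the attenuation worked example and trivial cases", {
  fig1 <- measurement_error_model(0.9, sqrt(0.10), sqrt(0.80))
  corr <- implied_correlations(fig1)
  expect_equal(corr["G", "Y"], sqrt(0.80) * sqrt(0.10) * 0.9, tolerance = 1e-12)
  expect_equal(round(corr["G", "Y"], 2), 0.25)
  expect_equal(diag(corr), setNames(rep(1, 4), rownames(corr)))
  expect_equal(corr, t(corr))

  empty <- path_model(NULL, variables = c("A", "B", "C"))
  expect_equal(unname(implied_correlations(empty)), diag(3))

  expect_error(implied_correlations(
    path_model(data.frame(source = c("A", "B"), target = c("B", "A"),
                          coefficient = c(0.6, 0.5)))), "invalid")
})

test_that("residual variances: exogenous 1, measured outcome 0.20, saturated child 0", {
  fig1 <- measurement_error_model(0.9, sqrt(0.10), sqrt(0.80))
  rv <- residual_variances(fig1)
  expect_equal(rv[["G*"]], 1)
  expect_equal(rv[["Y"]], 0.20, tolerance = 1e-12)
  expect_equal(rv[["G"]], 0.90, tolerance = 1e-12)

  sat <- path_model(data.frame(source = c("A", "B"), target = c("C", "C"),
                               coefficient = c(0.6, 0.8)))
  expect_equal(residual_variances(sat)[["C"]], 0, tolerance = 1e-12)
})

test_that("recursive solve agrees with reduced-form matrix solve and the path-enumeration oracle", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_valid_model()
    rec <- implied_correlations(m, method = "recursive")
    mat <- implied_correlations(m, method = "matrix")
    expect_equal(rec, mat, tolerance = 1e-12)
    expect_equal(rec, implied_corr_oracle(m), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(min(eigen(rec, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
  }
})

test_that("residual co-paths between exogenous variables propagate, and match a Monte-Carlo draw", {
  m <- path_model(
    data.frame(source = c("GM*", "GF*"), target = c("YC*", "YC*"),
               coefficient = c(0.4, 0.4)),
    residual_correlations = data.frame(a = "GM*", b = "GF*", rho = 0.3))
  corr <- implied_correlations(m)
  expect_equal(corr["GM*", "GF*"], 0.3)
  # var(YC*) = 0.16 + 0.16 + 2*0.4*0.4*0.3, cov(GM*, YC*) = 0.4 + 0.4*0.3
  expect_equal(corr["GM*", "YC*"], 0.4 + 0.4 * 0.3, tolerance = 1e-12)
  expect_equal(residual_variances(m)[["YC*"]],
               1 - (0.32 + 2 * 0.16 * 0.3), tolerance = 1e-12)

  d <- simulate_model(m, n = 2e5, seed = 99)
  expect_lt(abs(cor(d$"GM*", d$"GF*") - 0.3), 3 / sqrt(2e5) + 0.005)
  expect_lt(abs(cor(d$"GM*", d$"YC*") - corr["GM*", "YC*"]),
            3 / sqrt(2e5) + 0.005)

  # residual correlations on endogenous variables are rejected
  bad <- path_model(
    data.frame(source = "A", target = "B", coefficient = 0.5),
    residual_correlations = data.frame(a = "A", b = "B", rho = 0.2))
  expect_false(validate_model(bad)$valid)
})

test_that("deleting an observed indicator leaves remaining correlations unchanged", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_valid_model()
    corr <- implied_correlations(m)
    sinks <- setdiff(m$variables$name, m$paths$source)
    if (!length(sinks)) next
    drop_var <- sinks[1]
    keep <- setdiff(m$variables$name, drop_var)
    paths2 <- m$paths[m$paths$target != drop_var, , drop = FALSE]
    m2 <- path_model(if (nrow(paths2)) paths2 else NULL, variables = keep)
    expect_equal(implied_correlations(m2)[keep, keep], corr[keep, keep],
                 tolerance = 1e-12)
  }
})

test_that("YAML round trip is lossless and the TSV export carries variable names", {
  m <- collider_model(0.2, 0.6, 0.3, 0.5, 0.4, sqrt(0.1), sqrt(0.8), sqrt(0.8))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_path_model(m, f)
  m2 <- read_path_model(f)
  expect_equal(m2$variables, m$variables)
  expect_equal(m2$paths, m$paths)
  expect_equal(implied_correlations(m2), implied_correlations(m))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_correlations_tsv(implied_correlations(m), tsv)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(back$variable, rownames(implied_correlations(m)))
  expect_equal(as.matrix(back[, -1]), implied_correlations(m),
               ignore_attr = TRUE, tolerance = 1e-10)
})
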