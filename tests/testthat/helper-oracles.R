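# Independent oracles used across the suite. These deliberately avoid the
# package's own solving code: correlations are rebuilt from brute-force
# enumeration of directed paths (the reduced form of Wright's tracing rules),
# with residual variances calibrated sequentially to force unit variances.

# all directed paths u -> v as coefficient products (1 for the empty path
# u == v); recursion over the edge list
path_sum_oracle <- function(paths, u, v) {
  if (u == v) return(1)
  out <- paths$source[paths$target == v]
  if (!length(out)) return(0)
  total <- 0
  for (i in which(paths$target == v)) {
    total <- total + paths$coefficient[i] *
      path_sum_oracle(paths, u, paths$source[i])
  }
  total
}

# implied correlation matrix by enumeration: Sigma = T Psi T', with
# T[v, s] the path sum from s's residual into v and Psi the residual
# covariance calibrated variable-by-variable so every diagonal equals 1
implied_corr_oracle <- function(model) {
  vars <- model$variables$name
  k <- length(vars)
  # order variables by ancestry depth (parents before children)
  depth <- setNames(rep(0L, k), vars)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(model$paths))) {
      s <- model$paths$source[i]; t <- model$paths$target[i]
      if (depth[t] <= depth[s]) { depth[t] <- depth[s] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  ord <- vars[order(depth, vars)]
  Tm <- matrix(0, k, k, dimnames = list(ord, ord))
  for (v in ord) for (s in ord) Tm[v, s] <- path_sum_oracle(model$paths, s, v)
  Psi <- diag(0, k); dimnames(Psi) <- list(ord, ord)
  rc <- model$residual_correlations
  for (v in ord) {
    others <- ord[Psi[cbind(ord, ord)] > 0]
    cross <- 0
    for (s in others) for (s2 in others) {
      cross <- cross + Tm[v, s] * Tm[v, s2] * Psi[s, s2]
    }
    Psi[v, v] <- 1 - cross
    if (nrow(rc)) {
      for (j in seq_len(nrow(rc))) {
        if (rc$a[j] == v && Psi[rc$b[j], rc$b[j]] > 0) {
          Psi[v, rc$b[j]] <- Psi[rc$b[j], v] <-
            rc$rho[j] * sqrt(Psi[v, v] * Psi[rc$b[j], rc$b[j]])
        } else if (rc$b[j] == v && Psi[rc$a[j], rc$a[j]] > 0) {
          Psi[v, rc$a[j]] <- Psi[rc$a[j], v] <-
            rc$rho[j] * sqrt(Psi[v, v] * Psi[rc$a[j], rc$a[j]])
        }
      }
    }
  }
  sigma <- Tm %*% Psi %*% t(Tm)
  sigma[vars, vars]
}

# random acyclic standardized model over <= max_vars variables; rejection
# sampling until all residual variances are admissible
random_valid_model <- function(max_vars = 6, p_edge = 0.4, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    k <- sample(3:max_vars, 1)
    vars <- paste0("V", sample(LETTERS, k))
    edges <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    keep <- runif(nrow(edges)) < p_edge
    if (!any(keep)) next
    edges <- edges[keep, , drop = FALSE]
    paths <- data.frame(source = vars[edges[, 1]],
                        target = vars[edges[, 2]],
                        coefficient = runif(nrow(edges), -0.6, 0.6))
    m <- path_model(paths, variables = vars)
    if (validate_model(m)$valid) return(m)
  }
  stop("could not draw a valid random model")
}

# exact within-stratum phi for keep-if-either selection of two independent
# Bernoulli risks: enumerate the four joint cells, drop the excluded
# both-low cell, renormalize, and compute phi from the stratum probabilities
selection_phi_exact_oracle <- function(p1, p2) {
  cells <- expand.grid(a = c(1, 0), b = c(1, 0))
  cells$p <- (p1^cells$a * (1 - p1)^(1 - cells$a)) *
    (p2^cells$b * (1 - p2)^(1 - cells$b))
  cells <- cells[cells$a == 1 | cells$b == 1, ]
  cells$p <- cells$p / sum(cells$p)
  e_a <- sum(cells$p * cells$a)
  e_b <- sum(cells$p * cells$b)
  e_ab <- sum(cells$p * cells$a * cells$b)
  (e_ab - e_a * e_b) / sqrt(e_a * (1 - e_a) * e_b * (1 - e_b))
}

# random valid parameter draws for the canonical figure models
random_fig2_params <- function() {
  repeat {
    p <- list(beta_xy_star = runif(1, -0.6, 0.6),
              beta_gx_star = runif(1, -0.8, 0.8),
              beta_gy_star = runif(1, -0.6, 0.6),
              l_g = sqrt(runif(1, 0.05, 1)))
    m <- exposure_model(p$beta_xy_star, p$beta_gx_star, p$beta_gy_star, p$l_g)
    if (validate_model(m)$valid) return(p)
  }
}

random_collider_params <- function(with_loadings = TRUE) {
  repeat {
    p <- list(beta_xy_star = runif(1, -0.5, 0.5),
              beta_gx_star = runif(1, -0.7, 0.7),
              beta_gy_star = runif(1, -0.5, 0.5),
              beta_ux_star = runif(1, -0.6, 0.6),
              beta_uy_star = runif(1, -0.6, 0.6),
              l_g = if (with_loadings) sqrt(runif(1, 0.05, 1)) else 1,
              l_x = if (with_loadings) sqrt(runif(1, 0.3, 1)) else 1,
              l_y = if (with_loadings) sqrt(runif(1, 0.3, 1)) else 1)
    m <- do.call(collider_model, p)
    if (validate_model(m)$valid) return(p)
  }
}
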