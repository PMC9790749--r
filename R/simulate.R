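#' Simulate individual-level data from a path model
#'
#' Draws `n` observations from the Gaussian structural model: each variable
#' is generated in topological order (lexicographic tie-break, so the output
#' is platform-stable) as the linear combination of its parents plus a
#' Gaussian residual with the model-derived residual variance. Residual
#' correlations between exogenous variables are realized by a joint draw.
#' Sample correlations converge to [implied_correlations()] as `n` grows.
#'
#' @param model a valid `pgsbias_model`.
#' @param n number of rows.
#' @param seed integer seed; the same `(model, n, seed)` reproduces the
#'   cohort bit-for-bit.
#' @param keep_latent if `FALSE`, latent (starred) columns are dropped.
#' @return data frame of class `pgsbias_cohort` with one column per retained
#'   variable; attributes `seed` and `model`.
#' @examples
#' m <- measurement_error_model(0.9, sqrt(0.10), sqrt(0.80))
#' d <- simulate_model(m, n = 1e4, seed = 1)
#' cor(d$G, d$Y)  # near 0.2546
#' @export
simulate_model <- function(model, n, seed, keep_latent = TRUE) {
  stop_if_invalid(model)
  stopifnot(n >= 1)
  topo <- topological_order(model)
  sol <- solve_structure(model, topo)
  psi <- sol$psi
  rc <- model$residual_correlations

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  cols <- matrix(NA_real_, n, length(topo), dimnames = list(NULL, topo))
  # exogenous variables with correlated residuals: joint draw via Cholesky
  exo <- topo[vapply(topo, function(v) length(parents_of(model, v)$names) == 0L,
                     logical(1))]
  if (length(exo)) {
    R <- diag(length(exo))
    dimnames(R) <- list(exo, exo)
    if (nrow(rc)) {
      for (j in seq_len(nrow(rc))) {
        if (rc$a[j] %in% exo && rc$b[j] %in% exo) {
          R[rc$a[j], rc$b[j]] <- R[rc$b[j], rc$a[j]] <- rc$rho[j]
        }
      }
    }
    L <- chol(R)
    Z <- matrix(stats::rnorm(n * length(exo)), n, length(exo))
    cols[, exo] <- Z %*% L
  }
  for (v in topo) {
    pa <- parents_of(model, v)
    if (!length(pa$names)) next
    mu <- cols[, pa$names, drop = FALSE] %*% pa$coef
    cols[, v] <- mu + stats::rnorm(n, sd = sqrt(psi[v]))
  }

  keep <- model$variables$name
  if (!keep_latent) keep <- keep[model$variables$observed]
  out <- as.data.frame(cols[, keep, drop = FALSE], check.names = FALSE)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "model") <- model
  class(out) <- c("pgsbias_cohort", class(out))
  out
}

#' Dichotomize a cohort column at an empirical quantile
#'
#' Adds a 0/1 indicator marking the top `top_fraction` of the column by its
#' exact empirical quantile (type-1, so the realized top fraction is as close
#' to the target as the sample allows; ties broken by row order).
#' Re-dichotomizing an existing 0/1 column at 0.5 returns it unchanged.
#'
#' @param cohort data frame.
#' @param column column to cut.
#' @param top_fraction fraction of rows coded 1, in `(0, 1)`.
#' @param name name for the new column (default `<column>_high`).
#' @return the cohort with the indicator column appended (or, for an existing
#'   0/1 column, the indicator reproducing it).
#' @export
dichotomize <- function(cohort, column, top_fraction, name = NULL) {
  stopifnot(column %in% names(cohort), top_fraction > 0, top_fraction < 1)
  x <- cohort[[column]]
  if (length(unique(x)) == 1L) stop("constant column: ", column)
  if (is.null(name)) name <- paste0(column, "_high")
  if (all(x %in% c(0, 1))) {
    cohort[[name]] <- as.integer(x)
    return(cohort)
  }
  cut <- stats::quantile(x, probs = 1 - top_fraction, type = 1, names = FALSE)
  ind <- as.integer(x > cut)
  # exact-quantile ties: admit tied rows in row order until the target count
  target <- floor(top_fraction * length(x))
  short <- target - sum(ind)
  if (short > 0) {
    tied <- which(x == cut)
    ind[tied[seq_len(min(short, length(tied)))]] <- 1L
  }
  cohort[[name]] <- ind
  cohort
}

#' Select a stratum of a cohort (referral / participation selection)
#'
#' Keeps the rows satisfying a rule over 0/1 indicator columns and reports
#' the association between two risk indicators within the selected stratum.
#' The canonical case is certain referral: keep a row when either of two
#' independent binary risks is high. Within the referred stratum the two
#' risks become negatively associated (the both-low cell is empty by
#' construction) — stratifying on a collider.
#'
#' @param cohort data frame with 0/1 columns.
#' @param keep_any character vector of indicator columns; a row is kept when
#'   any of them equals 1 (certain referral). Alternatively supply `keep`, a
#'   logical vector.
#' @param keep optional explicit logical selection vector overriding
#'   `keep_any`.
#' @param report_pair length-2 character vector: the two indicators to
#'   cross-tabulate within the stratum (defaults to `keep_any` when it has
#'   exactly two columns).
#' @return list of class `pgsbias_selection` with the selected `cohort`, the
#'   2x2 `table` of the reported pair within the stratum, their `phi`
#'   coefficient and `odds_ratio`, and `n_selected` / `n_total`.
#' @export
apply_selection <- function(cohort, keep_any = NULL, keep = NULL,
                            report_pair = NULL) {
  if (is.null(keep)) {
    stopifnot(!is.null(keep_any), all(keep_any %in% names(cohort)))
    for (cl in keep_any) {
      if (!all(cohort[[cl]] %in% c(0, 1))) stop("column not 0/1: ", cl)
    }
    keep <- Reduce(`|`, lapply(keep_any, function(cl) cohort[[cl]] == 1))
  }
  sel <- cohort[keep, , drop = FALSE]
  if (!nrow(sel)) stop("empty selection")
  if (is.null(report_pair) && length(keep_any) == 2L) report_pair <- keep_any
  tab <- phi <- or <- NULL
  if (!is.null(report_pair)) {
    a <- factor(sel[[report_pair[1]]], levels = c(0, 1))
    b <- factor(sel[[report_pair[2]]], levels = c(0, 1))
    tab <- table(a, b, dnn = report_pair)
    phi <- phi_coefficient(tab)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    if (!is.finite(or)) or <- if (tab[1, 1] == 0 || tab[2, 2] == 0) 0 else Inf
  }
  structure(list(cohort = sel, table = tab, phi = phi, odds_ratio = or,
                 n_selected = nrow(sel), n_total = nrow(cohort)),
            class = "pgsbias_selection")
}

phi_coefficient <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  num <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
  den <- sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  if (den == 0) return(NA_real_)
  as.numeric(num / den)
}

#' @export
print.pgsbias_selection <- function(x, ...) {
  cat("Selection:", x$n_selected, "of", x$n_total, "rows kept\n")
  if (!is.null(x$table)) {
    print(x$table)
    cat("phi =", format(x$phi, digits = 4),
        " odds ratio =", format(x$odds_ratio, digits = 4), "\n")
  }
  invisible(x)
}

#' Read and write simulated cohorts as TSV
#'
#' @param cohort data frame.
#' @param file path.
#' @export
write_cohort_tsv <- function(cohort, file) {
  utils::write.table(cohort, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
}
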