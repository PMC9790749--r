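#' Standardized linear path models
#'
#' A `path_model` is an acyclic, fully standardized linear structural model:
#' every variable (latent or observed) has total variance 1, every directed
#' path carries a standardized coefficient, and residual variances are derived
#' (never user-set) so that the unit-variance constraint holds. Latent
#' variables follow the convention of being starred (e.g. `"G*"`); observed
#' indicators are unstarred. Correlations between the residuals of exogenous
#' variables ("co-paths", as induced by assortative mating) are supported.
#'
#' @param paths data frame with columns `source`, `target`, `coefficient`:
#'   one row per directed path, standardized coefficients in `[-1, 1]`.
#' @param variables optional character vector of variable names; names that
#'   appear in `paths` are added automatically. Use this to declare isolated
#'   variables.
#' @param latent optional character vector naming the latent variables; by
#'   default any name containing `"*"` is treated as latent.
#' @param residual_correlations optional data frame with columns `a`, `b`,
#'   `rho` giving residual correlations between exogenous variables.
#' @return an object of class `pgsbias_model`.
#' @examples
#' m <- path_model(data.frame(
#'   source = c("G*", "G*", "Y*"),
#'   target = c("Y*", "G", "Y"),
#'   coefficient = c(0.9, sqrt(0.1), sqrt(0.8))))
#' implied_correlations(m)["G", "Y"]
#' @export
path_model <- function(paths, variables = NULL, latent = NULL,
                       residual_correlations = NULL) {
  if (is.null(paths)) {
    paths <- data.frame(source = character(), target = character(),
                        coefficient = numeric())
  }
  paths <- as.data.frame(paths)
  stopifnot(all(c("source", "target", "coefficient") %in% names(paths)))
  paths$source <- as.character(paths$source)
  paths$target <- as.character(paths$target)
  paths$coefficient <- as.numeric(paths$coefficient)

  vars <- unique(c(variables, paths$source, paths$target))
  if (!is.null(residual_correlations)) {
    residual_correlations <- as.data.frame(residual_correlations)
    stopifnot(all(c("a", "b", "rho") %in% names(residual_correlations)))
    residual_correlations$a <- as.character(residual_correlations$a)
    residual_correlations$b <- as.character(residual_correlations$b)
    residual_correlations$rho <- as.numeric(residual_correlations$rho)
    vars <- unique(c(vars, residual_correlations$a, residual_correlations$b))
  } else {
    residual_correlations <- data.frame(a = character(), b = character(),
                                        rho = numeric())
  }
  if (is.null(latent)) latent <- vars[grepl("\\*", vars, fixed = FALSE)]

  structure(
    list(
      variables = data.frame(name = vars,
                             observed = !(vars %in% latent),
                             stringsAsFactors = FALSE),
      paths = paths[, c("source", "target", "coefficient")],
      residual_correlations = residual_correlations[, c("a", "b", "rho")]
    ),
    class = "pgsbias_model"
  )
}

#' @export
print.pgsbias_model <- function(x, ...) {
  cat("Standardized path model:", nrow(x$variables), "variables,",
      nrow(x$paths), "paths\n")
  lat <- x$variables$name[!x$variables$observed]
  if (length(lat)) cat("  latent:", paste(lat, collapse = ", "), "\n")
  if (nrow(x$paths)) {
    cat(paste0("  ", x$paths$source, " -> ", x$paths$target, "  (",
               formatC(x$paths$coefficient, digits = 4, format = "g"), ")",
               collapse = "\n"), "\n")
  }
  if (nrow(x$residual_correlations)) {
    rc <- x$residual_correlations
    cat(paste0("  ", rc$a, " ~~ ", rc$b, "  (rho = ",
               formatC(rc$rho, digits = 4, format = "g"), ")",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

# Kahn's algorithm with lexicographic tie-break so output order is
# deterministic across platforms. Returns NULL if the graph has a cycle.
topological_order <- function(model) {
  vars <- model$variables$name
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (tg in model$paths$target) indeg[tg] <- indeg[tg] + 1L
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg[avail] <- NA_integer_
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    for (tg in model$paths$target[model$paths$source == v]) {
      indeg[tg] <- indeg[tg] - 1L
      if (!is.na(indeg[tg]) && indeg[tg] == 0L) {
        avail <- sort(c(avail, tg))
        indeg[tg] <- NA_integer_
      }
    }
  }
  if (length(order) < length(vars)) NULL else order
}

parents_of <- function(model, v) {
  sel <- model$paths$target == v
  list(names = model$paths$source[sel], coef = model$paths$coefficient[sel])
}

#' Validate a path model
#'
#' Checks the structural invariants every standardized model must satisfy:
#' unique variable names, no self-loops or duplicate paths, coefficients in
#' `[-1, 1]`, acyclicity, residual correlations restricted to exogenous
#' variables, and derived residual variances in `[0, 1]` for every variable.
#' Validation reports; it never raises.
#'
#' @param model a `pgsbias_model`.
#' @return an object of class `pgsbias_validation`: a list with elements
#'   `valid` (logical) and `issues` (character vector naming each failed
#'   invariant and the offending variable or path).
#' @export
validate_model <- function(model) {
  issues <- character(0)
  vars <- model$variables$name
  if (anyDuplicated(vars)) {
    issues <- c(issues, paste0("duplicate variable name: ",
                               paste(unique(vars[duplicated(vars)]), collapse = ", ")))
  }
  p <- model$paths
  if (any(p$source == p$target)) {
    issues <- c(issues, paste0("self-loop on: ",
                               paste(p$source[p$source == p$target], collapse = ", ")))
  }
  key <- paste(p$source, p$target, sep = "\r")
  if (anyDuplicated(key)) {
    issues <- c(issues, paste0("duplicate path: ",
                               paste(gsub("\r", " -> ", unique(key[duplicated(key)])),
                                     collapse = ", ")))
  }
  bad_coef <- abs(p$coefficient) > 1 | !is.finite(p$coefficient)
  if (any(bad_coef)) {
    issues <- c(issues, paste0("coefficient outside [-1, 1] on path ",
                               paste(p$source[bad_coef], "->", p$target[bad_coef],
                                     collapse = ", ")))
  }
  topo <- topological_order(model)
  if (is.null(topo)) issues <- c(issues, "cycle in path graph")

  rc <- model$residual_correlations
  if (nrow(rc)) {
    if (any(rc$a == rc$b)) issues <- c(issues, "residual correlation of a variable with itself")
    if (any(abs(rc$rho) > 1)) issues <- c(issues, "residual correlation outside [-1, 1]")
    endo <- unique(p$target)
    bad <- unique(c(rc$a, rc$b)[c(rc$a, rc$b) %in% endo])
    if (length(bad)) {
      issues <- c(issues, paste0("residual correlation on non-exogenous variable: ",
                                 paste(bad, collapse = ", ")))
    }
  }

  if (!length(issues) && !is.null(topo)) {
    rv <- tryCatch(residual_variances_impl(model, topo), error = function(e) e)
    if (inherits(rv, "error")) {
      issues <- c(issues, conditionMessage(rv))
    } else {
      neg <- names(rv)[rv < -1e-10 | rv > 1 + 1e-10]
      if (length(neg)) {
        issues <- c(issues, paste0("residual variance outside [0, 1] for: ",
                                   paste(neg, collapse = ", ")))
      }
    }
  }
  structure(list(valid = !length(issues), issues = issues),
            class = "pgsbias_validation")
}

#' @export
print.pgsbias_validation <- function(x, ...) {
  if (x$valid) cat("Model valid.\n")
  else cat("Model INVALID:\n", paste0("  - ", x$issues, collapse = "\n"), "\n")
  invisible(x)
}

stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (!v$valid) stop("invalid path model: ", paste(v$issues, collapse = "; "),
                     call. = FALSE)
  invisible(model)
}

# Core recursive solve shared by residual_variances() and
# implied_correlations(): walk the DAG in topological order, accumulate the
# implied covariance among processed variables, and back out each residual
# variance as 1 minus the parent-explained variance.
solve_structure <- function(model, topo) {
  k <- length(topo)
  sigma <- matrix(0, k, k, dimnames = list(topo, topo))
  psi <- stats::setNames(numeric(k), topo)
  rc <- model$residual_correlations
  for (i in seq_len(k)) {
    v <- topo[i]
    pa <- parents_of(model, v)
    if (!length(pa$names)) {
      psi[v] <- 1
      sigma[v, v] <- 1
      if (i > 1 && nrow(rc)) {
        for (j in seq_len(nrow(rc))) {
          other <- if (rc$a[j] == v) rc$b[j] else if (rc$b[j] == v) rc$a[j] else NA
          if (!is.na(other) && other %in% topo[seq_len(i - 1L)]) {
            sigma[v, other] <- sigma[other, v] <- rc$rho[j]
          }
        }
      }
    } else {
      b <- pa$coef
      expl <- drop(t(b) %*% sigma[pa$names, pa$names, drop = FALSE] %*% b)
      res <- 1 - expl
      if (res < -1e-10) {
        stop("negative residual variance for ", v,
             " (parents explain variance ", format(expl), " > 1)", call. = FALSE)
      }
      psi[v] <- max(res, 0)
      if (i > 1) {
        earlier <- topo[seq_len(i - 1L)]
        sigma[v, earlier] <- sigma[earlier, v] <-
          drop(sigma[earlier, pa$names, drop = FALSE] %*% b)
      }
      sigma[v, v] <- 1
    }
  }
  list(sigma = sigma, psi = psi)
}

residual_variances_impl <- function(model, topo) {
  solve_structure(model, topo)$psi
}

#' Residual variances of a standardized path model
#'
#' For each variable, the residual variance is 1 minus the variance explained
#' by its parents (including covariance terms among correlated parents). For
#' an exogenous variable this is 1. A valid standardized model has all
#' residual variances in `[0, 1]`.
#'
#' @inheritParams validate_model
#' @return named numeric vector, in the model's declared variable order.
#' @export
residual_variances <- function(model) {
  stop_if_invalid(model)
  topo <- topological_order(model)
  residual_variances_impl(model, topo)[model$variables$name]
}

#' Model-implied correlation matrix
#'
#' Computes the exact correlation matrix implied by a standardized path model,
#' by solving the linear structural system in topological order with residual
#' variances chosen to force unit total variance for every variable. Residual
#' correlations between exogenous variables contribute cross-covariances.
#'
#' The default recursive solve is cross-checked in the test suite against the
#' reduced-form matrix solution `(I - B)^-1 Psi (I - B)^-T`, which is also
#' available via `method = "matrix"`.
#'
#' @inheritParams validate_model
#' @param method `"recursive"` (topological-order solve, default) or
#'   `"matrix"` (reduced-form matrix inversion).
#' @return symmetric unit-diagonal correlation matrix with dimnames in the
#'   model's declared variable order.
#' @export
implied_correlations <- function(model, method = c("recursive", "matrix")) {
  method <- match.arg(method)
  stop_if_invalid(model)
  topo <- topological_order(model)
  if (method == "recursive") {
    sigma <- solve_structure(model, topo)$sigma
  } else {
    k <- length(topo)
    B <- matrix(0, k, k, dimnames = list(topo, topo))
    for (i in seq_len(nrow(model$paths))) {
      B[model$paths$target[i], model$paths$source[i]] <- model$paths$coefficient[i]
    }
    psi <- solve_structure(model, topo)$psi
    Psi <- diag(psi, nrow = k)
    dimnames(Psi) <- list(topo, topo)
    rc <- model$residual_correlations
    if (nrow(rc)) {
      for (j in seq_len(nrow(rc))) {
        Psi[rc$a[j], rc$b[j]] <- Psi[rc$b[j], rc$a[j]] <-
          rc$rho[j] * sqrt(psi[rc$a[j]] * psi[rc$b[j]])
      }
    }
    IB <- solve(diag(k) - B)
    sigma <- IB %*% Psi %*% t(IB)
    dimnames(sigma) <- list(topo, topo)
  }
  ord <- model$variables$name
  sigma <- (sigma + t(sigma)) / 2
  sigma[ord, ord, drop = FALSE]
}

#' Read and write path models as YAML scenario documents
#'
#' Models serialize to a structured text document (one model per file) holding
#' the variable list, paths, and residual correlations; the round trip is
#' lossless.
#'
#' @param model a `pgsbias_model`.
#' @param file path to write to / read from.
#' @return `read_path_model` returns a `pgsbias_model`; `write_path_model`
#'   returns `file` invisibly.
#' @export
write_path_model <- function(model, file) {
  doc <- list(
    variables = lapply(seq_len(nrow(model$variables)), function(i) {
      list(name = model$variables$name[i],
           observed = model$variables$observed[i])
    }),
    paths = lapply(seq_len(nrow(model$paths)), function(i) {
      list(source = model$paths$source[i],
           target = model$paths$target[i],
           coefficient = model$paths$coefficient[i])
    }),
    residual_correlations = lapply(seq_len(nrow(model$residual_correlations)),
      function(i) {
        list(a = model$residual_correlations$a[i],
             b = model$residual_correlations$b[i],
             rho = model$residual_correlations$rho[i])
      })
  )
  writeLines(yaml::as.yaml(doc, precision = 17L), file)
  invisible(file)
}

#' @rdname write_path_model
#' @export
read_path_model <- function(file) {
  doc <- yaml::read_yaml(file)
  vars <- vapply(doc$variables, `[[`, character(1), "name")
  obs <- vapply(doc$variables, `[[`, logical(1), "observed")
  paths <- if (length(doc$paths)) {
    data.frame(
      source = vapply(doc$paths, `[[`, character(1), "source"),
      target = vapply(doc$paths, `[[`, character(1), "target"),
      coefficient = vapply(doc$paths, function(p) as.numeric(p$coefficient), numeric(1)),
      stringsAsFactors = FALSE)
  } else NULL
  rc <- if (length(doc$residual_correlations)) {
    data.frame(
      a = vapply(doc$residual_correlations, `[[`, character(1), "a"),
      b = vapply(doc$residual_correlations, `[[`, character(1), "b"),
      rho = vapply(doc$residual_correlations, function(p) as.numeric(p$rho), numeric(1)),
      stringsAsFactors = FALSE)
  } else NULL
  path_model(paths, variables = vars, latent = vars[!obs],
             residual_correlations = rc)
}

#' Export a correlation matrix as TSV
#'
#' Writes a correlation matrix with a header row of variable names and a
#' leading `variable` column, so the file round-trips through any delimited
#' reader.
#'
#' @param corr correlation matrix with dimnames.
#' @param file output path.
#' @export
write_correlations_tsv <- function(corr, file) {
  df <- data.frame(variable = rownames(corr), corr, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
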