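#' Simulate a generation of parents, with optional assortative mating
#'
#' Draws phased haplotypes for `n` mother-father pairs at `L` unlinked
#' biallelic loci (allele `1` frequency `freqs[l]` per locus, Hardy-Weinberg
#' within each haplotype). Under random mating (`spousal_corr = 0`) couples
#' are formed at random, so spousal polygenic scores are uncorrelated in
#' expectation. With `spousal_corr > 0`, couples are formed by noisy
#' rank-matching on a mating phenotype (the true polygenic score plus
#' Gaussian noise): the matching noise is tuned by bisection until the
#' realized spousal phenotype correlation is within `tol` of the target.
#'
#' @param L number of loci.
#' @param n number of couples.
#' @param freqs allele frequencies, length `L` (or scalar, recycled), each in
#'   `(0, 1)`.
#' @param spousal_corr target spousal correlation of the mating phenotype,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @param weights per-locus polygenic score weights (default standard normal
#'   draws); used for the mating phenotype and stored for downstream scoring.
#' @param tol calibration tolerance on the realized spousal correlation.
#' @param max_iter bisection iterations before declaring the target
#'   unattainable.
#' @return list of class `pgsbias_parents` with elements `mother` and
#'   `father` (each a list of two `n x L` 0/1 haplotype matrices `hap1`,
#'   `hap2`), `freqs`, `weights`, and `realized_spousal_corr`.
#' @export
simulate_parents <- function(L, n, freqs, spousal_corr = 0, seed = 1,
                             weights = NULL, tol = 0.02, max_iter = 50) {
  stopifnot(L >= 1, n >= 2, spousal_corr >= 0, spousal_corr < 1)
  freqs <- rep_len(as.numeric(freqs), L)
  if (any(freqs <= 0 | freqs >= 1)) stop("allele frequencies must lie in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  if (is.null(weights)) weights <- stats::rnorm(L)

  draw_haps <- function(n) {
    list(hap1 = matrix(stats::rbinom(n * L, 1L, rep(freqs, each = n)), n, L),
         hap2 = matrix(stats::rbinom(n * L, 1L, rep(freqs, each = n)), n, L))
  }
  mothers <- draw_haps(n)
  fathers <- draw_haps(n)
  realized <- 0
  if (spousal_corr > 0) {
    score <- function(h) pgs_from_counts(h$hap1 + h$hap2, weights, freqs)
    sm <- score(mothers)
    sf <- score(fathers)
    # bisection on the matching-noise SD: sigma = 0 gives near-perfect rank
    # matching, large sigma approaches random pairing
    lo <- 0; hi <- 50
    ord_m <- order(sm)
    best <- NULL
    for (it in seq_len(max_iter)) {
      sigma <- (lo + hi) / 2
      perm <- order(sf + stats::rnorm(n, sd = sigma))
      r <- stats::cor(sm[ord_m], sf[perm])
      if (is.null(best) || abs(r - spousal_corr) < abs(best$r - spousal_corr)) {
        best <- list(perm = perm, r = r)
      }
      if (abs(r - spousal_corr) <= tol) break
      if (r > spousal_corr) lo <- sigma else hi <- sigma
    }
    if (abs(best$r - spousal_corr) > tol) {
      stop("could not reach spousal correlation ", spousal_corr,
           " within ", max_iter, " iterations (best: ", format(best$r), ")")
    }
    reorder <- function(h, idx) list(hap1 = h$hap1[idx, , drop = FALSE],
                                     hap2 = h$hap2[idx, , drop = FALSE])
    mothers <- reorder(mothers, ord_m)
    fathers <- reorder(fathers, best$perm)
    realized <- best$r
  }
  structure(list(mother = mothers, father = fathers, freqs = freqs,
                 weights = weights, realized_spousal_corr = realized,
                 n = n, L = L),
            class = "pgsbias_parents")
}

# Per-count standardized weighted score on the theoretical scale: counts are
# centered by 2f and scaled by sqrt(2f(1-f)); the weighted sum is divided by
# sqrt(sum(w^2)) so the score has unit variance under Hardy-Weinberg and
# linkage equilibrium. Using the theoretical (not sample) scale keeps the
# transmitted and non-transmitted half-scores exactly additive.
pgs_from_counts <- function(counts, weights, freqs) {
  drop(sweep(counts, 2, 2 * freqs) %*% (weights / sqrt(2 * freqs * (1 - freqs)))) /
    sqrt(sum(weights^2))
}

# Half-score from a single haplotype (one allele per locus), centered by f.
pgs_from_haplotype <- function(hap, weights, freqs) {
  drop(sweep(hap, 2, freqs) %*% (weights / sqrt(2 * freqs * (1 - freqs)))) /
    sqrt(sum(weights^2))
}

#' Mendelian transmission from parent couples to one child each
#'
#' Each parent transmits, independently per locus, one of their two
#' haplotypes with probability 1/2; the non-transmitted allele is recorded.
#' The child's genotype at every locus is the sum of the transmitted
#' maternal and paternal alleles, and the parental true score splits exactly
#' into transmitted plus non-transmitted half-scores.
#'
#' @param parents a `pgsbias_parents`.
#' @param seed integer seed.
#' @return list of class `pgsbias_trios` with haplotype matrices
#'   (`child_mat`, `child_pat`, `mat_nt`, `pat_nt` — transmitted and
#'   non-transmitted maternal/paternal alleles), the parent object, and a
#'   data frame `scores` with per-trio true scores `G_M`, `G_F`, `G_C` and
#'   half-scores `G_Mt`, `G_Mnt`, `G_Ft`, `G_Fnt` (all on the standardized
#'   per-count scale, so `G_Mt + G_Mnt = G_M`).
#' @export
mate_and_transmit <- function(parents, seed = 1) {
  stopifnot(inherits(parents, "pgsbias_parents"))
  n <- parents$n; L <- parents$L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  pick_m <- matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
  pick_f <- matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
  transmit <- function(h, pick) h$hap1 * (1L - pick) + h$hap2 * pick
  child_mat <- transmit(parents$mother, pick_m)
  mat_nt <- transmit(parents$mother, 1L - pick_m)
  child_pat <- transmit(parents$father, pick_f)
  pat_nt <- transmit(parents$father, 1L - pick_f)

  w <- parents$weights; f <- parents$freqs
  scores <- data.frame(
    G_M = pgs_from_counts(parents$mother$hap1 + parents$mother$hap2, w, f),
    G_F = pgs_from_counts(parents$father$hap1 + parents$father$hap2, w, f),
    G_C = pgs_from_counts(child_mat + child_pat, w, f),
    G_Mt = pgs_from_haplotype(child_mat, w, f),
    G_Mnt = pgs_from_haplotype(mat_nt, w, f),
    G_Ft = pgs_from_haplotype(child_pat, w, f),
    G_Fnt = pgs_from_haplotype(pat_nt, w, f))
  structure(list(parents = parents, child_mat = child_mat,
                 child_pat = child_pat, mat_nt = mat_nt, pat_nt = pat_nt,
                 scores = scores, n = n, L = L),
            class = "pgsbias_trios")
}

#' Polygenic score from a genotype matrix, with calibrated estimation noise
#'
#' Computes the standardized weighted score (counts centered by `2f` and
#' scaled by `sqrt(2f(1-f))`). GWAS weight estimation error is emulated by
#' perturbing the weight vector: the perturbation is drawn orthogonal to the
#' true weights and scaled so that the population squared correlation
#' between true and observed scores equals `reliability` exactly.
#'
#' @param counts `n x L` allele-count matrix (values 0/1/2).
#' @param weights true per-locus weights.
#' @param freqs allele frequencies.
#' @param reliability target squared correlation between true and observed
#'   score, in `(0, 1]`; `1` returns the true score unchanged.
#' @param seed integer seed for the perturbation draw.
#' @return list with `true` and `observed` score vectors and the realized
#'   sample `reliability_hat`.
#' @export
compute_pgs <- function(counts, weights, freqs, reliability = 1, seed = 1) {
  stopifnot(length(weights) == ncol(counts), reliability > 0, reliability <= 1)
  freqs <- rep_len(freqs, ncol(counts))
  if (sum(weights^2) == 0) stop("zero-variance score: all weights are zero")
  true <- pgs_from_counts(counts, weights, freqs)
  if (reliability == 1) {
    return(list(true = true, observed = true, reliability_hat = 1))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  delta <- stats::rnorm(length(weights))
  delta <- delta - sum(delta * weights) / sum(weights^2) * weights
  delta <- delta * sqrt((1 - reliability) / reliability * sum(weights^2) /
                          sum(delta^2))
  observed <- pgs_from_counts(counts, weights + delta, freqs) /
    sqrt(sum((weights + delta)^2) / sum(weights^2))
  list(true = true, observed = observed,
       reliability_hat = stats::cor(true, observed)^2)
}

#' Configuration of intergenerational effects on the child outcome
#'
#' Bundles the standardized path strengths of the family phenotype model:
#' parental genetics shape the parental environment
#' (`parent_env_m`, `parent_env_f`), the child's genetics may evoke the
#' parental environment (`evocative_m`, `evocative_f`), the parental
#' environments affect the child outcome (`nurture_m`, `nurture_f` — genetic
#' nurture when combined with the parental-genetics paths), and the child's
#' own genetics affect the outcome directly (`individual_effect`).
#'
#' @param individual_effect standardized effect of the child's true score on
#'   the outcome.
#' @param nurture_m,nurture_f standardized effects of the maternal/paternal
#'   environment on the child outcome.
#' @param parent_env_m,parent_env_f standardized effects of the parental true
#'   score on the own environment.
#' @param evocative_m,evocative_f standardized evocative effects of the child
#'   score on each parental environment.
#' @return list of class `pgsbias_family_config`.
#' @export
family_effect_config <- function(individual_effect = 0,
                                 nurture_m = 0, nurture_f = 0,
                                 parent_env_m = 0.5, parent_env_f = 0.5,
                                 evocative_m = 0, evocative_f = 0) {
  structure(list(individual_effect = individual_effect,
                 nurture_m = nurture_m, nurture_f = nurture_f,
                 parent_env_m = parent_env_m, parent_env_f = parent_env_f,
                 evocative_m = evocative_m, evocative_f = evocative_f),
            class = "pgsbias_family_config")
}

#' Generate parental environments and the child outcome for trios
#'
#' Realizes the intergenerational phenotype model on a simulated trio
#' cohort: each parental environment is a linear combination of the parental
#' true score (and, if configured, an evocative path from the child's true
#' score) plus Gaussian noise; the child outcome combines the direct
#' (individual) genetic effect and the two environmental (nurture) paths.
#' Every generated variable is standardized to unit variance using the
#' empirical covariance of its inputs, so the configured coefficients are
#' standardized paths; a configuration whose systematic part already exceeds
#' unit variance is rejected.
#'
#' @param trios a `pgsbias_trios`.
#' @param config a `pgsbias_family_config`.
#' @param seed integer seed for the noise draws.
#' @return the `pgsbias_trios` with columns `E_M`, `E_F`, `Y_C` added to
#'   `$scores`.
#' @export
simulate_family_phenotypes <- function(trios, config, seed = 1) {
  stopifnot(inherits(trios, "pgsbias_trios"),
            inherits(config, "pgsbias_family_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sc <- trios$scores
  n <- nrow(sc)
  zs <- function(x) (x - mean(x)) / stats::sd(x)

  standardized_combo <- function(parts, coefs, label) {
    keep <- coefs != 0
    sys <- if (any(keep)) {
      as.matrix(as.data.frame(parts)[, keep, drop = FALSE]) %*% coefs[keep]
    } else matrix(0, n, 1)
    v <- if (any(keep)) stats::var(drop(sys)) else 0
    if (v > 1 + 1e-8) {
      stop("invalid variance decomposition for ", label,
           ": systematic variance ", format(v), " exceeds 1")
    }
    drop(sys) + stats::rnorm(n, sd = sqrt(max(1 - v, 0)))
  }

  zgm <- zs(sc$G_M); zgf <- zs(sc$G_F); zgc <- zs(sc$G_C)
  e_m <- standardized_combo(list(zgm, zgc),
                            c(config$parent_env_m, config$evocative_m), "E_M")
  e_f <- standardized_combo(list(zgf, zgc),
                            c(config$parent_env_f, config$evocative_f), "E_F")
  y_c <- standardized_combo(list(zgc, zs(e_m), zs(e_f)),
                            c(config$individual_effect,
                              config$nurture_m, config$nurture_f), "Y_C")
  trios$scores$E_M <- e_m
  trios$scores$E_F <- e_f
  trios$scores$Y_C <- y_c
  trios$config <- config
  trios
}

#' Transmitted and non-transmitted score regressions on a trio cohort
#'
#' Fits the three regressions that separate individual from familial genetic
#' effects: (a) the child outcome on the child score alone (the population
#' polygenic score association, which absorbs genetic nurture), (b) the
#' child outcome on child plus both parental scores (the within-family
#' adjusted estimate of the individual effect), and (c) the child outcome on
#' the two non-transmitted parental half-scores alone (a pure familial
#' signal: non-transmitted alleles can only act through the environment).
#' Bootstrap standard errors are attached to every coefficient.
#'
#' @param trios a `pgsbias_trios` with phenotypes attached.
#' @param n_boot bootstrap resamples for the standard errors.
#' @param seed integer seed for the bootstrap.
#' @return list of class `pgsbias_nurture` with data frames `child_only`,
#'   `child_adjusted`, `non_transmitted` (columns `term`, `estimate`, `se`).
#' @export
estimate_nurture <- function(trios, n_boot = 200, seed = 1) {
  sc <- trios$scores
  if (is.null(sc$Y_C)) stop("run simulate_family_phenotypes() first")
  specs <- list(child_only = c("G_C"),
                child_adjusted = c("G_C", "G_M", "G_F"),
                non_transmitted = c("G_Mnt", "G_Fnt"))
  fit_one <- function(d, preds) fit_ols(d, "Y_C", preds)$coefficients
  point <- lapply(specs, fit_one, d = sc)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  boots <- lapply(specs, function(p) matrix(NA_real_, n_boot, length(p)))
  n <- nrow(sc)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- sc[idx, , drop = FALSE]
    for (k in names(specs)) {
      est <- tryCatch(fit_one(d, specs[[k]]), error = function(e) NULL)
      if (!is.null(est)) boots[[k]][b, ] <- est
    }
  }
  out <- lapply(names(specs), function(k) {
    data.frame(term = specs[[k]],
               estimate = as.numeric(point[[k]]),
               se = apply(boots[[k]], 2, stats::sd, na.rm = TRUE))
  })
  names(out) <- names(specs)
  structure(out, class = "pgsbias_nurture")
}

#' @export
print.pgsbias_nurture <- function(x, ...) {
  for (k in names(x)) {
    cat(k, ":\n", sep = "")
    print(x[[k]], row.names = FALSE)
  }
  invisible(x)
}

#' Two-subpopulation stratification scenario
#'
#' Simulates two subpopulations whose allele frequencies differ by
#' `delta_freq` and whose outcome means differ by `outcome_offset`, with an
#' optional true individual genetic effect. Scores are standardized against
#' the pooled allele frequencies, as an analyst blind to structure would do.
#' With positive frequency and outcome offsets and no true effect, the score
#' picks up ancestry and shows a spurious association with the outcome that
#' adjusting for the subpopulation label removes.
#'
#' @param delta_freq per-locus allele-frequency difference between the two
#'   subpopulations.
#' @param outcome_offset difference in outcome means (in outcome SD units of
#'   the residual scale).
#' @param n_per_pop individuals per subpopulation.
#' @param seed integer seed.
#' @param L number of loci.
#' @param true_effect standardized effect of the true score on the outcome
#'   within each subpopulation.
#' @return list of class `pgsbias_stratification` with `unadjusted` and
#'   `adjusted` score coefficients (the latter from outcome ~ score + label)
#'   and the simulated `data`.
#' @export
stratification_scenario <- function(delta_freq, outcome_offset, n_per_pop,
                                    seed = 1, L = 500, true_effect = 0) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  base <- stats::runif(L, 0.2, 0.8)
  f1 <- base - delta_freq / 2
  f2 <- base + delta_freq / 2
  if (any(f1 <= 0 | f1 >= 1 | f2 <= 0 | f2 >= 1)) {
    stop("allele frequencies leave (0, 1) after applying delta_freq")
  }
  # positive weights emulate a GWAS confounded in the direction of the
  # frequency shift (the classic chopstick situation)
  w <- stats::runif(L, 0.2, 1)
  geno <- function(f, n) {
    matrix(stats::rbinom(n * L, 2L, rep(f, each = n)), n, L)
  }
  g1 <- geno(f1, n_per_pop)
  g2 <- geno(f2, n_per_pop)
  pooled_f <- (f1 + f2) / 2
  score <- pgs_from_counts(rbind(g1, g2), w, pooled_f)
  label <- rep(c(0, 1), each = n_per_pop)
  zsc <- (score - mean(score)) / stats::sd(score)
  y <- true_effect * zsc + outcome_offset * label +
    stats::rnorm(2 * n_per_pop, sd = sqrt(max(1 - true_effect^2, 0.05)))
  d <- data.frame(G = score, A = label, Y = y)
  unadj <- fit_ols(d, "Y", "G")$coefficients[["G"]]
  adj <- fit_ols(d, "Y", c("G", "A"))$coefficients[["G"]]
  structure(list(unadjusted = unadj, adjusted = adj, true_effect = true_effect,
                 data = d),
            class = "pgsbias_stratification")
}

#' Write a trio cohort's scores, environments, and outcome as TSV
#'
#' @param trios a `pgsbias_trios`.
#' @param file output path.
#' @export
write_trios_tsv <- function(trios, file) {
  utils::write.table(trios$scores, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
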