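#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the
#' probability of each possible heterozygote count is computed under the
#' Hardy-Weinberg null (all distinct orderings of alleles into genotypes
#' equally likely), and the p-value is the total mass of outcomes whose
#' probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return The exact p-value; a monomorphic sample returns 1.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0, n_AA + n_Aa + n_aa > 0)
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa            # minor-side allele count
  n_A <- 2 * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) return(1)
  rare <- min(n_a, n_A)
  # P(het = h | allele counts) = n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)!
  # evaluated in log space for all h with the parity of the rare count
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    aa <- (rare - h) / 2
    AA <- n - aa - h
    lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
      h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hs == n_Aa]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Build a genetic risk score model
#'
#' A risk score model is a set of variants with log-odds-ratio weights,
#' split into SNP terms (dosage coded 0/1/2) and HLA-DRB1 allele terms
#' (indicator counts 0/1/2 summing to at most 2 per subject). The three
#' model kinds mirror the study design: `"hla"` uses the HLA terms only,
#' `"nonhla"` the SNP terms only, and `"integrative"` both.
#'
#' @param snp_or Named vector of per-allele odds ratios for SNPs.
#' @param hla_or Named vector of per-allele odds ratios for HLA-DRB1
#'   alleles.
#' @param model_kind One of `"hla"`, `"nonhla"`, `"integrative"`.
#' @return A list of class `risk_score_model` with elements `weights`
#'   (log ORs actually used), `snp_variants`, `hla_variants`,
#'   `model_kind`.
#' @export
risk_score_model <- function(snp_or = numeric(), hla_or = numeric(),
                             model_kind = c("integrative", "hla", "nonhla")) {
  model_kind <- match.arg(model_kind)
  snp_w <- log(snp_or)
  hla_w <- log(hla_or)
  stopifnot(all(is.finite(snp_w)), all(is.finite(hla_w)))
  weights <- switch(model_kind,
                    hla = hla_w,
                    nonhla = snp_w,
                    integrative = c(snp_w, hla_w))
  structure(list(weights = weights,
                 snp_variants = if (model_kind == "hla") character()
                                else names(snp_or),
                 hla_variants = if (model_kind == "nonhla") character()
                                else names(hla_or),
                 model_kind = model_kind),
            class = "risk_score_model")
}

#' Genetic risk score of subjects
#'
#' The score of a subject is the sum over model variants of the number of
#' risk alleles carried times the log odds ratio of the variant:
#' SNP dosages and HLA-DRB1 indicator counts both enter as 0/1/2 counts.
#'
#' @param model A [risk_score_model()].
#' @param genotypes Data frame with one column per model variant (plus
#'   any others, ignored) and one row per subject.
#' @return Numeric vector of scores, one per subject.
#' @export
compute_risk_score <- function(model, genotypes) {
  vars <- names(model$weights)
  missing_cols <- setdiff(vars, names(genotypes))
  if (length(missing_cols)) {
    stop("genotype table lacks model variant(s): ",
         paste(missing_cols, collapse = ", "))
  }
  g <- as.matrix(genotypes[, vars, drop = FALSE])
  if (anyNA(g)) {
    bad <- vars[colSums(is.na(g)) > 0]
    stop("missing genotypes for variant(s): ", paste(bad, collapse = ", "),
         "; exclude incomplete subjects first (see complete_cases)")
  }
  drop(g %*% model$weights)
}

#' Restrict a genotype table to subjects complete for a model
#'
#' Complete-case policy: subjects missing any genotype among the model's
#' variants are removed before scoring (no imputation).
#'
#' @inheritParams compute_risk_score
#' @return The genotype table restricted to complete subjects.
#' @export
complete_cases <- function(model, genotypes) {
  vars <- names(model$weights)
  keep <- stats::complete.cases(genotypes[, vars, drop = FALSE])
  genotypes[keep, , drop = FALSE]
}

#' Maximum-likelihood logistic regression with AIC
#'
#' Thin wrapper around the iteratively reweighted least squares fit of
#' `stats::glm` that enforces the contracts needed here: it errors on
#' complete separation and non-convergence instead of returning a
#' degenerate fit, and reports the log-likelihood and AIC.
#'
#' @param predictors Data frame or matrix of predictors (columns named).
#' @param status 0/1 disease status vector.
#' @param max_iter Maximum IRLS iterations.
#' @return A list with `coefficients`, `log_likelihood`, `aic`, `fit`
#'   (the underlying `glm` object).
#' @export
fit_logistic <- function(predictors, status, max_iter = 100) {
  status <- as.integer(status)
  stopifnot(all(status %in% c(0L, 1L)))
  if (!any(status == 1L) || !any(status == 0L)) {
    stop("need at least one case and one control")
  }
  dat <- as.data.frame(predictors)
  dat$.status <- status
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.status ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8,
                                            maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  fv <- stats::fitted(fit)
  separated <- max(abs(stats::coef(fit)), na.rm = TRUE) > 10 &&
    all(pmin(fv, 1 - fv) < 1e-6) && all((fv > 0.5) == (status == 1L))
  if (separated || (sep_warned && max(abs(stats::coef(fit)), na.rm = TRUE) > 10)) {
    stop("separation: the logistic likelihood has no finite maximum")
  }
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iter, " iterations")
  }
  ll <- as.numeric(stats::logLik(fit))
  list(coefficients = stats::coef(fit), log_likelihood = ll,
       aic = -2 * ll + 2 * length(stats::coef(fit)), fit = fit)
}

# Midrank placements used by the DeLong variance estimator.
delong_placements <- function(cases, controls) {
  m <- length(cases)
  n <- length(controls)
  all_r <- rank(c(cases, controls), ties.method = "average")
  rc <- rank(cases, ties.method = "average")
  rk <- rank(controls, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rc) / n            # P(case > control) per case
  v01 <- 1 - (all_r[m + seq_len(n)] - rk) / m    # per control
  auc <- sum(all_r[seq_len(m)]) / (m * n) - (m + 1) / (2 * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney estimator: the probability that a randomly
#' chosen case scores higher than a randomly chosen control, ties counted
#' one half. The 95% confidence interval uses the DeLong placement
#' variance. The curve sweeps all distinct score thresholds.
#'
#' @param scores_case,scores_control Risk scores of cases and controls.
#' @param conf_level Confidence level of the interval.
#' @return A list of class `roc_result` with `auc`, `ci_low`, `ci_high`,
#'   `se`, `curve` (data frame of `fpr`, `tpr` from (0,0) to (1,1)),
#'   `n_case`, `n_control`.
#' @examples
#' empirical_auc(c(2, 3), c(1, 2))
#' @export
empirical_auc <- function(scores_case, scores_control, conf_level = 0.95) {
  stopifnot(length(scores_case) > 0, length(scores_control) > 0)
  pl <- delong_placements(scores_case, scores_control)
  v <- if (pl$m > 1 && pl$n > 1) {
    stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  } else {
    NA_real_
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  thr <- sort(unique(c(scores_case, scores_control)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_case >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores_control >= t), 0)
  curve <- unique(data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
  structure(list(auc = pl$auc,
                 ci_low = if (is.na(se)) NA_real_
                          else max(0, pl$auc - zq * se),
                 ci_high = if (is.na(se)) NA_real_
                           else min(1, pl$auc + zq * se),
                 se = se, curve = curve,
                 n_case = pl$m, n_control = pl$n),
            class = "roc_result")
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of the AUCs of two scoring models evaluated on the
#' same subjects, using the covariance of the DeLong placements.
#'
#' @param scores_a,scores_b Scores of every subject under model A and B
#'   (same subjects, same order).
#' @param status 0/1 disease status of the subjects.
#' @return A list with `auc_a`, `auc_b`, `delta_auc`, `z`, `p`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, status) {
  status <- as.integer(status)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(status)) {
    stop("subject sets differ between the two models")
  }
  case <- status == 1L
  pa <- delong_placements(scores_a[case], scores_a[!case])
  pb <- delong_placements(scores_b[case], scores_b[!case])
  d <- pa$auc - pb$auc
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  if (v <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = d,
                z = 0, p = 1))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = d,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Gaussian kernel density of risk scores
#'
#' @param scores Numeric scores (at least two, non-degenerate).
#' @param bandwidth Either `"silverman"` (the default rule of thumb) or a
#'   positive number.
#' @param n_grid Number of evenly spaced grid points.
#' @return Data frame with columns `x` and `density`.
#' @export
score_density <- function(scores, bandwidth = "silverman", n_grid = 512) {
  stopifnot(length(scores) >= 2)
  if (stats::var(scores) == 0) stop("degenerate scores: zero variance")
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(scores)
        else as.numeric(bandwidth)
  d <- stats::density(scores, bw = bw, kernel = "gaussian", n = n_grid)
  data.frame(x = d$x, density = d$y)
}

#' Do case and control score distributions differ?
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test by default; a
#' permutation test on the rank-sum statistic is available as a check
#' since the original analysis does not name its test.
#'
#' @param scores_case,scores_control Scores per group.
#' @param method `"wilcoxon"` or `"permutation"`.
#' @param n_perm Permutations when `method = "permutation"`.
#' @return The two-sided p-value.
#' @export
score_distribution_test <- function(scores_case, scores_control,
                                    method = c("wilcoxon", "permutation"),
                                    n_perm = 10000) {
  method <- match.arg(method)
  stopifnot(length(scores_case) > 0, length(scores_control) > 0)
  if (method == "wilcoxon") {
    stats::wilcox.test(scores_case, scores_control, exact = FALSE,
                       correct = FALSE)$p.value
  } else {
    m <- length(scores_case)
    pooled <- c(scores_case, scores_control)
    r <- rank(pooled)
    obs <- abs(sum(r[seq_len(m)]) - m * (length(pooled) + 1) / 2)
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pooled), m)
      abs(sum(r[idx]) - m * (length(pooled) + 1) / 2)
    })
    (1 + sum(perm >= obs)) / (n_perm + 1)
  }
}
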