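#' Per-locus genotype distributions under the multiplicative model
#'
#' Every locus is assumed to be in Hardy-Weinberg equilibrium and in
#' linkage equilibrium with all others. A diallelic SNP with risk allele
#' frequency p therefore has three genotype states with probabilities
#' `((1-p)^2, 2p(1-p), p^2)` and risk multipliers `(1, OR, OR^2)`. A
#' multi-allelic HLA block with risk alleles of frequencies `f_j` and
#' odds ratios `o_j` (plus a pooled non-risk "other" allele of frequency
#' `1 - sum(f_j)`) enumerates all unordered allele pairs; the multiplier
#' of a genotype is the product of the odds ratios of the risk alleles
#' carried. Six risk alleles plus the pooled other allele give 28
#' genotype states.
#'
#' @param snps Data frame with columns `or` and `raf` (one row per SNP);
#'   may be `NULL` or empty.
#' @param hla Data frame with columns `or` and `freq` (one row per HLA
#'   risk allele); may be `NULL` or empty.
#' @return A list of locus distributions, each a list with numeric
#'   vectors `multiplier` and `prob` (probabilities summing to 1).
#' @export
genotype_locus_distributions <- function(snps = NULL, hla = NULL) {
  out <- list()
  if (!is.null(snps) && nrow(snps)) {
    stopifnot(all(snps$raf > 0), all(snps$raf < 1), all(snps$or > 0))
    for (i in seq_len(nrow(snps))) {
      p <- snps$raf[i]
      or <- snps$or[i]
      out[[length(out) + 1]] <- list(
        multiplier = c(1, or, or^2),
        prob = c((1 - p)^2, 2 * p * (1 - p), p^2)
      )
    }
  }
  if (!is.null(hla) && nrow(hla)) {
    stopifnot(all(hla$freq > 0), all(hla$or > 0))
    f <- hla$freq
    if (sum(f) > 1) stop("HLA allele frequencies sum above 1")
    freqs <- c(f, 1 - sum(f))
    ors <- c(hla$or, 1)
    k <- length(freqs)
    mult <- numeric(0)
    prob <- numeric(0)
    for (i in seq_len(k)) {
      for (j in i:k) {
        mult <- c(mult, ors[i] * ors[j])
        prob <- c(prob, if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j])
      }
    }
    out[[length(out) + 1]] <- list(multiplier = mult, prob = prob)
  }
  out
}

# Convolve independent per-locus multiplier distributions in log space.
# Values are merged at relative tolerance 1e-9; when the support would
# exceed max_support the log-risk axis is compressed onto a
# probability-weighted grid (compress = TRUE) or an error is raised.
convolve_loci <- function(loci, max_support = 16384L, compress = TRUE) {
  logv <- 0
  prob <- 1
  for (locus in loci) {
    lm <- log(locus$multiplier)
    logv <- as.vector(outer(logv, lm, `+`))
    prob <- as.vector(outer(prob, locus$prob))
    keep <- prob > 0      # binomial tails can underflow to exact zero
    logv <- logv[keep]
    prob <- prob[keep]
    o <- order(logv)
    logv <- logv[o]
    prob <- prob[o]
    merged <- merge_support(logv, prob)
    logv <- merged$logv
    prob <- merged$prob
    if (length(logv) > max_support) {
      if (!compress) {
        stop("risk-distribution support exceeds the bin budget (",
             max_support, "); enable compression or use Monte Carlo")
      }
      comp <- compress_support(logv, prob, max_support)
      logv <- comp$logv
      prob <- comp$prob
    }
  }
  list(logv = logv, prob = prob)
}

# Merge sorted log-values equal within relative tolerance 1e-9.
merge_support <- function(logv, prob, rel_tol = 1e-9) {
  if (length(logv) <= 1) return(list(logv = logv, prob = prob))
  tol <- rel_tol * pmax(1, abs(logv[-length(logv)]))
  g <- cumsum(c(TRUE, diff(logv) > tol))
  psum <- as.numeric(rowsum(prob, g))
  vsum <- as.numeric(rowsum(logv * prob, g))
  list(logv = vsum / psum, prob = psum)
}

# Probability-weighted grid compression of the log-risk axis.
compress_support <- function(logv, prob, n_bins) {
  rng <- range(logv)
  if (diff(rng) == 0) return(list(logv = rng[1], prob = sum(prob)))
  bin <- pmin(n_bins, 1L + floor((logv - rng[1]) / diff(rng) * n_bins))
  w <- as.numeric(rowsum(prob, bin))
  v <- as.numeric(rowsum(logv * prob, bin)) / w
  list(logv = v, prob = w)
}

#' Calibrate the background risk to the disease prevalence
#'
#' The disease risk of a multilocus genotype X is `b` times the product
#' of the per-locus multipliers. `b` is set so that the population mean
#' risk equals the prevalence K. In `"uncapped"` mode this is closed
#' form, `b = K / E[prod OR^X]` (per-locus means multiply under linkage
#' equilibrium). In `"exact"` mode, where risks are truncated at 1
#' before averaging, `b` is found by monotone bisection so that
#' `E[min(1, b * prod)] = K` to within 1e-10.
#'
#' @param loci List of per-locus distributions from
#'   [genotype_locus_distributions()] (or extra-loci blocks).
#' @param K Disease prevalence in (0,1).
#' @param mode `"uncapped"` or `"exact"`.
#' @param dist Optional precomputed convolution (internal reuse).
#' @return The background risk `b`.
#' @export
calibrate_background <- function(loci, K = 0.01,
                                 mode = c("uncapped", "exact"),
                                 dist = NULL) {
  mode <- match.arg(mode)
  stopifnot(K > 0, K < 1)
  mean_mult <- prod(vapply(loci, function(l) sum(l$multiplier * l$prob), 0))
  b0 <- K / mean_mult
  if (mode == "uncapped") return(b0)
  if (is.null(dist)) dist <- convolve_loci(loci)
  capped_mean <- function(b) sum(dist$prob * pmin(1, b * exp(dist$logv)))
  if (capped_mean(b0) >= K - 1e-12) return(b0)
  lo <- b0
  hi <- b0
  while (capped_mean(hi) < K) {
    hi <- hi * 2
    if (hi > 1e12) stop("exact calibration infeasible: mean risk below K")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (capped_mean(mid) < K) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * hi) break
  }
  (lo + hi) / 2
}

#' Scenario for the constrained multiplicative risk model
#'
#' Bundles the base variants (SNPs and HLA alleles observed in the
#' association study) with blocks of hypothetical additional loci, the
#' disease prevalence and the calibration mode.
#'
#' @param snps,hla Base variants, as in
#'   [genotype_locus_distributions()].
#' @param blocks Data frame of additional-locus blocks with columns `n`
#'   (number of identical loci), `or`, `raf`; may be `NULL`.
#' @param prevalence Disease prevalence K (default 0.01).
#' @param calibration `"uncapped"` (background from the uncapped
#'   expectation, risks capped at 1 afterwards) or `"exact"`.
#' @param max_support,compress Support budget of the exact convolution
#'   and whether to grid-compress when exceeded.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(snps = NULL, hla = NULL, blocks = NULL,
                          prevalence = 0.01,
                          calibration = c("uncapped", "exact"),
                          max_support = 16384L, compress = TRUE) {
  calibration <- match.arg(calibration)
  stopifnot(prevalence > 0, prevalence < 1)
  if (!is.null(blocks) && nrow(blocks)) {
    stopifnot(all(blocks$n >= 0), all(blocks$or > 0),
              all(blocks$raf > 0), all(blocks$raf < 1))
  }
  structure(list(snps = snps, hla = hla, blocks = blocks,
                 prevalence = prevalence, calibration = calibration,
                 max_support = max_support, compress = compress),
            class = "scenario_spec")
}

# Identical-locus blocks collapse to Binomial(2N, p) risk-allele counts.
block_distribution <- function(n, or, raf) {
  k <- 0:(2 * n)
  list(multiplier = or^k, prob = stats::dbinom(k, 2 * n, raf))
}

scenario_loci <- function(scenario) {
  loci <- genotype_locus_distributions(scenario$snps, scenario$hla)
  if (!is.null(scenario$blocks)) {
    for (i in seq_len(nrow(scenario$blocks))) {
      if (scenario$blocks$n[i] > 0) {
        loci[[length(loci) + 1]] <- block_distribution(
          scenario$blocks$n[i], scenario$blocks$or[i],
          scenario$blocks$raf[i])
      }
    }
  }
  loci
}

#' Population and status-conditional risk distributions
#'
#' Builds the discrete distribution of disease risk `f(X) = min(1, b *
#' prod_l OR_l^{X_l})` over multilocus genotypes by exact sequential
#' convolution of per-locus multiplier distributions on the log scale,
#' then derives the case- and control-conditional distributions by Bayes
#' inversion: `P(X|case)` is proportional to `f(X) P(X)` and
#' `P(X|control)` to `(1 - f(X)) P(X)` (each renormalised).
#'
#' @param scenario A [scenario_spec()].
#' @return A list of class `risk_distribution` with `risk` (sorted
#'   support), `p_pop`, `p_case`, `p_control`, `b`, `prevalence`,
#'   `capped_mass` (population probability of capped genotypes) and
#'   `realised_prevalence` (mean capped risk, equals K under exact
#'   calibration).
#' @export
risk_distribution <- function(scenario) {
  loci <- scenario_loci(scenario)
  if (!length(loci)) {
    b <- scenario$prevalence
    return(structure(list(risk = b, p_pop = 1, p_case = 1, p_control = 1,
                          b = b, prevalence = scenario$prevalence,
                          capped_mass = 0, realised_prevalence = b),
                     class = "risk_distribution"))
  }
  dist <- convolve_loci(loci, scenario$max_support, scenario$compress)
  b <- calibrate_background(loci, scenario$prevalence,
                            scenario$calibration, dist = dist)
  risk <- pmin(1, b * exp(dist$logv))
  p <- dist$prob / sum(dist$prob)
  mean_risk <- sum(p * risk)
  p_case <- p * risk
  p_control <- p * (1 - risk)
  structure(list(risk = risk, p_pop = p,
                 p_case = p_case / sum(p_case),
                 p_control = p_control / sum(p_control),
                 b = b, prevalence = scenario$prevalence,
                 capped_mass = sum(p[b * exp(dist$logv) > 1]),
                 realised_prevalence = mean_risk),
            class = "risk_distribution")
}

#' ROC curve and AUC of a discrete risk distribution
#'
#' Sweeps every distinct risk value as a cut-off: the true positive rate
#' at cut-off t is `P(f(X) >= t | case)` and the false positive rate is
#' `P(f(X) >= t | control)`; the AUC is the trapezoid area under the
#' swept curve, which equals the Mann-Whitney probability
#' `P(f_case > f_control) + P(f_case = f_control) / 2`.
#'
#' @param dist A [risk_distribution()].
#' @return A list of class `roc_curve` with `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_and_auc <- function(dist) {
  o <- order(dist$risk)
  risk <- dist$risk[o]
  pc <- dist$p_case[o]
  pk <- dist$p_control[o]
  tpr <- rev(cumsum(rev(pc)))      # P(case risk >= t) at each support point
  fpr <- rev(cumsum(rev(pk)))
  # trapezoid over (fpr, tpr) swept from the highest cutoff down,
  # closing the curve at (0,0) and (1,1)
  x <- c(0, rev(fpr), 1)
  y <- c(0, rev(tpr), 1)
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(list(thresholds = rev(risk), tpr = rev(tpr), fpr = rev(fpr),
                 auc = auc),
            class = "roc_curve")
}

#' AUC implied by a single diagnostic operating point
#'
#' The area under the two-segment ROC curve through (0,0),
#' (1 - specificity, sensitivity) and (1,1) by the trapezoid rule, which
#' simplifies to `(sensitivity + specificity) / 2`. Used to translate a
#' published sensitivity/specificity pair for a diagnostic marker into
#' an AUC target.
#'
#' @param sensitivity,specificity Operating point, both in \[0,1\].
#' @return The implied AUC.
#' @examples
#' naive_auc_single_point(0.67, 0.95)  # 0.81
#' @export
naive_auc_single_point <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  (sensitivity + specificity) / 2
}

scenario_with_n <- function(scenario, block, n) {
  extra <- data.frame(n = n, or = block$or, raf = block$raf)
  blocks <- rbind(scenario$blocks, extra)
  s <- scenario
  s$blocks <- blocks
  s
}

#' Smallest number of additional loci reaching a target AUC
#'
#' Adds N identical loci (given odds ratio and risk allele frequency) to
#' a base scenario and finds the smallest N whose exact-model AUC
#' reaches `target_auc`, by doubling to bracket and then bisection
#' (valid because the AUC is non-decreasing in N).
#'
#' @param scenario Base [scenario_spec()].
#' @param block A list or one-row data frame with `or` and `raf`.
#' @param target_auc Target AUC in (0.5, 1).
#' @param n_max Search ceiling.
#' @return A list with `n` (loci needed), `auc` (achieved at `n`) and
#'   `base_auc`.
#' @export
loci_needed <- function(scenario, block, target_auc, n_max = 10000L) {
  auc_at <- function(n) {
    roc_and_auc(risk_distribution(scenario_with_n(scenario, block, n)))$auc
  }
  base_auc <- auc_at(0L)
  if (base_auc >= target_auc) {
    return(list(n = 0L, auc = base_auc, base_auc = base_auc))
  }
  hi <- 1L
  while (auc_at(hi) < target_auc) {
    hi <- hi * 2L
    if (hi > n_max) {
      stop("target AUC unreachable below n_max = ", n_max,
           "; achieved ", signif(auc_at(n_max), 4), " at the ceiling")
    }
  }
  lo <- hi %/% 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (auc_at(mid) < target_auc) lo <- mid else hi <- mid
  }
  list(n = hi, auc = auc_at(hi), base_auc = base_auc)
}

#' Monte Carlo AUC of a scenario
#'
#' Samples case and control genotypes by exact status-conditional
#' sampling (tilted per-locus proposals with rejection correcting for
#' the risk cap) and estimates the AUC by the tie-corrected Mann-Whitney
#' statistic; the standard error comes from batching the draws.
#'
#' @param scenario A [scenario_spec()].
#' @param n_draws Number of case and of control draws (at least 1000).
#' @param seed Integer seed (deterministic output).
#' @param n_batches Batches for the standard error.
#' @return A list with `auc` and `mc_se`.
#' @export
monte_carlo_auc <- function(scenario, n_draws = 10000L, seed,
                            n_batches = 10L) {
  stopifnot(n_draws >= 1000L)
  loci <- scenario_loci(scenario)
  b <- calibrate_background(loci, scenario$prevalence, scenario$calibration,
                            dist = if (scenario$calibration == "exact")
                              convolve_loci(loci, scenario$max_support,
                                            scenario$compress) else NULL)
  withr_seed(seed, {
    case_risk <- sample_status_risks(loci, b, n_draws, case = TRUE)
    control_risk <- sample_status_risks(loci, b, n_draws, case = FALSE)
  })
  batch <- rep(seq_len(n_batches), length.out = n_draws)
  aucs <- vapply(seq_len(n_batches), function(bt) {
    delong_placements(case_risk[batch == bt], control_risk[batch == bt])$auc
  }, 0)
  list(auc = delong_placements(case_risk, control_risk)$auc,
       mc_se = stats::sd(aucs) / sqrt(n_batches))
}

# Evaluate expr with a local, restored RNG state seeded from `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Exact sampling of capped risks given status.
# Cases: per-locus tilted proposal q*m / E[m] (exact for the uncapped
# product risk), then rejection with probability min(1, b*prod)/(b*prod)
# to correct for the cap. Controls: population proposal, accepted with
# probability 1 - min(1, b*prod).
sample_status_risks <- function(loci, b, n, case) {
  means <- vapply(loci, function(l) sum(l$multiplier * l$prob), 0)
  out <- numeric(0)
  while (length(out) < n) {
    todo <- n - length(out)
    m_take <- max(todo * 2L, 100L)
    prod_mult <- rep(1, m_take)
    for (i in seq_along(loci)) {
      l <- loci[[i]]
      pr <- if (case) l$prob * l$multiplier / means[i] else l$prob
      idx <- sample.int(length(l$multiplier), m_take, replace = TRUE,
                        prob = pr)
      prod_mult <- prod_mult * l$multiplier[idx]
    }
    uncapped <- b * prod_mult
    risk <- pmin(1, uncapped)
    acc <- if (case) stats::runif(m_take) < risk / uncapped
           else stats::runif(m_take) < (1 - risk)
    out <- c(out, risk[acc])
  }
  out[seq_len(n)]
}
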