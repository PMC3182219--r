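#' Log odds ratio from an allele-level 2x2 table
#'
#' Computes the per-allele log odds ratio of the risk allele versus the
#' non-risk allele from allele counts in cases and controls, with the
#' Haldane-Anscombe continuity correction applied to all four cells when
#' any cell is zero.
#'
#' @param case_risk,case_total Risk-allele count and total allele count in
#'   cases.
#' @param control_risk,control_total Risk-allele count and total allele
#'   count in controls.
#' @param zero_cell_correction Value added to every cell when any cell of
#'   the 2x2 table is zero (default 0.5).
#' @return A list with elements `log_or` and `se` (the standard error
#'   `sqrt(1/a + 1/b + 1/c + 1/d)` over the corrected cells).
#' @examples
#' logodds_from_table(30, 100, 20, 100)
#' @export
logodds_from_table <- function(case_risk, case_total, control_risk,
                               control_total,
                               zero_cell_correction = 0.5) {
  stopifnot(case_risk >= 0, control_risk >= 0,
            case_risk <= case_total, control_risk <= control_total,
            zero_cell_correction >= 0)
  a <- case_risk
  b <- case_total - case_risk
  c_ <- control_risk
  d <- control_total - control_risk
  cells <- c(a, b, c_, d)
  # a margin of zero cannot be rescued by a continuity correction
  if (a + c_ == 0 || b + d == 0 || a + b == 0 || c_ + d == 0) {
    stop("degenerate table: a margin of the 2x2 table is zero")
  }
  if (any(cells == 0)) {
    if (zero_cell_correction == 0) {
      stop("degenerate table: zero cell and no correction")
    }
    cells <- cells + zero_cell_correction
  }
  list(
    log_or = log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4]),
    se = sqrt(sum(1 / cells))
  )
}

#' Convert an odds ratio with 95% confidence interval to log-OR and SE
#'
#' Published meta-analyses usually report `OR (95% CI)`; pooling needs the
#' log odds ratio and its standard error. The standard error is recovered
#' as `(log(upper) - log(lower)) / (2 * 1.96)`.
#'
#' @param or Odds ratio.
#' @param ci_low,ci_high Bounds of the 95% confidence interval.
#' @return A list with `log_or` and `se`.
#' @export
or_ci_to_effect <- function(or, ci_low, ci_high) {
  stopifnot(or > 0, ci_low > 0, ci_high > ci_low)
  list(log_or = log(or), se = (log(ci_high) - log(ci_low)) / (2 * 1.96))
}

check_effects <- function(log_or, se, min_n = 1L) {
  stopifnot(length(log_or) == length(se))
  if (length(log_or) < min_n) {
    stop(if (min_n >= 2L) "random effects undefined with fewer than 2 studies"
         else "at least one study effect is required")
  }
  if (any(!is.finite(log_or)) || any(!is.finite(se)) || any(se <= 0)) {
    stop("effects must be finite with positive standard errors")
  }
}

#' Fixed-effects (inverse-variance) pooling
#'
#' @param log_or Per-study log odds ratios.
#' @param se Per-study standard errors (positive).
#' @return A list with `pooled`, `se` and the two-sided normal `p`.
#' @export
pool_fixed <- function(log_or, se) {
  check_effects(log_or, se, 1L)
  w <- 1 / se^2
  pooled <- sum(w * log_or) / sum(w)
  se_p <- sqrt(1 / sum(w))
  list(pooled = pooled, se = se_p,
       p = 2 * stats::pnorm(-abs(pooled / se_p)))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance by the method of moments,
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`
#' and fixed-effects weights `w = 1/se^2`, then pools with weights
#' `1/(se^2 + tau2)`. When the studies are homogeneous (`Q <= df`) the
#' estimate truncates to zero and the result coincides with
#' [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return A list with `pooled`, `se`, `tau2` and the two-sided `p`.
#' @export
pool_dl <- function(log_or, se) {
  check_effects(log_or, se, 2L)
  w <- 1 / se^2
  fe <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - fe)^2)
  df <- length(log_or) - 1
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_dl)
  w_re <- 1 / (se^2 + tau2)
  pooled <- sum(w_re * log_or) / sum(w_re)
  se_p <- sqrt(1 / sum(w_re))
  list(pooled = pooled, se = se_p, tau2 = tau2,
       p = 2 * stats::pnorm(-abs(pooled / se_p)))
}

#' Cochran's Q test and the I-squared heterogeneity metric
#'
#' Q is the fixed-effects weighted sum of squared deviations from the
#' pooled estimate, referred to a chi-squared distribution on
#' `n_studies - 1` degrees of freedom. I-squared expresses the excess of
#' Q over its degrees of freedom as a percentage,
#' `max(0, (Q - df)/Q) * 100`; values over 50 are conventionally read as
#' large heterogeneity.
#'
#' @inheritParams pool_fixed
#' @param alpha Significance level of the Q test (default 0.1).
#' @return A list with `q`, `df`, `p_q`, `i2` and the logical
#'   `large_heterogeneity` (`i2 > 50`), plus `significant` at `alpha`.
#' @export
cochran_q <- function(log_or, se, alpha = 0.1) {
  check_effects(log_or, se, 2L)
  w <- 1 / se^2
  fe <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - fe)^2)
  df <- length(log_or) - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  p_q <- stats::pchisq(q, df, lower.tail = FALSE)
  list(q = q, df = df, p_q = p_q, i2 = i2,
       large_heterogeneity = i2 > 50, significant = p_q < alpha)
}

#' Meta-analyse one variant across studies
#'
#' Convenience wrapper returning fixed-effects, DerSimonian-Laird and
#' heterogeneity summaries as one row, the unit of the re-analysis of
#' published meta-analyses.
#'
#' @param studies A data frame of [StudyRecord][read_study_table] rows for
#'   one variant: either allele-level 2x2 counts (`case_risk_alleles`,
#'   `case_total_alleles`, `control_risk_alleles`,
#'   `control_total_alleles`) or precomputed `log_or` and `se`.
#' @param variant_id Identifier stored in the result.
#' @param zero_cell_correction Passed to [logodds_from_table()].
#' @return A one-row data frame (a `MetaResult`): pooled log-ORs and SEs
#'   under both models, `tau2`, `q`, `df`, `p_q`, `i2`, `p_fe`, `p_re`,
#'   `n_studies`.
#' @export
meta_analyse <- function(studies, variant_id = studies$variant_id[1],
                         zero_cell_correction = 0.5) {
  eff <- study_effects(studies, zero_cell_correction)
  fe <- pool_fixed(eff$log_or, eff$se)
  if (nrow(eff) >= 2) {
    re <- pool_dl(eff$log_or, eff$se)
    het <- cochran_q(eff$log_or, eff$se)
  } else {
    re <- c(fe, list(tau2 = 0))
    het <- list(q = 0, df = 0, p_q = NA_real_, i2 = 0)
  }
  data.frame(
    variant_id = variant_id, n_studies = nrow(eff),
    pooled_log_or_fe = fe$pooled, se_fe = fe$se, p_fe = fe$p,
    pooled_log_or_re = re$pooled, se_re = re$se, p_re = re$p,
    tau2 = re$tau2, q = het$q, df = het$df, p_q = het$p_q, i2 = het$i2,
    stringsAsFactors = FALSE
  )
}

# Per-study effects from a StudyRecord data frame: counts take precedence,
# otherwise precomputed (log_or, se) is used.
study_effects <- function(studies, zero_cell_correction = 0.5) {
  has_counts <- all(c("case_risk_alleles", "case_total_alleles",
                      "control_risk_alleles", "control_total_alleles")
                    %in% names(studies)) &&
    !anyNA(studies$case_risk_alleles)
  if (has_counts) {
    eff <- lapply(seq_len(nrow(studies)), function(i) {
      logodds_from_table(studies$case_risk_alleles[i],
                         studies$case_total_alleles[i],
                         studies$control_risk_alleles[i],
                         studies$control_total_alleles[i],
                         zero_cell_correction)
    })
    data.frame(log_or = vapply(eff, `[[`, 0, "log_or"),
               se = vapply(eff, `[[`, 0, "se"))
  } else {
    stopifnot(all(c("log_or", "se") %in% names(studies)))
    data.frame(log_or = studies$log_or, se = studies$se)
  }
}

#' Heterogeneity of pooled effects between two subgroups
#'
#' Two-sample z-test on the pooled log odds ratios of two independent
#' subgroups (for instance East Asian versus European descent studies of
#' the same variant): `z = (theta_a - theta_b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param pooled_a,se_a Pooled log-OR and its SE in the first subgroup.
#' @param pooled_b,se_b Same for the second subgroup.
#' @return A list with `z` and the two-sided `p`.
#' @export
subgroup_heterogeneity <- function(pooled_a, se_a, pooled_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  z <- (pooled_a - pooled_b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Is between-study heterogeneity more frequent than expected by chance?
#'
#' Upper binomial tail `P(X >= n_significant)` with
#' `X ~ Binomial(n_tests, alpha)`: the probability of observing at least
#' the seen number of significant Q tests if each test were significant
#' with probability `alpha` independently.
#'
#' @param n_significant Number of heterogeneity tests that came out
#'   significant.
#' @param n_tests Total number of heterogeneity tests performed.
#' @param alpha Significance level of each individual Q test.
#' @return The one-sided upper-tail probability.
#' @examples
#' excess_heterogeneity_test(10, 20, 0.1)
#' @export
excess_heterogeneity_test <- function(n_significant, n_tests, alpha = 0.1) {
  stopifnot(n_significant >= 0, n_significant <= n_tests,
            alpha > 0, alpha < 1)
  if (n_significant == 0) return(1)
  stats::pbinom(n_significant - 1, n_tests, alpha, lower.tail = FALSE)
}

#' Default variant selection criteria
#'
#' Thresholds used to select variants for the risk model: association
#' evidence in the re-analysed meta-analyses at `P < 2.5e-3` (0.05/20,
#' Bonferroni over the candidate variants) or genome-wide significance
#' `P < 5e-8` in a GWAS catalog, a minor-allele-frequency floor of 5% in
#' the target population, and the subgroup rules under which an
#' ethnicity-specific odds ratio replaces the overall one.
#'
#' @param meta_p_threshold,gwas_p_threshold,maf_floor Main gates.
#' @param min_studies_per_group,min_subjects_per_group,subgroup_p,heterogeneity_p
#'   Subgroup rules: both subgroups need at least this many studies and
#'   subjects, the target-group effect must be significant at
#'   `subgroup_p`, and the between-group heterogeneity at
#'   `heterogeneity_p`.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(meta_p_threshold = 2.5e-3,
                               gwas_p_threshold = 5e-8,
                               maf_floor = 0.05,
                               min_studies_per_group = 3L,
                               min_subjects_per_group = 2000L,
                               subgroup_p = 2.5e-3,
                               heterogeneity_p = 0.05) {
  stopifnot(meta_p_threshold > 0, meta_p_threshold < 1,
            gwas_p_threshold > 0, gwas_p_threshold < 1,
            maf_floor > 0, maf_floor <= 0.5)
  structure(list(meta_p_threshold = meta_p_threshold,
                 gwas_p_threshold = gwas_p_threshold,
                 maf_floor = maf_floor,
                 min_studies_per_group = min_studies_per_group,
                 min_subjects_per_group = min_subjects_per_group,
                 subgroup_p = subgroup_p,
                 heterogeneity_p = heterogeneity_p),
            class = "selection_criteria")
}

#' Rule-based selection of variants for the risk model
#'
#' Keeps every variant that passes the association gate (meta-analysis
#' `p_fe` below `meta_p_threshold` or a GWAS catalog p-value below
#' `gwas_p_threshold`) and whose minor allele frequency in the target
#' population is at least `maf_floor`. When an ethnicity-specific
#' subgroup analysis for a variant satisfies all subgroup rules, the
#' target-group OR is attached in place of the overall OR.
#'
#' @param meta Data frame of [meta_analyse()] rows (one per variant).
#' @param gwas_hits Optional data frame with columns `variant_id`, `p`.
#' @param maf Named numeric vector: minor allele frequency per variant in
#'   the target population; must cover every candidate.
#' @param criteria A [selection_criteria()] list.
#' @param subgroups Optional data frame describing per-variant subgroup
#'   analyses with columns `variant_id`, `target_pooled`, `target_se`,
#'   `target_p`, `target_n_studies`, `target_n_subjects`,
#'   `major_pooled`, `major_se`, `major_n_studies`, `major_n_subjects`.
#' @return A data frame of selected variants ordered by `variant_id`,
#'   with columns `variant_id`, `log_or`, `or`, `se`, `source`
#'   (`"meta"` or `"gwas"`) and `ethnicity_specific` (logical).
#' @export
select_variants <- function(meta, gwas_hits = NULL, maf,
                            criteria = selection_criteria(),
                            subgroups = NULL) {
  candidates <- unique(c(meta$variant_id,
                         if (!is.null(gwas_hits)) gwas_hits$variant_id))
  missing_maf <- setdiff(candidates, names(maf))
  if (length(missing_maf)) {
    stop("missing minor allele frequency for variant(s): ",
         paste(missing_maf, collapse = ", "))
  }
  rows <- lapply(sort(candidates), function(v) {
    m <- meta[meta$variant_id == v, , drop = FALSE]
    g <- if (!is.null(gwas_hits)) {
      gwas_hits[gwas_hits$variant_id == v, , drop = FALSE]
    }
    pass_meta <- nrow(m) == 1 && m$p_fe < criteria$meta_p_threshold
    pass_gwas <- !is.null(g) && nrow(g) >= 1 &&
      any(g$p < criteria$gwas_p_threshold)
    if (!(pass_meta || pass_gwas)) return(NULL)
    if (maf[[v]] < criteria$maf_floor) return(NULL)
    log_or <- if (pass_meta) m$pooled_log_or_fe else NA_real_
    se <- if (pass_meta) m$se_fe else NA_real_
    eth <- FALSE
    if (!is.null(subgroups)) {
      s <- subgroups[subgroups$variant_id == v, , drop = FALSE]
      if (nrow(s) == 1 && subgroup_rules_pass(s, criteria)) {
        log_or <- s$target_pooled
        se <- s$target_se
        eth <- TRUE
      }
    }
    data.frame(variant_id = v, log_or = log_or, or = exp(log_or), se = se,
               source = if (pass_meta) "meta" else "gwas",
               ethnicity_specific = eth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), log_or = numeric(),
                      or = numeric(), se = numeric(), source = character(),
                      ethnicity_specific = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

subgroup_rules_pass <- function(s, criteria) {
  het <- subgroup_heterogeneity(s$target_pooled, s$target_se,
                                s$major_pooled, s$major_se)
  s$target_n_studies >= criteria$min_studies_per_group &&
    s$major_n_studies >= criteria$min_studies_per_group &&
    s$target_n_subjects >= criteria$min_subjects_per_group &&
    s$major_n_subjects >= criteria$min_subjects_per_group &&
    s$target_p < criteria$subgroup_p &&
    het$p < criteria$heterogeneity_p
}
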