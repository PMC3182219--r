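test_that("HWE exact test equals full enumeration", {
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)

  expect_equal(hwe_exact_test(25, 50, 25), bf_hwe(25, 50, 25),
               tolerance = 1e-10)
  # expected proportions: the observed table is near the mode
  expect_gt(hwe_exact_test(25, 50, 25), 0.9)

  # extreme heterozygote deficit fails the P < 0.001 exclusion gate
  expect_lt(hwe_exact_test(50, 0, 50), 1e-3)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:250, 1)      # up to 500 alleles
    g <- as.vector(stats::rmultinom(1, n, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 bf_hwe(g[1], g[2], g[3]), tolerance = 1e-10)
  }
})

test_that("risk scores are log-OR-weighted allele counts", {
  m_null <- risk_score_model(snp_or = c(rs1 = 1, rs2 = 1), model_kind = "nonhla")
  g <- data.frame(rs1 = c(0, 1, 2), rs2 = c(2, 1, 0))
  expect_equal(compute_risk_score(m_null, g), c(0, 0, 0))

  m1 <- risk_score_model(snp_or = c(rs1 = 2), model_kind = "nonhla")
  expect_equal(compute_risk_score(m1, data.frame(rs1 = 2)), 2 * log(2))

  # integrative score is the sum of the HLA and non-HLA scores
  snp_or <- c(rs1 = 1.3, rs2 = 0.8)
  hla_or <- c(h1 = 2.3, h2 = 1.2)
  gt <- data.frame(rs1 = c(0, 1, 2, 2), rs2 = c(1, 2, 0, 1),
                   h1 = c(0, 1, 2, 0), h2 = c(1, 0, 0, 2))
  s_int <- compute_risk_score(risk_score_model(snp_or, hla_or,
                                               "integrative"), gt)
  s_hla <- compute_risk_score(risk_score_model(snp_or, hla_or, "hla"), gt)
  s_non <- compute_risk_score(risk_score_model(snp_or, hla_or, "nonhla"), gt)
  expect_equal(s_int, s_hla + s_non)

  gt$rs1[2] <- NA
  expect_error(compute_risk_score(risk_score_model(snp_or, hla_or,
                                                   "integrative"), gt),
               "rs1")
  expect_equal(nrow(complete_cases(risk_score_model(snp_or, hla_or,
                                                    "integrative"), gt)), 3)
})

test_that("logistic fits satisfy closed forms and recover parameters", {
  n <- 40
  status <- rep(c(1, 0), each = n)
  fit0 <- fit_logistic(data.frame(x = rep(0, 2 * n))[, 0, drop = FALSE],
                       status)
  expect_equal(fit0$log_likelihood, 2 * n * log(0.5), tolerance = 1e-6)
  expect_equal(fit0$aic, -4 * n * log(0.5) + 2, tolerance = 1e-6)

  # adding an all-zero predictor leaves the likelihood, costs 2 AIC
  fitz <- fit_logistic(data.frame(z = rep(0, 2 * n)), status)
  expect_equal(fitz$log_likelihood, fit0$log_likelihood, tolerance = 1e-6)
  expect_equal(fitz$aic, fit0$aic + 2, tolerance = 1e-6)

  # parameter recovery on generator output
  sc <- scenario_spec(snps = data.frame(or = 2, raf = 0.3))
  coh <- gen_cohort(sc, 4000, 4000, missing_rate = 0, seed = 100)
  fit <- fit_logistic(coh[, "snp1", drop = FALSE], coh$status)
  se <- sqrt(diag(vcov(fit$fit)))["snp1"]
  expect_lt(abs(fit$coefficients["snp1"] - log(2)), 2 * se)

  # complete separation errors rather than returning a degenerate fit
  expect_error(fit_logistic(data.frame(x = c(0, 0, 0, 1, 1, 1)),
                            c(0, 0, 0, 1, 1, 1)), "separation")
})

test_that("empirical AUC equals the exhaustive pairwise oracle", {
  r <- empirical_auc(c(2, 3), c(1, 2))
  expect_equal(r$auc, 0.875)

  set.seed(17)
  for (i in 1:10) {
    m <- sample(5:200, 1)
    n <- sample(5:200, 1)
    x <- round(rnorm(m, 0.3), 1)   # rounding forces ties
    y <- round(rnorm(n), 1)
    expect_equal(empirical_auc(x, y)$auc, bf_auc(x, y), tolerance = 1e-12)
  }

  # identical distributions give AUC 1/2 exactly under exchangeability
  z <- rnorm(50)
  expect_equal(empirical_auc(z, z)$auc, 0.5)

  # rank invariance under strictly increasing transforms
  x <- rnorm(80); y <- rnorm(60, -0.5)
  expect_equal(empirical_auc(exp(x), exp(y))$auc,
               empirical_auc(x, y)$auc)

  # curve is a monotone path from (0,0) to (1,1), AUC inside the CI
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  big <- empirical_auc(rnorm(100, 1), rnorm(100))
  expect_true(big$ci_low <= big$auc && big$auc <= big$ci_high)
})

test_that("DeLong machinery agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  x <- rnorm(80, 0.8)
  y <- rnorm(90)
  mine <- empirical_auc(x, y)
  ref <- pROC::roc(controls = y, cases = x, quiet = TRUE)
  expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-10)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ci)[c(1, 3)],
               tolerance = 1e-8)

  status <- rep(c(1, 0), c(80, 90))
  s_a <- c(x, y)
  s_b <- s_a + rnorm(170, sd = 0.7)
  mine2 <- compare_auc_paired(s_a, s_b, status)
  ref2 <- pROC::roc.test(pROC::roc(status, s_a, quiet = TRUE,
                                   direction = "<"),
                         pROC::roc(status, s_b, quiet = TRUE,
                                   direction = "<"),
                         method = "delong", paired = TRUE)
  expect_equal(mine2$p, ref2$p.value, tolerance = 1e-8)
})

test_that("paired AUC comparison is calibrated and powered", {
  x <- rnorm(40, 1)
  y <- rnorm(40)
  s <- c(x, y)
  st <- rep(c(1, 0), each = 40)
  self <- compare_auc_paired(s, s, st)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p, 1)

  # null calibration: a pure-noise extra variant gives uniform-ish p
  set.seed(41)
  ps <- replicate(300, {
    base <- rnorm(120) + rep(c(0.8, 0), each = 60)
    noise <- base + rnorm(120, sd = 0.5)
    compare_auc_paired(base, noise, rep(c(1, 0), each = 60))$p
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.13)

  # power: a strongly informative addition is detected
  set.seed(43)
  base <- rnorm(400) + rep(c(0.3, 0), each = 200)
  strong <- base + rep(c(1.5, 0), each = 200)
  pw <- compare_auc_paired(strong, base, rep(c(1, 0), each = 200))
  expect_gt(pw$delta_auc, 0)
  expect_lt(pw$p, 0.01)

  expect_error(compare_auc_paired(1:5, 1:4, c(1, 1, 0, 0)))
})

test_that("score density integrates to one and tracks multimodality", {
  set.seed(19)
  z <- rnorm(500)
  d <- score_density(z)
  expect_equal(sum(d$density) * diff(d$x[1:2]), 1, tolerance = 1e-3)

  # translation equivariance
  d2 <- score_density(z + 5)
  expect_equal(d2$density, d$density, tolerance = 1e-9)
  expect_equal(d2$x, d$x + 5, tolerance = 1e-9)

  # HLA-driven scores are multimodal: carriers of a strong allele sit in
  # separate score bands
  sc <- scenario_spec(hla = data.frame(or = 6, freq = 0.2))
  coh <- gen_cohort(sc, 800, 800, missing_rate = 0, seed = 77)
  sco <- coh$hla1 * log(6) + rnorm(1600, sd = 0.1)
  dd <- score_density(sco, bandwidth = 0.15)
  peaks <- sum(diff(sign(diff(dd$density))) == -2)
  expect_gte(peaks, 2)

  expect_error(score_density(rep(1, 10)), "degenerate")
})

test_that("case-control score distribution test behaves at the extremes", {
  z <- rnorm(30)
  expect_equal(score_distribution_test(z, z), 1, tolerance = 1e-9)

  # disjoint supports: two-sided Mann-Whitney attains its sample-size
  # minimum, matched by complete enumeration at small n
  x <- 11:15; y <- 1:5
  p <- score_distribution_test(x, y)
  exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(p, 0.01)
  expect_equal(exact, 2 / choose(10, 5), tolerance = 1e-12)

  # normal-approximation p agrees with the permutation reference
  set.seed(59)
  a <- rnorm(25, 0.7)
  b <- rnorm(30)
  p_w <- score_distribution_test(a, b)
  p_perm <- score_distribution_test(a, b, method = "permutation",
                                    n_perm = 20000)
  expect_lt(abs(p_w - p_perm), 0.02)
})
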