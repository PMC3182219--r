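test_that("per-locus genotype distributions follow HWE", {
  d <- genotype_locus_distributions(snps = data.frame(or = 2, raf = 0.5))
  expect_equal(d[[1]]$multiplier, c(1, 2, 4))
  expect_equal(d[[1]]$prob, c(0.25, 0.5, 0.25))

  hla <- data.frame(or = rep(1.5, 6), freq = rep(0.05, 6))
  dh <- genotype_locus_distributions(hla = hla)
  expect_length(dh[[1]]$multiplier, 28)   # 7*8/2 unordered pairs
  expect_equal(sum(dh[[1]]$prob), 1, tolerance = 1e-12)

  d1 <- genotype_locus_distributions(snps = data.frame(or = 1, raf = 0.3))
  expect_equal(d1[[1]]$multiplier, c(1, 1, 1))

  expect_error(genotype_locus_distributions(
    hla = data.frame(or = c(2, 2), freq = c(0.6, 0.5))), "sum")
})

test_that("background risk calibration hits the prevalence", {
  null_loci <- genotype_locus_distributions(
    snps = data.frame(or = c(1, 1), raf = c(0.3, 0.4)))
  expect_equal(calibrate_background(null_loci, K = 0.01), 0.01)

  one <- genotype_locus_distributions(snps = data.frame(or = 2, raf = 0.5))
  expect_equal(calibrate_background(one, K = 0.01), 0.01 / 2.25,
               tolerance = 1e-12)

  # exact mode equals uncapped mode when the cap never binds
  expect_equal(calibrate_background(one, K = 0.01, mode = "exact"),
               calibrate_background(one, K = 0.01), tolerance = 1e-9)

  # with strong effects the cap binds; exact calibration restores K
  sc <- scenario_spec(snps = data.frame(or = rep(8, 4), raf = rep(0.3, 4)),
                      prevalence = 0.05, calibration = "exact")
  d <- risk_distribution(sc)
  expect_gt(d$capped_mass, 0)
  expect_equal(d$realised_prevalence, 0.05, tolerance = 1e-8)
})

test_that("risk distribution matches direct Bayes enumeration", {
  empty <- risk_distribution(scenario_spec())
  expect_equal(empty$risk, 0.01)
  expect_equal(empty$p_case, 1)
  expect_equal(empty$p_control, 1)

  # one SNP: 3-outcome hand enumeration of Eq.-style Bayes inversion
  p <- 0.3; or <- 2; K <- 0.01
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mult <- c(1, or, or^2)
  b <- K / sum(probs * mult)
  risk <- b * mult
  d <- risk_distribution(scenario_spec(snps = data.frame(or = or, raf = p)))
  expect_equal(d$risk, risk, tolerance = 1e-12)
  expect_equal(d$p_case, risk * probs / sum(risk * probs),
               tolerance = 1e-12)
  expect_equal(d$p_control, (1 - risk) * probs / sum((1 - risk) * probs),
               tolerance = 1e-12)

  # conditional distributions are normalised
  sc <- scenario_spec(snps = data.frame(or = c(1.5, 2), raf = c(0.2, 0.4)),
                      hla = data.frame(or = c(3, 1.4), freq = c(0.1, 0.2)))
  dd <- risk_distribution(sc)
  expect_equal(sum(dd$p_pop), 1, tolerance = 1e-9)
  expect_equal(sum(dd$p_case), 1, tolerance = 1e-9)
  expect_equal(sum(dd$p_control), 1, tolerance = 1e-9)
})

test_that("identical-locus blocks collapse to a binomial allele count", {
  for (n in c(3, 10)) {
    block <- risk_distribution(scenario_spec(
      blocks = data.frame(n = n, or = 1.4, raf = 0.25)))
    separate <- risk_distribution(scenario_spec(
      snps = data.frame(or = rep(1.4, n), raf = rep(0.25, n))))
    expect_equal(block$risk, separate$risk, tolerance = 1e-9)
    expect_equal(block$p_pop, separate$p_pop, tolerance = 1e-9)
    # allele-count distribution is Binomial(2N, p)
    expect_equal(block$p_pop, dbinom(0:(2 * n), 2 * n, 0.25),
                 tolerance = 1e-12)
  }

  # convolution is invariant to locus processing order
  a <- risk_distribution(scenario_spec(
    snps = data.frame(or = c(1.3, 2.2, 0.8), raf = c(0.1, 0.5, 0.35))))
  b <- risk_distribution(scenario_spec(
    snps = data.frame(or = c(0.8, 1.3, 2.2), raf = c(0.35, 0.1, 0.5))))
  expect_equal(a$risk, b$risk, tolerance = 1e-9)
  expect_equal(a$p_pop, b$p_pop, tolerance = 1e-9)
})

test_that("exact AUC equals the pairwise-probability oracle", {
  flat <- risk_distribution(scenario_spec(
    snps = data.frame(or = c(1, 1), raf = c(0.3, 0.4))))
  expect_equal(roc_and_auc(flat)$auc, 0.5)

  one <- risk_distribution(scenario_spec(
    snps = data.frame(or = 2, raf = 0.3)))
  expect_equal(roc_and_auc(one)$auc, bf_dist_auc(one), tolerance = 1e-12)

  set.seed(47)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    sc <- scenario_spec(snps = data.frame(or = runif(k, 0.7, 3),
                                          raf = runif(k, 0.05, 0.6)))
    d <- risk_distribution(sc)
    expect_equal(roc_and_auc(d)$auc, bf_dist_auc(d), tolerance = 1e-10)
  }

  # AUC strictly increases with a locus odds ratio
  aucs <- sapply(c(1.2, 1.6, 2.5), function(or) {
    roc_and_auc(risk_distribution(scenario_spec(
      snps = data.frame(or = c(or, 1.3), raf = c(0.3, 0.4)))))$auc
  })
  expect_true(all(diff(aucs) > 0))

  # continuity: AUC -> 1/2 as effects vanish
  tiny <- roc_and_auc(risk_distribution(scenario_spec(
    snps = data.frame(or = 1 + 1e-6, raf = 0.3))))$auc
  expect_equal(tiny, 0.5, tolerance = 1e-5)
})

test_that("single-operating-point AUC is the trapezoid through the point", {
  expect_equal(naive_auc_single_point(0.67, 0.95), 0.81)
  expect_equal(naive_auc_single_point(0.5, 0.5), 0.5)
  expect_equal(naive_auc_single_point(1, 1), 1)
})

test_that("loci-needed search equals the linear scan", {
  base <- scenario_spec()
  block <- list(or = 1.5, raf = 0.3)
  res <- loci_needed(base, block, target_auc = 0.75)
  # independent linear scan
  scan <- 0
  repeat {
    scan <- scan + 1
    auc <- roc_and_auc(risk_distribution(scenario_spec(
      blocks = data.frame(n = scan, or = 1.5, raf = 0.3))))$auc
    if (auc >= 0.75) break
  }
  expect_equal(res$n, scan)
  expect_gte(res$auc, 0.75)

  # zero loci needed when the base already meets the target
  done <- loci_needed(base, block, target_auc = res$base_auc)
  expect_equal(done$n, 0)

  # stronger effects need fewer loci
  ns <- sapply(c(1.3, 1.6, 2.0), function(or) {
    loci_needed(base, list(or = or, raf = 0.3), target_auc = 0.7)$n
  })
  expect_true(all(diff(ns) <= 0))

  expect_error(loci_needed(base, list(or = 1.01, raf = 0.3),
                           target_auc = 0.99, n_max = 64), "unreachable")
})

test_that("Monte Carlo AUC cross-validates the exact engine", {
  sc <- scenario_spec(snps = data.frame(or = c(2, 1.5, 0.8),
                                        raf = c(0.3, 0.2, 0.5)),
                      hla = data.frame(or = c(2.5, 1.3),
                                       freq = c(0.12, 0.2)))
  exact <- roc_and_auc(risk_distribution(sc))$auc
  mc <- monte_carlo_auc(sc, n_draws = 20000, seed = 303)
  expect_lt(abs(mc$auc - exact), 3 * mc$mc_se)

  # determinism under a fixed seed
  mc2 <- monte_carlo_auc(sc, n_draws = 2000, seed = 11)
  mc3 <- monte_carlo_auc(sc, n_draws = 2000, seed = 11)
  expect_identical(mc2, mc3)

  null_mc <- monte_carlo_auc(scenario_spec(
    snps = data.frame(or = 1, raf = 0.3)), n_draws = 2000, seed = 5)
  expect_equal(null_mc$auc, 0.5, tolerance = 0.05)
})

test_that("support compression errors when disabled, engages when enabled", {
  set.seed(61)
  sc_err <- scenario_spec(snps = data.frame(or = runif(12, 1.1, 2),
                                            raf = runif(12, 0.2, 0.5)),
                          max_support = 1000, compress = FALSE)
  expect_error(risk_distribution(sc_err), "bin budget")

  sc_ok <- sc_err
  sc_ok$compress <- TRUE
  d <- risk_distribution(sc_ok)
  expect_lte(length(d$risk), 1001)
  expect_equal(sum(d$p_pop), 1, tolerance = 1e-9)
  # compressed AUC stays close to the exact one
  sc_exact <- sc_err
  sc_exact$max_support <- 1e6
  expect_equal(roc_and_auc(d)$auc,
               roc_and_auc(risk_distribution(sc_exact))$auc,
               tolerance = 1e-3)
})
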