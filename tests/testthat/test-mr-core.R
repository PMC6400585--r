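test_that("Wald ratio arithmetic and orientation invariance", {
  w <- wald_ratio(0.4, 0.05, 0.2, 0.05)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.125)
  expect_equal(wald_ratio(0.4, 0.05, 0, 0.05)$estimate, 0)
  expect_error(wald_ratio(0, 0.05, 0.2, 0.05), "zero")
  flipped <- wald_ratio(-0.4, 0.05, -0.2, 0.05)
  expect_equal(flipped$estimate, w$estimate)
})

test_that("IVW closed form matches its hand-computed examples", {
  instr <- make_instruments(c(0.4, 0.2), c(0.2, 0.1), se_out = 0.1)
  est <- mr_ivw(instr)
  expect_equal(est$estimate, 0.5)
  expect_equal(est$Q, 0)
  expect_equal(mr_ivw(instr, "fixed")$se, sqrt(1 / 20))
  # ratios 0.5, 0.3 with weights 16, 4
  instr2 <- make_ratio_instruments(c(0.5, 0.3), c(16, 4))
  est2 <- mr_ivw(instr2)
  expect_equal(est2$estimate, 0.46)
  expect_equal(est2$Q, 16 * 0.04^2 + 4 * 0.16^2)
  expect_equal(est2$Q, 0.128)
  # a duplicated pair collapses to the Wald ratio with Q = 0
  dup <- make_instruments(rep(0.4, 5), rep(0.2, 5), se_out = 0.1)
  expect_equal(mr_ivw(dup)$estimate, 0.5)
  expect_equal(mr_ivw(dup)$Q, 0, tolerance = 1e-12)
  expect_error(mr_ivw(make_instruments(0.4, 0.2)), "wald_ratio")
})

test_that("IVW equals a brute-force weighted least squares solve", {
  set.seed(300)
  for (i in 1:20) {
    j <- sample(3:15, 1)
    instr <- make_instruments(runif(j, 0.05, 0.5),
                              rnorm(j, 0.1, 0.05),
                              se_out = runif(j, 0.01, 0.1))
    ours <- mr_ivw(instr, "fixed")
    ref <- lm(beta_out ~ 0 + beta_exp, data = as.data.frame(instr),
              weights = 1 / instr$se_out^2)
    expect_equal(ours$estimate, unname(coef(ref)), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers intercept and slope exactly on noiseless data", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.1 + 0.5 * bx
  instr <- make_instruments(bx, by, se_out = 0.05)
  est <- mr_egger(instr)
  expect_equal(est$estimate, 0.5, tolerance = 1e-10)
  expect_equal(est$intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(make_instruments(c(0.1, 0.2), c(0.1, 0.2))),
               ">= 3")
})

test_that("Egger intercept is centred on zero without pleiotropy and detects it when present", {
  # tested under the causal null: with a nonzero causal effect and noisy
  # instrument estimates the intercept picks up the known regression-
  # dilution artefact, which is a separate phenomenon
  sim_intercepts <- function(alpha_mean, reps = 150) {
    replicate(reps, {
      cfg <- sim_config(n_individuals = 2000, n_snps = 15,
                        causal_effect = 0,
                        pleiotropy_fraction = if (alpha_mean > 0) 1 else 0,
                        pleiotropy_mean = alpha_mean, pleiotropy_sd = 0.01,
                        seed = NULL)
      pair <- simulate_two_sample_gwas(cfg, keep_samples = FALSE)
      s <- pair$exposure_stats; o <- pair$outcome_stats
      instr <- instrument_set(data.frame(
        snp = s$snp, effect_allele = s$effect_allele,
        other_allele = s$other_allele, beta_exp = s$beta, se_exp = s$se,
        pval_exp = s$pval, n_exp = s$n, beta_out = o$beta, se_out = o$se,
        pval_out = o$pval, n_out = o$n))
      mr_egger(instr)$intercept
    })
  }
  set.seed(301)
  null_int <- sim_intercepts(0)
  expect_lt(abs(mean(null_int)), 3 * sd(null_int) / sqrt(length(null_int)))
  dir_int <- sim_intercepts(0.05)
  # directional pleiotropy shifts the intercept away from zero
  expect_gt(mean(dir_int), 3 * sd(dir_int) / sqrt(length(dir_int)))
})

test_that("weighted median matches the cumulative-weight oracle", {
  instr <- make_ratio_instruments(c(0.1, 0.2, 0.3), c(1, 1, 1))
  expect_equal(mr_weighted_median(instr, n_boot = 50, seed = 1)$estimate, 0.2)
  const <- make_instruments(rep(1, 5), rep(0.4, 5), se_exp = 0.005,
                            se_out = 0.01)
  wm <- mr_weighted_median(const, n_boot = 200, seed = 1)
  expect_equal(wm$estimate, 0.4)
  expect_lt(wm$se, 0.05)
  # majority-valid scenario: estimate stays near the valid ratio
  mix <- make_ratio_instruments(c(rep(0.5, 10), rep(2, 4)),
                                c(rep(10, 10), rep(1, 4)))
  expect_lt(abs(mr_weighted_median(mix, n_boot = 50, seed = 1)$estimate - 0.5),
            0.05)
  set.seed(302)
  for (i in 1:1000) {
    j <- sample(3:12, 1)
    ratios <- rnorm(j)
    weights <- runif(j, 0.1, 5)
    instr_i <- make_ratio_instruments(ratios, weights)
    rw <- instr_i$beta_out / instr_i$beta_exp
    ours <- mr_weighted_median(instr_i, n_boot = 2, seed = 1)$estimate
    expect_equal(ours, oracle_weighted_median(ratios, weights),
                 tolerance = 1e-12)
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  const <- make_ratio_instruments(rep(0.4, 4), rep(1, 4))
  m0 <- mr_weighted_mode(const, n_boot = 10, seed = 1)
  expect_equal(m0$estimate, 0.4)
  expect_equal(m0$se, 0)
  set.seed(303)
  cluster <- make_ratio_instruments(c(rnorm(12, 0.5, 0.01), rnorm(4, 2, 0.01)),
                                    c(rep(5, 12), rep(0.5, 4)))
  m1 <- mr_weighted_mode(cluster, n_boot = 10, seed = 1)
  expect_lt(abs(m1$estimate - 0.5), 0.05)
  # permutation invariance
  perm <- sample(nrow(cluster))
  shuffled <- instrument_set(as.data.frame(cluster)[perm, ])
  m2 <- mr_weighted_mode(shuffled, n_boot = 10, seed = 1)
  expect_equal(m2$estimate, m1$estimate, tolerance = 1e-12)
  expect_error(mr_weighted_mode(make_instruments(c(0.1, 0.2), c(0.1, 0.2))),
               ">= 3")
})

test_that("all estimators are invariant to joint sign flips of single SNPs", {
  set.seed(304)
  instr <- make_instruments(runif(8, 0.1, 0.4), rnorm(8, 0.15, 0.03),
                            se_out = 0.04)
  flipped_df <- as.data.frame(instr)
  flip <- c(2, 5, 7)
  flipped_df$beta_exp[flip] <- -flipped_df$beta_exp[flip]
  flipped_df$beta_out[flip] <- -flipped_df$beta_out[flip]
  flipped <- instrument_set(flipped_df)
  expect_equal(mr_ivw(flipped)$estimate, mr_ivw(instr)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$estimate, mr_egger(instr)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$intercept, mr_egger(instr)$intercept,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(flipped, n_boot = 2, seed = 1)$estimate,
               mr_weighted_median(instr, n_boot = 2, seed = 1)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(flipped, n_boot = 2, seed = 1)$estimate,
               mr_weighted_mode(instr, n_boot = 2, seed = 1)$estimate,
               tolerance = 1e-12)
})

test_that("Steiger filtering keeps instruments explaining more exposure variance", {
  df <- data.frame(snp = c("keep", "drop"), effect_allele = "A",
                   other_allele = "G",
                   beta_exp = c(0.20, 0.03), se_exp = c(0.014, 0.014),
                   pval_exp = 1e-10, n_exp = 10000,
                   beta_out = c(0.03, 0.20), se_out = c(0.014, 0.014),
                   pval_out = 0.5, n_out = 10000)
  res <- steiger_filter(instrument_set(df))
  expect_equal(res$instruments$snp, "keep")
  expect_true(res$verdicts$retained[1])
  expect_false(res$verdicts$retained[2])
  bad <- df; bad$n_exp <- NA
  expect_error(steiger_filter(instrument_set(bad)), "keep")
})

test_that("Steiger retains most true instruments of a simulated chain", {
  set.seed(305)
  retained <- replicate(20, {
    cfg <- sim_config(n_individuals = 5000, n_snps = 10, causal_effect = 0.3,
                      seed = NULL)
    pair <- simulate_two_sample_gwas(cfg, keep_samples = FALSE)
    s <- pair$exposure_stats; o <- pair$outcome_stats
    instr <- instrument_set(data.frame(
      snp = s$snp, effect_allele = s$effect_allele,
      other_allele = s$other_allele, beta_exp = s$beta, se_exp = s$se,
      pval_exp = s$pval, n_exp = s$n, beta_out = o$beta, se_out = o$se,
      pval_out = o$pval, n_out = o$n))
    mean(steiger_filter(instr)$verdicts$retained)
  })
  expect_gte(mean(retained), 0.9)
})

test_that("leave-one-out flags a constructed outlier and nothing else", {
  instr <- make_instruments(rep(0.3, 6), rep(0.15, 6), se_out = 0.02)
  loo_flat <- leave_one_out(instr)
  expect_equal(nrow(loo_flat), 6)
  full <- attr(loo_flat, "full")
  expect_true(all(abs(loo_flat$estimate - full$estimate) < 1e-10))
  # one outlier with huge leverage dominates the pooled estimate
  out_df <- as.data.frame(make_instruments(c(rep(0.3, 4), 0.3),
                                           c(0.012, 0.009, 0.012, 0.009, 0.9),
                                           se_out = c(rep(0.09, 4), 0.005)))
  loo <- leave_one_out(instrument_set(out_df))
  expect_true(loo$influential[loo$snp_removed == "rs5"])
})

test_that("single-instrument fits reduce to the Wald ratio", {
  instr <- make_instruments(0.4, 0.2, se_out = 0.05)
  fit <- mr_fit(instr, seed = 1, n_boot = 10)
  expect_equal(nrow(fit$estimates), 1)
  expect_equal(fit$estimates$method, "wald_ratio")
  expect_equal(unname(coef(fit)), 0.5)
})

test_that("IVW type-I error is near nominal under the null", {
  set.seed(306)
  reject <- replicate(400, {
    cfg <- sim_config(n_individuals = 1000, n_snps = 10, causal_effect = 0,
                      seed = NULL)
    pair <- simulate_two_sample_gwas(cfg, keep_samples = FALSE)
    s <- pair$exposure_stats; o <- pair$outcome_stats
    instr <- instrument_set(data.frame(
      snp = s$snp, effect_allele = s$effect_allele,
      other_allele = s$other_allele, beta_exp = s$beta, se_exp = s$se,
      pval_exp = s$pval, n_exp = s$n, beta_out = o$beta, se_out = o$se,
      pval_out = o$pval, n_out = o$n))
    mr_ivw(instr)$p < 0.05
  })
  rate <- mean(reject)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("weighted median resists pleiotropic contamination that biases IVW", {
  set.seed(307)
  truth <- 0.3
  res <- replicate(60, {
    j <- 20
    bx <- runif(j, 0.1, 0.3)
    alpha <- c(rep(0, 12), rnorm(8, 0.08, 0.01)) # 40% invalid, directional
    se_out <- rep(0.001, j)
    by <- truth * bx + alpha + rnorm(j, 0, se_out)
    instr <- make_instruments(bx, by, se_exp = 0.005, se_out = se_out)
    c(ivw = mr_ivw(instr)$estimate,
      med = mr_weighted_median(instr, n_boot = 2, seed = 1)$estimate)
  })
  med_bias <- mean(res["med", ]) - truth
  med_mc <- sd(res["med", ]) / sqrt(ncol(res))
  ivw_bias <- mean(res["ivw", ]) - truth
  ivw_mc <- sd(res["ivw", ]) / sqrt(ncol(res))
  expect_lt(abs(med_bias), 3 * med_mc + 0.01)
  expect_gt(abs(ivw_bias), 3 * ivw_mc)
})

test_that("harmonization aligns outcome alleles and logs exclusions", {
  set.seed(308)
  pair <- simulate_two_sample_gwas(sim_config(n_individuals = 3000,
                                              n_snps = 10,
                                              causal_effect = 0.3,
                                              seed = NULL))
  panel <- pair$samples$exposure$genotypes
  base <- harmonize_two_sample(pair$exposure_stats, pair$outcome_stats,
                               panel, instrument_p = 1e-4)
  expect_gt(nrow(base), 0)
  # swapping outcome alleles at one SNP negates its aligned effect
  swapped <- as.data.frame(pair$outcome_stats)
  target <- base$snp[1]
  i <- which(swapped$snp == target)
  swapped[i, c("effect_allele", "other_allele")] <-
    swapped[i, c("other_allele", "effect_allele")]
  swapped$beta[i] <- -swapped$beta[i]
  swapped$eaf[i] <- 1 - swapped$eaf[i]
  harm2 <- harmonize_two_sample(pair$exposure_stats,
                                gwas_sumstats(swapped, trait = "outcome"),
                                panel, instrument_p = 1e-4)
  expect_equal(harm2$beta_out[harm2$snp == target],
               base$beta_out[base$snp == target])
  # SNPs absent from the outcome are dropped and logged
  trimmed <- as.data.frame(pair$outcome_stats)
  trimmed <- trimmed[trimmed$snp != target, ]
  harm3 <- harmonize_two_sample(pair$exposure_stats,
                                gwas_sumstats(trimmed, trait = "outcome"),
                                panel, instrument_p = 1e-4)
  expect_false(target %in% harm3$snp)
  expect_true(target %in% attr(harm3, "log")$snp)
  # instruments exceed the exposure threshold by construction
  expect_true(all(base$pval_exp <= 1e-4))
})

test_that("mr_fit accessors behave like a fitted model object", {
  set.seed(309)
  instr <- make_instruments(runif(6, 0.1, 0.4), rnorm(6, 0.1, 0.02),
                            se_out = 0.03)
  fit <- mr_fit(instr, n_boot = 20, seed = 2)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), fit$estimates$method)
  ci <- confint(fit)
  expect_equal(nrow(ci), nrow(fit$estimates))
  expect_true(all(ci[, 1] < ci[, 2]))
  r <- residuals(fit)
  expect_length(r, 6)
  expect_output(print(summary(fit)), "Heterogeneity")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
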