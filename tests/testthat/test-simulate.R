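# synthetic GWAS generator: determinism, variance accounting, per-SNP
# regression fits, scenario-level behaviour

small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_exposure_sample = 3000,
               n_mediator_sample = 3000, n_outcome_sample = 3000,
               m_ea_snps = 15, m_med_snps = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("identical configs give byte-identical output; truth is conserved", {
  s1 <- simulate_cohort(small_cfg(seed = 11))
  s2 <- simulate_cohort(small_cfg(seed = 11))
  expect_identical(s1, s2)
  s3 <- simulate_cohort(small_cfg(seed = 12))
  expect_false(identical(s1$samples$exposure$data$ea,
                         s3$samples$exposure$data$ea))
  tr <- s1$truth
  expect_identical(tr$total, tr$direct + sum(tr$indirect))
  expect_identical(unname(tr$pm), unname(tr$indirect / tr$total))
})

test_that("SNP effects are scaled to the target heritability exactly", {
  # exposure-scale panel: 1271 SNPs explaining 11%, mean per-SNP R^2 = h2/m
  cfg <- sim_config(seed = 2, n_exposure_sample = 200,
                    n_mediator_sample = 200, n_outcome_sample = 200,
                    m_ea_snps = 1271, m_med_snps = 20, h2_ea = 0.11)
  tr <- simulate_cohort(cfg)$truth
  eff <- tr$snp_effects
  ea_rows <- eff$block == "EA"
  r2 <- 2 * eff$maf * (1 - eff$maf) * eff$beta_ea^2
  expect_equal(sum(r2[ea_rows]), 0.11, tolerance = 1e-12)
  expect_equal(mean(r2[ea_rows]), 0.11 / 1271, tolerance = 1e-12)
  expect_equal(sum(2 * eff$maf[!ea_rows] * (1 - eff$maf[!ea_rows]) *
                     eff$gamma_BMI[!ea_rows]^2),
               0.10, tolerance = 1e-12)
  # and the realised exposure variance is close to its unit budget
  big <- simulate_cohort(small_cfg(seed = 3, n_exposure_sample = 50000))
  expect_equal(var(big$samples$exposure$data$ea), 1, tolerance = 0.05)
})

test_that("the logistic intercept hits the target prevalence", {
  cfg <- sim_config(seed = 4, n_exposure_sample = 500,
                    n_mediator_sample = 500, n_outcome_sample = 2e5,
                    m_ea_snps = 15, m_med_snps = 5,
                    outcome_prevalence = 0.08)
  s <- simulate_cohort(cfg)
  expect_lt(abs(mean(s$samples$outcome$data$outcome) - 0.08), 0.005)
})

test_that("infeasible variance budgets are refused", {
  expect_error(sim_config(h2_ea = 0.9, conf_strength = c(0.5, 0.2, 0.2)),
               class = "twostepmr_config_error")
  expect_error(sim_config(outcome_prevalence = 0),
               class = "twostepmr_config_error")
  expect_error(sim_config(h2_med = 1.2), class = "twostepmr_config_error")
  expect_error(sim_config(alpha = c(M = 0.1), theta = c(0.1, 0.2)),
               class = "twostepmr_config_error")
})

test_that("per-SNP linear summaries match a hand-computed OLS slope", {
  # 6-individual toy: slope = Sxy/Sxx
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(1.0, 1.4, 2.1, 0.9, 1.6, 1.9)
  sample <- list(G = matrix(g, 6, 1, dimnames = list(NULL, "rs1")),
                 data = data.frame(y = y),
                 snp = data.frame(snp = "rs1", ea = "A", oa = "G",
                                  stringsAsFactors = FALSE))
  ss <- gwas_summarise(sample, "y")
  slope <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  expect_equal(ss$beta, slope)
  fit <- summary(lm(y ~ g))$coefficients        # independent route
  expect_equal(ss$beta, fit["g", "Estimate"], tolerance = 1e-12)
  expect_equal(ss$se, fit["g", "Std. Error"], tolerance = 1e-12)
  expect_equal(ss$pval, fit["g", "Pr(>|t|)"], tolerance = 1e-12)
  expect_equal(ss$eaf, mean(g) / 2)
})

test_that("per-SNP logistic summaries reproduce glm and behave at the null", {
  withr::with_seed(7, {
    n <- 800
    g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, plogis(-1.2 + 0.5 * g1))
  })
  sample <- list(G = cbind(rs1 = g1, rs2 = g2),
                 data = data.frame(y = y),
                 snp = data.frame(snp = c("rs1", "rs2"), ea = "A", oa = "G",
                                  stringsAsFactors = FALSE))
  ss <- gwas_summarise(sample, "y")
  for (i in 1:2) {
    fit <- summary(glm(y ~ g, family = binomial(),
                       data = data.frame(y = y, g = cbind(g1, g2)[, i])))
    expect_equal(ss$beta[i], fit$coefficients["g", "Estimate"],
                 tolerance = 1e-6)
    expect_equal(ss$se[i], fit$coefficients["g", "Std. Error"],
                 tolerance = 1e-6)
  }
  # null SNP: log-OR within 3 SE of zero
  expect_lt(abs(ss$beta[2]) / ss$se[2], 3)
})

test_that("null-trait p-values are uniform across many SNPs", {
  withr::with_seed(8, {
    n <- 400; m <- 2000
    G <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(NULL, paste0("rs", 1:m)))
    y <- rnorm(n)
  })
  sample <- list(G = G, data = data.frame(y = y),
                 snp = data.frame(snp = paste0("rs", 1:m), ea = "A", oa = "G",
                                  stringsAsFactors = FALSE))
  ss <- gwas_summarise(sample, "y")
  expect_gt(ks.test(ss$pval, "punif")$p.value, 0.01)
})

test_that("non-varying genotype columns are skipped with a message", {
  withr::with_seed(9, {
    G <- cbind(rs1 = rbinom(100, 2, 0.3), rs2 = rep(0L, 100))
    y <- rnorm(100)
  })
  sample <- list(G = G, data = data.frame(y = y),
                 snp = data.frame(snp = c("rs1", "rs2"), ea = "A", oa = "G",
                                  stringsAsFactors = FALSE))
  expect_message(ss <- gwas_summarise(sample, "y"), "non-varying")
  expect_identical(ss$snp, "rs1")
})

test_that("covariate adjustment residualises continuous traits", {
  s <- simulate_cohort(small_cfg(seed = 10, alpha = c(M1 = -0.4),
                                 theta = c(M1 = 0.6)))
  plain <- gwas_summarise(s$samples$mediator, "M1")
  adj <- gwas_summarise(s$samples$mediator, "M1", adjust_for = "ea")
  # adjusting for the exposure strips its instruments' effect on the mediator
  ea_ids <- s$truth$instruments$EA
  expect_lt(mean(abs(adj$beta[match(ea_ids, adj$snp)])),
            mean(abs(plain$beta[match(ea_ids, plain$snp)])))
  expect_error(gwas_summarise(s$samples$outcome, "outcome",
                              adjust_for = "ea"),
               class = "twostepmr_config_error")
})

test_that("the global null scenario centres the IVW estimate on zero", {
  zs <- vapply(1:8, function(i) {
    sc <- make_two_sample_scenario(
      small_cfg(seed = 100 + i, alpha = c(M1 = 0), theta = c(M1 = 0.5),
                direct = 0))
    h <- harmonise(restrict_snps_for_test(sc$stats$exposure,
                                          sc$truth$instruments$EA),
                   sc$stats$outcome)
    est <- mr_ivw(h)
    est$beta / est$se
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 / sqrt(8))
})

test_that("two-sample scenarios recover the true total effect", {
  devs <- vapply(1:10, function(i) {
    sc <- make_two_sample_scenario(small_cfg(seed = 200 + i))
    h <- harmonise(restrict_snps_for_test(sc$stats$exposure,
                                          sc$truth$instruments$EA),
                   sc$stats$outcome)
    mr_ivw(h)$beta - sc$truth$total
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.08)   # ~3 SD of the replicate mean
})

test_that("bidirectional scenarios are detected by reverse MR", {
  run_rev <- function(rev) {
    sc <- make_two_sample_scenario(
      small_cfg(seed = 41, reverse_beta = rev,
                n_exposure_sample = 12000))
    h <- harmonise(restrict_snps_for_test(sc$stats$mediators$BMI,
                                          sc$truth$instruments$BMI),
                   sc$stats$exposure)
    mr_ivw(h)
  }
  null_est <- run_rev(0)
  expect_lt(abs(null_est$beta / null_est$se), 3)
  rev_est <- run_rev(-0.15)
  expect_lt(rev_est$beta, 0)
  expect_gt(abs(rev_est$beta / rev_est$se), 3)
})

test_that("directional pleiotropy trips the Egger intercept while biasing IVW", {
  hit <- bias_ivw <- bias_egger <- numeric(12)
  for (i in 1:12) {
    sc <- make_two_sample_scenario(
      sim_config(seed = 300 + i, n_exposure_sample = 15000,
                 n_mediator_sample = 500, n_outcome_sample = 15000,
                 m_ea_snps = 30, m_med_snps = 5,
                 pleiotropy = "directional", pleiotropy_magnitude = 0.15,
                 pleiotropy_fraction = 0.5))
    h <- harmonise(restrict_snps_for_test(sc$stats$exposure,
                                          sc$truth$instruments$EA),
                   sc$stats$outcome)
    eg <- mr_egger(h)
    hit[i] <- eg$egger_intercept_pval < 0.05
    bias_ivw[i] <- mr_ivw(h)$beta - sc$truth$total
    bias_egger[i] <- eg$beta - sc$truth$total
  }
  expect_gt(mean(hit), 0.5)
  expect_gt(abs(mean(bias_ivw)), abs(mean(bias_egger)))
  expect_gt(mean(bias_ivw), 0.2)   # positive pleiotropy inflates IVW upward
})

test_that("recovered pm increases with the generating alpha", {
  mean_pm <- function(alpha, seeds) {
    mean(vapply(seeds, function(s) {
      sc <- make_two_sample_scenario(
        small_cfg(seed = s, alpha = c(M1 = alpha), theta = c(M1 = 0.6),
                  direct = -0.35, n_outcome_sample = 8000))
      res <- two_step_mediation(sc$stats$exposure, sc$stats$mediators,
                                sc$stats$outcome, sc$truth$instruments,
                                combinations = FALSE, sensitivity = FALSE,
                                seed = 1, n_boot = 10)
      res$individual$pm[res$individual$method == "product"]
    }, numeric(1)))
  }
  seeds <- 500:514
  expect_gt(mean_pm(-0.5, seeds), mean_pm(-0.2, seeds) + 0.1)
})
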