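test_that("identical seed and configuration reproduce the dataset bitwise", {
  cfg <- sim_config(n_individuals = 200, n_variants = 100, n_causal = 10,
                    L = 5, seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$phenotypes$value, s2$phenotypes$value)
  expect_identical(s1$truth$effects, s2$truth$effects)
})

test_that("allele frequencies and dosages follow the configured law", {
  set.seed(50)
  cfg <- sim_config(n_individuals = 500, n_variants = 4000, n_causal = 10)
  g <- simulate_genotypes(cfg)
  f <- attr(g, "freq")
  expect_gte(min(f), 0.01)                        # offset enforces the floor
  expect_equal(mean(f), 2 / 12 + 0.01, tolerance = 0.01)
  # per-variant dosage mean ~ 2f
  expect_equal(unname(colMeans(g$dosage)), 2 * f, tolerance = 0.12)
  # HWE goodness of fit holds for nearly all variants
  common <- which(f > 0.05 & f < 0.5)
  pvals <- vapply(sample(common, 300), function(v) {
    obs <- tabulate(g$dosage[, v] + 1, 3)
    fv <- f[v]
    expp <- c((1 - fv)^2, 2 * fv * (1 - fv), fv^2)
    suppressWarnings(stats::chisq.test(obs, p = expp)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.92)
})

test_that("effect draws follow the configured moments and L scaling", {
  set.seed(51)
  cfg1 <- sim_config(n_individuals = 10, n_variants = 12000, n_causal = 12000,
                     L = 1)
  eff <- simulate_effects(cfg1)$effects
  expect_equal(unname(colMeans(eff)), rep(10, 6), tolerance = 0.15)
  emp <- stats::cov(eff[, 1:3])
  expect_lt(max(abs(emp - cfg1$var_beta)), 0.6)
  emp_lt <- stats::cov(eff[, 4:6])
  expect_lt(max(abs(emp_lt - cfg1$var_beta)), 0.6)
  # L = 100: E(delta) = 0.1, var(delta) = var(beta)/100
  cfg2 <- sim_config(n_individuals = 10, n_variants = 12000, n_causal = 12000,
                     L = 100)
  eff2 <- simulate_effects(cfg2)$effects
  expect_lt(max(abs(colMeans(eff2[, 4:6]) - 0.1)), 0.015)   # ~3 MC SE
  expect_equal(unname(diag(stats::cov(eff2[, 4:6]))),
               unname(diag(cfg2$var_beta)) / 100, tolerance = 0.1)
  # background variants are ~1000-fold attenuated
  cfg3 <- sim_config(n_individuals = 10, n_variants = 5000, n_causal = 100)
  eff3 <- simulate_effects(cfg3)
  expect_equal(sum(eff3$causal), 100)
  expect_lt(max(abs(colMeans(eff3$effects[!eff3$causal, ]) - 0.01)), 0.01)
})

test_that("phenotype construction is exact when all noise is removed", {
  cfg <- sim_config(n_individuals = 50, n_variants = 20, n_causal = 5,
                    covariate_effects = c(2, 1.5, 3), seed = 7)
  set.seed(7)
  geno <- simulate_genotypes(cfg)
  truth <- list(effects = matrix(0, 20, 6), causal = rep(FALSE, 20))
  cfg_nores <- cfg
  cfg_nores$residual_cov <- diag(1e-20, 3)
  ph <- simulate_phenotypes(geno, truth, cfg_nores)
  expect_equal(ph$value,
               2 + 1.5 * ph$time + 3 * ph$covar, tolerance = 1e-6)
})

test_that("baseline variance decomposes into genetic plus residual parts", {
  cfg <- sim_config(n_individuals = 4000, n_variants = 3000, n_causal = 30,
                    L = 1, seed = 53)
  sim <- simulate_dataset(cfg)
  ph <- as.data.frame(sim$phenotypes)
  base <- ph[ph$time == 0 & ph$trait_id == "trait1", ]
  v_obs <- stats::var(base$value)
  v_exp <- sim$truth$vc$C["trait1:CS", "trait1:CS"] +
    cfg$covariate_effects[3]^2 + cfg$residual_cov[1, 1]
  expect_equal(v_obs, v_exp, tolerance = 0.12 * v_exp)
})

test_that("implied components match the analytic aggregate of effects", {
  cfg <- sim_config(n_individuals = 800, n_variants = 500, n_causal = 20,
                    L = 5, seed = 54)
  sim <- simulate_dataset(cfg)
  w <- apply(sim$genotypes$dosage, 2, stats::var)
  manual <- t(sim$truth$effects) %*% (sim$truth$effects * w)
  perm <- c(1, 4, 2, 5, 3, 6)
  expect_equal(unname(sim$truth$vc$C), unname(manual[perm, perm]),
               tolerance = 1e-6)
})

test_that("MAC filter default rule rejects sparse genotype-by-time cells", {
  set.seed(55)
  N <- 800
  intervals <- runif(N, 4, 9)
  zero <- matrix(0, N, 1)
  common <- matrix(rbinom(N, 2, 0.3) + 0.0, N)
  expect_false(apply_mac_filter(zero, intervals))
  expect_true(apply_mac_filter(common, intervals))
  # a variant with a single carrier in some year category fails
  rare <- matrix(0, N, 1); rare[1:4, 1] <- 1
  expect_false(apply_mac_filter(rare, intervals))
  # frequency-based readings
  expect_false(apply_mac_filter(zero, intervals, rule = "dosage_time"))
  expect_true(apply_mac_filter(common, intervals, rule = "dosage_time"))
  expect_true(apply_mac_filter(common, intervals, rule = "both"))
})

test_that("MAC pass rate matches the Beta(2,10)+0.01 frequency arithmetic", {
  set.seed(56)
  cfg <- sim_config(n_individuals = 3000, n_variants = 4000, n_causal = 10)
  g <- simulate_genotypes(cfg)
  intervals <- runif(3000, 4, 9)
  pass <- apply_mac_filter(g, intervals)
  expect_gt(mean(pass), 0.62)
  expect_lt(mean(pass), 0.74)
})

test_that("missingness injection drops what it should and only that", {
  cfg <- sim_config(n_individuals = 300, n_variants = 50, n_causal = 5, seed = 57)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  expect_identical(inject_missingness(ph, 0, trait = "trait3"), ph)
  # individuals mode: half the individuals lose both records of trait3
  m1 <- inject_missingness(ph, 0.5, mode = "individuals", trait = "trait3",
                           seed = 1)
  cnt <- table(as.data.frame(m1)$trait_id)
  expect_equal(unname(cnt[["trait3"]]), 300)       # 150 individuals x 2 records
  expect_equal(unname(cnt[["trait1"]]), 600)
  # records mode conserves the other traits' record counts
  m2 <- inject_missingness(ph, 0.15, mode = "records", trait = "trait3",
                           seed = 2)
  cnt2 <- table(as.data.frame(m2)$trait_id)
  expect_equal(unname(cnt2[["trait3"]]), 510)
  expect_equal(unname(cnt2[["trait1"]]), 600)
})
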