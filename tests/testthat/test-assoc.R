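test_that("null solutions equal the dense mixed-model solve", {
  set.seed(20)
  ph <- random_pheno(3, 1, miss_prob = 0)
  des <- build_design(ph)
  vc <- variance_components(random_spd(2), matrix(2), des$traits)
  ns <- build_null_system(des, vc)
  o <- dense_gls(des, vc)
  expect_lt(max(abs(ns$bhat - o$beta)), 1e-8)
  expect_lt(ns$null_residual, 1e-8)
  # fixed core dimension = sum of per-trait fixed-effect counts
  expect_equal(dim(ns$fixed_core_inv), c(sum(des$p_k), sum(des$p_k)))
})

test_that("zero phenotype vector gives zero null solutions", {
  df <- data.frame(individual_id = rep(sprintf("i%02d", 1:4), each = 2),
                   trait_id = "t1", time = rep(c(0, 5), 4), value = 0)
  des <- build_design(pheno_long(df))
  ns <- build_null_system(des, variance_components(diag(2), matrix(1), "t1"))
  expect_equal(max(abs(ns$bhat)), 0)
  expect_equal(max(abs(ns$uhat)), 0)
})

test_that("bordered per-variant estimates match dense GLS with the variant included", {
  set.seed(21)
  for (rep in 1:4) {
    K <- sample(1:3, 1); N <- sample(8:40, 1)
    ph <- random_pheno(N, K, miss_prob = 0.2)
    des <- build_design(ph)
    vc <- variance_components(random_spd(2 * K), random_spd(K), des$traits)
    ns <- build_null_system(des, vc)
    d <- rbinom(N, 2, 0.3) + 0.0; d[1] <- 1   # ensure polymorphic
    names(d) <- des$individuals
    o <- dense_gls(des, vc, dosages = d)
    res <- test_snp(ns, d)
    res <- res[order(match(res$trait, des$traits), res$effect), ]
    expect_lt(max(abs(res$beta - o$beta[1:(2 * K)]) / pmax(abs(o$beta[1:(2 * K)]), 1e-8)),
              1e-8)
    expect_lt(max(abs(res$se - o$se[1:(2 * K)]) / o$se[1:(2 * K)]), 1e-8)
  }
})

test_that("monomorphic variants are filtered, not errors", {
  set.seed(22)
  ph <- random_pheno(10, 2)
  des <- build_design(ph)
  vc <- variance_components(random_spd(4), random_spd(2), des$traits)
  ns <- build_null_system(des, vc)
  res <- test_snp(ns, stats::setNames(rep(0, 10), des$individuals))
  expect_true(all(res$filter_status == "failed_mac"))
  expect_true(all(is.na(res$beta)))
  # frequency floor removes rare variants
  d <- stats::setNames(c(1, rep(0, 9)), des$individuals)   # MAF 0.05
  g1 <- genotype_dosage(matrix(d, ncol = 1, dimnames = list(names(d), "v1")))
  s1 <- scan_genotypes(ns, g1, mac_min = 0, maf_min = 0.10)
  expect_false(s1$tested)
  s2 <- scan_genotypes(ns, g1, mac_min = 0, maf_min = 0.01)
  expect_true(s2$tested)
})

test_that("two-sided Wald p-values behave", {
  expect_equal(pvalue(0, 1), 1)
  expect_equal(pvalue(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(pvalue(3, 2), pvalue(-3, 2))
  expect_error(pvalue(1, 0), "positive")
  expect_gt(pvalue(1e6, 1), 0)                    # floored, never exactly 0
})

test_that("results are invariant to individual and variant permutations", {
  set.seed(23)
  cfg <- sim_config(n_individuals = 120, n_variants = 60, n_causal = 5, L = 2,
                    seed = 77)
  sim <- simulate_dataset(cfg)
  scan1 <- scan_simulated(sim, mac_min = 0)
  # permute individuals (rows) and variants (columns)
  G <- sim$genotypes$dosage
  pi_ <- sample(nrow(G)); pv <- sample(ncol(G))
  geno2 <- genotype_dosage(G[pi_, pv], sim$genotypes$info[pv, ])
  des <- build_design(sim$phenotypes)
  ns <- build_null_system(des, sim$truth$vc)
  scan2 <- scan_genotypes(ns, geno2, mac_min = 0)
  d1 <- as.data.frame(scan1); d2 <- as.data.frame(scan2)
  ord <- function(d) d[order(d$variant_id, d$trait, d$effect), ]
  d1 <- ord(d1); d2 <- ord(d2)
  expect_equal(d1$beta, d2$beta, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})

test_that("single-trait scan equals the joint engine at K = 1 and decouples", {
  set.seed(24)
  cfg <- sim_config(n_individuals = 150, n_variants = 40, n_causal = 4, L = 1,
                    seed = 31)
  sim <- simulate_dataset(cfg)
  vc <- sim$truth$vc
  joint1 <- single_trait_scan(sim$phenotypes, sim$genotypes, vc, "trait1",
                              mac_min = 0)
  # manual K=1 pipeline
  ph1 <- sim$phenotypes[sim$phenotypes$trait_id == "trait1", ]
  ph1 <- pheno_long(as.data.frame(ph1), covariates = "covar", traits = "trait1")
  ns1 <- build_null_system(build_design(ph1), vc_subset(vc, "trait1"))
  ref <- scan_genotypes(ns1, sim$genotypes, mac_min = 0)
  expect_equal(joint1$beta, ref$beta, tolerance = 1e-12)

  # near-zero cross-trait covariance: joint and single estimates agree closely
  C <- as.matrix(Matrix::bdiag(random_spd(2), random_spd(2), random_spd(2)))
  C <- C + diag(1e-6, 6)
  E <- diag(c(2, 3, 2.5))
  vc0 <- variance_components(C, E, paste0("trait", 1:3))
  des <- build_design(sim$phenotypes)
  nsj <- build_null_system(des, vc0)
  js <- scan_genotypes(nsj, sim$genotypes, mac_min = 0)
  ss <- single_trait_scan(sim$phenotypes, sim$genotypes, vc0, "trait2",
                          mac_min = 0)
  jd <- as.data.frame(js); jd <- jd[jd$trait == "trait2", ]
  sd_ <- as.data.frame(ss)
  ordk <- function(d) d[order(d$variant_id, d$effect), ]
  jd <- ordk(jd); sd_ <- ordk(sd_)
  expect_equal(jd$beta, sd_$beta, tolerance = 1e-6)
})

test_that("rate-of-change comparator computes rates and detects only strong CS-coupled signal", {
  # rate arithmetic
  df <- data.frame(individual_id = rep(sprintf("i%02d", 1:30), each = 2),
                   trait_id = "t1", time = rep(c(0, 4), 30),
                   value = rep(c(10, 14), 30) + rnorm(60, 0, 1e-3))
  res <- rate_of_change_gwas(pheno_long(df),
                             genotype_dosage(matrix(rbinom(30, 2, 0.4) + 0.0, 30,
                                                    dimnames = list(sprintf("i%02d", 1:30), "v1"))),
                             covariates = character(0))
  expect_equal(res$n_used, rep(30, nrow(res)))
  # constant phenotype: zero rates, no signal
  df2 <- df; df2$value <- rep(c(10, 10), 30)
  res2 <- rate_of_change_gwas(pheno_long(df2),
                              genotype_dosage(matrix(rbinom(30, 2, 0.4) + 0.0, 30,
                                                     dimnames = list(sprintf("i%02d", 1:30), "v1"))),
                              covariates = character(0))
  expect_true(all(res2$p > 0.9 | is.na(res2$p)))
})

test_that("rate-of-change hits are a subset of longitudinal-engine hits", {
  set.seed(25)
  cfg <- sim_config(n_individuals = 2000, n_variants = 300, n_causal = 30,
                    L = 1, seed = 99)
  sim <- simulate_dataset(cfg)
  scan <- scan_simulated(sim, mac_min = 0)
  roc <- rate_of_change_gwas(sim$phenotypes, sim$genotypes)
  thr <- 0.05 / 300
  roc_hits <- unique(roc$variant_id[roc$p < thr & !is.na(roc$p)])
  K <- 3
  joint_hits <- unique(sim$genotypes$info$variant_id[
    colSums(scan$p < thr, na.rm = TRUE) > 0])
  expect_gt(length(roc_hits), 0)
  expect_true(all(roc_hits %in% joint_hits))
})
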