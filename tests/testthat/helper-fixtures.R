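# Shared fixture builders: small random mixed-model instances and dense
# oracles the structured solvers are checked against.

random_spd <- function(m, scale = 1) {
  A <- matrix(rnorm(m * m), m)
  crossprod(A) / m * scale + diag(m) * 0.25 * scale
}

# random long-format phenotype with 2 time points and optional missingness
random_pheno <- function(N, K, miss_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  cv <- rnorm(N); names(cv) <- sprintf("i%03d", seq_len(N))
  for (i in seq_len(N)) {
    t2 <- runif(1, 4, 9)
    for (k in seq_len(K)) for (j in 1:2) {
      if (j == 2 && runif(1) < miss_prob) next
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("i%03d", i), trait_id = paste0("trait", k),
        time = if (j == 1) 0 else t2, value = rnorm(1),
        covar = cv[sprintf("i%03d", i)])
    }
  }
  pheno_long(do.call(rbind, rows))
}

# densified covariance of the trait-major random-effect stacking (k, i, c)
dense_G <- function(C, N) {
  K <- nrow(C) / 2
  G <- matrix(0, 2 * N * K, 2 * N * K)
  for (k in seq_len(K)) for (kp in seq_len(K)) for (i in seq_len(N))
    for (a in 1:2) for (b in 1:2)
      G[2 * N * (k - 1) + 2 * (i - 1) + a,
        2 * N * (kp - 1) + 2 * (i - 1) + b] <-
        C[2 * (k - 1) + a, 2 * (kp - 1) + b]
  G
}

# dense GLS oracle on the zero-padded system: V = Z G Z' + E x I_n
dense_gls <- function(design, vc, dosages = NULL) {
  dm <- design_matrices(design)
  X <- as.matrix(dm$X); Z <- as.matrix(dm$Z); y <- dm$y
  V <- Z %*% dense_G(vc$C, design$N) %*% t(Z) + vc$E %x% diag(dm$n)
  Vi <- solve(V)
  XF <- if (is.null(dosages)) X else {
    W <- as.matrix(build_snp_design(dosages, design)$W)
    cbind(W, X)
  }
  cf <- solve(t(XF) %*% Vi %*% XF)
  est <- drop(cf %*% t(XF) %*% Vi %*% y)
  list(beta = est, se = sqrt(diag(cf)), vcov = cf)
}

# truth-component engine run on one simulated dataset
scan_simulated <- function(sim, mac_min = 3) {
  des <- build_design(sim$phenotypes)
  ns <- build_null_system(des, sim$truth$vc)
  scan_genotypes(ns, sim$genotypes, mac_min = mac_min)
}

# model-based bivariate null data (no variants) for REML recovery tests
bivariate_model_data <- function(N, C0, E0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t2 <- runif(N, 4, 9); cv <- rnorm(N)
  u <- matrix(rnorm(N * 4), N) %*% chol(C0)
  rows <- list()
  for (j in 1:2) {
    tj <- if (j == 1) rep(0, N) else t2
    eps <- matrix(rnorm(N * 2), N) %*% chol(E0)
    for (k in 1:2) rows[[length(rows) + 1L]] <- data.frame(
      individual_id = sprintf("i%04d", seq_len(N)), trait_id = paste0("trait", k),
      time = tj, value = 1 + 0.5 * tj + 0.8 * cv + u[, 2 * k - 1] + u[, 2 * k] * tj +
        eps[, k],
      covar = cv)
  }
  pheno_long(do.call(rbind, rows))
}
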