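# Synthetic-data generator for power and type-I-error studies: independent
# variants with Beta(2,10)+0.01 allele frequencies and Hardy-Weinberg
# genotype sampling; causal multi-trait cross-sectional (CS) and longitudinal
# (LT) variant effects drawn from a multivariate normal with configurable
# LT:CS attenuation; background (infinitesimal) effects for all remaining
# variants; two time points per individual with a continuous 4-9 year
# interval; one standard-normal time-independent covariate; configurable
# missingness; and the genotype-by-time-category allele-count filter.

#' Genotype dosage container
#'
#' @param dosage individuals x variants matrix of dosages in `[0, 2]`;
#'   rownames are individual ids (required for alignment against designs).
#' @param info optional data.frame with columns `variant_id, chrom, pos,
#'   ref, alt`; synthesized when absent.
#' @export
genotype_dosage <- function(dosage, info = NULL) {
  stopifnot(is.matrix(dosage))
  V <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%05d", seq_len(V))
  if (is.null(info))
    info <- data.frame(variant_id = colnames(dosage), chrom = "1",
                       pos = seq_len(V), ref = "A", alt = "B",
                       stringsAsFactors = FALSE)
  stopifnot(nrow(info) == V)
  structure(list(dosage = dosage, info = info), class = "genotype_dosage")
}

as_genotype_dosage <- function(x) {
  if (inherits(x, "genotype_dosage")) return(x)
  if (is.matrix(x)) return(genotype_dosage(x))
  stop("cannot interpret object as genotype dosages")
}

#' Simulation configuration
#'
#' Defaults reproduce the evaluation design: K = 3 correlated traits, 10,000
#' variants of which 100 are causal, expected CS effect 10 with the fixed
#' 3 x 3 CS effect covariance, LT effects attenuated by the scalar `L >= 1`
#' (`E(delta) = E(beta)/L`, `var(delta) = var(beta)/L`, CS-LT effect
#' covariance fixed), residual covariance equal to the CS effect covariance,
#' allele frequencies Beta(2,10)+0.01, two time points with a continuous
#' Uniform(4, 9)-year interval, and one standard-normal time-independent
#' covariate with fixed-effect coefficients `(alpha0, alpha1, alpha2)`.
#' Background effects for non-causal variants come from
#' `MVN(mu/1000, Sigma/1000)`.
#'
#' @param n_individuals sample size N.
#' @param n_variants number of variants simulated per individual.
#' @param n_causal number of causal variants (drawn at random).
#' @param L LT attenuation scalar (>= 1); LT:CS ratio is 1/L.
#' @param mu_beta expected CS effect per causal variant.
#' @param var_beta K x K covariance of CS effects across traits.
#' @param covar_beta_delta K x K covariance between CS and LT effects.
#' @param residual_cov K x K residual covariance.
#' @param maf_beta shape parameters of the Beta allele-frequency draw.
#' @param maf_offset added to every frequency (minimum frequency).
#' @param time_range interval range (years) of the second time point.
#' @param covariate_effects `(alpha0, alpha1, alpha2)`: intercept, time
#'   slope, covariate effect.
#' @param background_scale divisor for non-causal effect moments (`mu/s`,
#'   `Sigma/s`); `Inf` gives exactly null background variants.
#' @param polygenic_cov optional 2K x 2K covariance for an additional
#'   model-based per-individual random intercept/slope component (used for
#'   pure-null calibration runs).
#' @param missing_fraction,missing_mode,missing_trait optional missingness
#'   injected after simulation (see [inject_missingness()]).
#' @param seed RNG seed applied by [simulate_dataset()].
#' @export
sim_config <- function(n_individuals,
                       n_variants = 10000L, n_causal = 100L,
                       L = 1,
                       mu_beta = 10,
                       var_beta = matrix(c(10, 8, -7, 8, 12, -1, -7, -1, 18), 3, 3),
                       covar_beta_delta = matrix(c(0.5, 0.4, -0.35,
                                                   0.4, 0.6, -0.05,
                                                   -0.35, -0.05, 0.9), 3, 3),
                       residual_cov = var_beta,
                       maf_beta = c(2, 10), maf_offset = 0.01,
                       time_range = c(4, 9),
                       covariate_effects = c(0, 1, 1),
                       background_scale = 1000,
                       polygenic_cov = NULL,
                       missing_fraction = 0,
                       missing_mode = "individuals",
                       missing_trait = NULL,
                       seed = NULL) {
  K <- nrow(as.matrix(var_beta))
  stopifnot(L >= 1, n_causal <= n_variants, n_individuals >= 1,
            length(time_range) == 2L, time_range[1] <= time_range[2],
            missing_fraction >= 0, missing_fraction < 1)
  var_beta <- as.matrix(var_beta)
  covar_beta_delta <- as.matrix(covar_beta_delta)
  residual_cov <- as.matrix(residual_cov)
  stopifnot(nrow(covar_beta_delta) == K, nrow(residual_cov) == K)
  Sigma <- rbind(cbind(var_beta, covar_beta_delta),
                 cbind(t(covar_beta_delta), var_beta / L))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("assembled effect covariance is not positive definite (eigenvalue %.3g)",
                 min(ev)))
  check_spd(residual_cov, "residual covariance")
  if (!is.null(polygenic_cov)) {
    polygenic_cov <- as.matrix(polygenic_cov)
    stopifnot(nrow(polygenic_cov) == 2L * K)
    check_spd(polygenic_cov, "polygenic covariance")
  }
  mu <- c(rep(mu_beta, K), rep(mu_beta / L, K))
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_variants = as.integer(n_variants), n_causal = as.integer(n_causal),
         K = K, L = L, mu = mu, Sigma = Sigma,
         var_beta = var_beta, covar_beta_delta = covar_beta_delta,
         residual_cov = residual_cov,
         maf_beta = maf_beta, maf_offset = maf_offset,
         time_range = time_range, covariate_effects = covariate_effects,
         background_scale = background_scale, polygenic_cov = polygenic_cov,
         missing_fraction = missing_fraction, missing_mode = missing_mode,
         missing_trait = missing_trait, seed = seed),
    class = "sim_config")
}

rmvn <- function(n, mu, Sigma) {
  Z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(Z %*% chol(Sigma), 2L, mu, "+")
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Frequencies are `Beta(shape1, shape2) + offset`; dosages 0/1/2 are drawn
#' independently per variant with probabilities
#' `{(1-f)^2, 2f(1-f), f^2}`.
#'
#' @param config a [sim_config()].
#' @return [genotype_dosage()] with attribute `freq` (the frequency draws).
#' @export
simulate_genotypes <- function(config) {
  N <- config$n_individuals; V <- config$n_variants
  f <- stats::rbeta(V, config$maf_beta[1], config$maf_beta[2]) + config$maf_offset
  # Hardy-Weinberg genotype counts per variant, then random placement
  p2 <- f^2; p1 <- 2 * f * (1 - f)
  n2 <- stats::rbinom(V, N, p2)
  n1 <- stats::rbinom(V, N - n2, ifelse(p2 < 1, p1 / (1 - p2), 0))
  G <- matrix(0, N, V)
  for (v in seq_len(V)) {
    nc <- n1[v] + n2[v]
    if (nc == 0L) next
    idx <- sample.int(N, nc)
    if (n1[v] > 0L) G[idx[seq_len(n1[v])], v] <- 1
    if (n2[v] > 0L) G[idx[n1[v] + seq_len(n2[v])], v] <- 2
  }
  rownames(G) <- sprintf("ind%06d", seq_len(N))
  g <- genotype_dosage(G)
  attr(g, "freq") <- f
  g
}

#' Simulate per-variant CS and LT effect vectors
#'
#' `n_causal` variants drawn at random receive `MVN(mu, Sigma)` effects; all
#' remaining variants receive infinitesimal background effects
#' `MVN(mu/background_scale, Sigma/background_scale)`.
#'
#' @param config a [sim_config()].
#' @return list with `effects` (V x 2K matrix, columns `beta_1..K` then
#'   `delta_1..K`) and `causal` (logical V).
#' @export
simulate_effects <- function(config) {
  V <- config$n_variants; K <- config$K
  causal <- logical(V)
  causal[sample.int(V, config$n_causal)] <- TRUE
  eff <- matrix(0, V, 2L * K)
  if (config$n_causal > 0)
    eff[causal, ] <- rmvn(config$n_causal, config$mu, config$Sigma)
  nbg <- V - config$n_causal
  if (nbg > 0 && is.finite(config$background_scale))
    eff[!causal, ] <- rmvn(nbg, config$mu / config$background_scale,
                           config$Sigma / config$background_scale)
  colnames(eff) <- c(paste0("beta_", seq_len(K)), paste0("delta_", seq_len(K)))
  list(effects = eff, causal = causal)
}

#' Simulate longitudinal phenotypes from genotypes and effects
#'
#' Two time points per individual (baseline 0 and a Uniform interval), one
#' standard-normal time-independent covariate, value
#' `alpha0 + alpha1*t + alpha2*Cov + sum_r beta_r g_r + t * sum_r delta_r g_r
#'  (+ optional model-based polygenic term) + eps`, residuals drawn
#' independently per (individual, time) from `MVN(0, residual_cov)`.
#'
#' @param genotypes a [genotype_dosage()].
#' @param truth result of [simulate_effects()].
#' @param config a [sim_config()].
#' @return A [pheno_long()] table; attribute `intervals` holds each
#'   individual's second time point.
#' @export
simulate_phenotypes <- function(genotypes, truth, config) {
  N <- config$n_individuals; K <- config$K
  G <- genotypes$dosage
  t2 <- stats::runif(N, config$time_range[1], config$time_range[2])
  covar <- stats::rnorm(N)
  a <- config$covariate_effects
  gv <- G %*% truth$effects                                       # N x 2K
  u <- gv[, seq_len(K), drop = FALSE]
  slope <- gv[, K + seq_len(K), drop = FALSE]
  if (!is.null(config$polygenic_cov)) {
    pg <- rmvn(N, numeric(2L * K), config$polygenic_cov)
    u <- u + pg[, seq(1L, 2L * K, 2L), drop = FALSE]
    slope <- slope + pg[, seq(2L, 2L * K, 2L), drop = FALSE]
  }
  chE <- chol(config$residual_cov)
  eps1 <- matrix(stats::rnorm(N * K), N) %*% chE
  eps2 <- matrix(stats::rnorm(N * K), N) %*% chE
  y1 <- a[1] + a[3] * covar + u + eps1
  y2 <- a[1] + a[2] * t2 + a[3] * covar + u + slope * t2 + eps2
  ids <- rownames(G)
  df <- data.frame(
    individual_id = rep(ids, times = 2L * K),
    trait_id = rep(rep(paste0("trait", seq_len(K)), each = N), 2L),
    time = c(rep(0, N * K), rep(t2, K)),
    value = c(as.vector(y1), as.vector(y2)),
    covar = rep(covar, 2L * K),
    stringsAsFactors = FALSE)
  ph <- pheno_long(df, covariates = "covar")
  attr(ph, "intervals") <- stats::setNames(t2, ids)
  ph
}

#' Implied aggregate polygenic covariance of a simulated dataset
#'
#' The per-individual random intercept/slope the analysis model fits absorbs
#' the aggregate of all variant effects, so the generating ("truth")
#' components are `C = sum_r var(g_r) a_r a_r'` (arranged trait-interleaved
#' CS/LT, using realized dosage variances) plus any model-based polygenic
#' term, and `E = residual_cov`.
#'
#' @param genotypes,truth,config as in [simulate_phenotypes()].
#' @return A [variance_components()] object.
#' @export
implied_components <- function(genotypes, truth, config) {
  K <- config$K
  w <- matrixStats_colSds(genotypes$dosage)^2
  Craw <- crossprod(truth$effects, truth$effects * w)   # beta/delta-blocked
  perm <- as.vector(rbind(seq_len(K), K + seq_len(K)))  # -> CS/LT interleaved
  C <- Craw[perm, perm]
  if (!is.null(config$polygenic_cov)) C <- C + config$polygenic_cov
  variance_components(pd_repair(C)$m, config$residual_cov,
                      paste0("trait", seq_len(K)))
}

#' Simulate a complete dataset
#'
#' Genotypes, effects, phenotypes, optional missingness, and the implied
#' variance components, under a single seed for bitwise reproducibility.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`: `genotypes`, `phenotypes`, `truth`
#'   (`effects`, `causal`, `freq`, `vc`), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  geno <- simulate_genotypes(config)
  truth <- simulate_effects(config)
  pheno <- simulate_phenotypes(geno, truth, config)
  if (config$missing_fraction > 0) {
    tr <- config$missing_trait
    if (is.null(tr)) tr <- paste0("trait", config$K)
    pheno <- inject_missingness(pheno, config$missing_fraction,
                                mode = config$missing_mode, trait = tr)
  }
  truth$freq <- attr(geno, "freq")
  truth$vc <- implied_components(geno, truth, config)
  structure(list(genotypes = geno, phenotypes = pheno, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Minor-allele-count filter over genotype-by-time categories
#'
#' Default rule (`"geno_time_cells"`): a variant is tested only if every
#' carrier genotype class (dosage 1 and dosage 2) contains at least
#' `min_count` individuals within every follow-up-interval category
#' (intervals rounded to whole years). Alternative frequency readings:
#' `"dosage_time"` requires the minor-allele frequency of the dosage-by-time
#' product vector to exceed `min_count / N`; `"both"` additionally requires a
#' plain minor-allele count of `min_count`.
#'
#' @param geno [genotype_dosage()] or dosage matrix.
#' @param intervals numeric vector of follow-up intervals (years), one per
#'   individual, aligned with the dosage rows.
#' @param min_count minimum count per category (default 3).
#' @param rule filter reading (see above).
#' @param G2 optional precomputed elementwise square of the dosage matrix
#'   (shared with the scan to avoid a large temporary).
#' @return logical vector, `TRUE` for variants passing.
#' @export
apply_mac_filter <- function(geno, intervals,
                             min_count = 3,
                             rule = c("geno_time_cells", "dosage_time", "both"),
                             G2 = NULL) {
  rule <- match.arg(rule)
  G <- if (inherits(geno, "genotype_dosage")) geno$dosage else geno
  N <- nrow(G)
  stopifnot(length(intervals) == N)
  if (rule == "geno_time_cells") {
    yr <- round(intervals)
    uy <- sort(unique(yr))
    Y <- outer(yr, uy, "==") + 0                     # N x categories
    if (is.null(G2)) G2 <- G * G
    s1 <- crossprod(Y, G)                            # n1 + 2 n2 per cell
    s2 <- crossprod(Y, G2)                           # n1 + 4 n2 per cell
    cnt2 <- (s2 - s1) / 2                            # hom-alt individuals
    cnt1 <- 2 * s1 - s2                              # het individuals
    pass <- colSums(cnt1 < min_count) == 0 & colSums(cnt2 < min_count) == 0
    return(unname(pass))
  }
  ac <- colSums(G)
  freq_t <- colSums(G * intervals) / (2 * sum(intervals))
  pass_t <- pmin(freq_t, 1 - freq_t) > min_count / N
  if (rule == "dosage_time") return(unname(pass_t))
  mac <- pmin(ac, 2 * N - ac)
  unname(pass_t & mac >= min_count)
}

#' Inject missingness into a phenotype table
#'
#' `mode = "records"` drops a random fraction of the target trait's rows;
#' `mode = "individuals"` drops all of the target trait's rows (baseline and
#' follow-up) for a random fraction of individuals. Individuals left with no
#' records at all, or without any baseline record, are removed entirely
#' (reported via attribute `n_individuals_dropped`).
#'
#' @param pheno a [pheno_long()] table.
#' @param fraction fraction in `[0, 1)`.
#' @param mode `"records"` or `"individuals"`.
#' @param trait trait to make missing.
#' @param seed optional seed for standalone reproducibility.
#' @export
inject_missingness <- function(pheno, fraction,
                               mode = c("records", "individuals"),
                               trait, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pheno, "pheno_long"), fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  traits <- attr(pheno, "traits")
  if (!trait %in% traits) stop("unknown trait: ", trait)
  if (fraction == 0) return(pheno)
  df <- as.data.frame(pheno)
  tr_rows <- which(df$trait_id == trait)
  drop <- if (mode == "records") {
    sample(tr_rows, round(fraction * length(tr_rows)))
  } else {
    ids <- unique(df$individual_id[tr_rows])
    sel <- sample(ids, round(fraction * length(ids)))
    tr_rows[df$individual_id[tr_rows] %in% sel]
  }
  out <- df[-drop, , drop = FALSE]
  # individuals must keep a baseline record somewhere
  base_ok <- tapply(out$time, out$individual_id, function(t) any(t == 0))
  bad <- names(base_ok)[!base_ok]
  if (length(bad)) {
    message(length(bad), " individual(s) dropped entirely (no baseline record left)")
    out <- out[!out$individual_id %in% bad, , drop = FALSE]
  }
  res <- pheno_long(out, covariates = attr(pheno, "covariates"), traits = traits)
  attr(res, "intervals") <- attr(pheno, "intervals")
  attr(res, "n_individuals_dropped") <- length(bad)
  res
}
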