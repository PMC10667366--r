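# Construction of the multi-trait longitudinal design: the stacked phenotype
# vector, per-trait fixed-effect and random intercept/slope incidence
# matrices, the Kronecker residual precision and the structured genetic
# precision, with zero-row handling for records missing in some traits.

#' Long-format repeated-measures phenotype table
#'
#' Validates and classes a tidy table with one row per (individual, trait,
#' time) measurement. Times are years from baseline; every individual must
#' have a baseline (time 0) record for at least one trait. Covariate columns
#' may be time-dependent (vary across an individual's rows) or
#' time-independent (constant per individual).
#'
#' @param data data.frame with columns `individual_id`, `trait_id`, `time`,
#'   `value`, plus optional covariate columns.
#' @param covariates character vector naming covariate columns (default: all
#'   non-reserved columns).
#' @param traits optional trait ordering; default sorted unique `trait_id`.
#' @return `data` with class `pheno_long` and attributes `traits`,
#'   `covariates`.
#' @export
pheno_long <- function(data, covariates = NULL, traits = NULL) {
  data <- as.data.frame(data)
  req <- c("individual_id", "trait_id", "time", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (is.null(covariates)) covariates <- setdiff(names(data), req)
  absent <- setdiff(covariates, names(data))
  if (length(absent)) stop("covariate columns absent from data: ",
                           paste(absent, collapse = ", "))
  data$individual_id <- as.character(data$individual_id)
  data$trait_id <- as.character(data$trait_id)
  if (any(!is.finite(data$time)) || any(data$time < 0))
    stop("times must be finite, non-negative years from baseline")
  if (anyNA(data$value))
    stop("NA phenotype values: drop the rows of missing records instead")
  key <- paste(data$individual_id, data$trait_id, data$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual, trait, time) records: e.g. ",
         gsub("\r", "/", key[duplicated(key)][1L]))
  if (is.null(traits)) traits <- sort(unique(data$trait_id))
  if (!all(data$trait_id %in% traits)) stop("trait_id outside declared traits")
  structure(data, traits = traits, covariates = covariates,
            class = c("pheno_long", "data.frame"))
}

#' Build the multi-trait longitudinal design
#'
#' Rows are aligned across traits: the row set is the union over traits of
#' observed (individual, time) slots, stacked trait-major. Slots missing for a
#' trait are kept as all-zero rows in the phenotype vector, the fixed-effects
#' matrix and the random intercept/slope matrix, so that all K per-trait
#' blocks have `n` rows (`n` = total union slots) and the same row index
#' addresses the same (individual, time) everywhere. Each individual's
#' random-effect block per trait is a `q_i x 2` matrix `[1, t]` with the
#' baseline time interval 0.
#'
#' Continuous covariates are centred and scaled to unit variance over
#' observed rows; 0/1 indicator covariates are left as is. Every trait's
#' fixed effects always include an intercept and a time slope.
#'
#' @param pheno a [pheno_long()] table.
#' @param fixed_effects named list (per trait) of covariate names, or a single
#'   character vector recycled to all traits. Default: all covariates.
#' @param scale_covariates center/scale continuous covariates.
#' @return An object of class `design_set`.
#' @export
build_design <- function(pheno, fixed_effects = NULL, scale_covariates = TRUE) {
  stopifnot(inherits(pheno, "pheno_long"))
  traits <- attr(pheno, "traits")
  K <- length(traits)
  covs <- attr(pheno, "covariates")
  if (is.null(fixed_effects)) fixed_effects <- covs
  if (!is.list(fixed_effects))
    fixed_effects <- stats::setNames(rep(list(fixed_effects), K), traits)
  if (is.null(names(fixed_effects))) names(fixed_effects) <- traits
  for (k in traits) {
    bad <- setdiff(fixed_effects[[k]], covs)
    if (length(bad)) stop("fixed-effect covariate not present for trait ", k,
                          ": ", paste(bad, collapse = ", "))
  }

  ids <- unique(pheno$individual_id)
  has_baseline <- tapply(pheno$time, pheno$individual_id, function(t) any(t == 0))
  no_base <- names(has_baseline)[!has_baseline]
  if (length(no_base))
    stop("individual(s) with no baseline (time 0) record: ",
         paste(utils::head(no_base, 5L), collapse = ", "))

  # covariate scaling statistics over observed rows
  cov_center <- cov_scale <- stats::setNames(numeric(length(covs)), covs)
  for (cv in covs) {
    v <- pheno[[cv]]
    if (all(v %in% c(0, 1), na.rm = TRUE)) { cov_center[cv] <- 0; cov_scale[cv] <- 1 }
    else if (scale_covariates) {
      cov_center[cv] <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      cov_scale[cv] <- if (is.finite(s) && s > 0) s else 1
    } else { cov_center[cv] <- 0; cov_scale[cv] <- 1 }
  }

  trait_idx <- match(pheno$trait_id, traits)
  ind_idx <- match(pheno$individual_id, ids)
  N <- length(ids)

  # union time slots per individual
  times <- vector("list", N)
  sp <- split(pheno$time, ind_idx)
  for (i in seq_len(N)) times[[i]] <- sort(unique(sp[[as.character(i)]]))
  qs <- lengths(times)
  n <- sum(qs)                      # records per trait after zero-fill
  off <- c(0L, cumsum(qs))          # within-trait row offset per individual

  slot <- integer(nrow(pheno))
  for (r in seq_len(nrow(pheno)))
    slot[r] <- match(pheno$time[r], times[[ind_idx[r]]])

  p_k <- vapply(traits, function(k) 2L + length(fixed_effects[[k]]), integer(1))
  xcols <- lapply(traits, function(k) c("(Intercept)", "time", fixed_effects[[k]]))
  names(xcols) <- traits

  # per-individual ragged containers
  obs <- lapply(seq_len(N), function(i) matrix(FALSE, K, qs[i]))
  y <- lapply(seq_len(N), function(i) matrix(0, K, qs[i]))
  Xi <- lapply(seq_len(N), function(i)
    lapply(seq_len(K), function(k) matrix(0, qs[i], p_k[k])))
  covmat <- if (length(covs))
    sweep(sweep(as.matrix(pheno[, covs, drop = FALSE]), 2L, cov_center, "-"),
          2L, cov_scale, "/") else matrix(0, nrow(pheno), 0L)
  fe_idx <- lapply(traits, function(k) match(fixed_effects[[k]], covs))
  tvec <- pheno$time; vvec <- pheno$value
  for (r in seq_len(nrow(pheno))) {
    i <- ind_idx[r]; k <- trait_idx[r]; s <- slot[r]
    obs[[i]][k, s] <- TRUE
    y[[i]][k, s] <- vvec[r]
    row <- c(1, tvec[r], covmat[r, fe_idx[[k]]])
    if (anyNA(row)) stop("NA covariate/value at observed record for individual ",
                         ids[i], ", trait ", traits[k])
    Xi[[i]][[k]][s, ] <- row
  }

  structure(
    list(traits = traits, K = K, individuals = ids, N = N,
         times = times, q = qs, n = n, offsets = off,
         obs = obs, y = y, X = Xi, p_k = p_k, x_columns = xcols,
         fixed_effects = fixed_effects,
         cov_center = cov_center, cov_scale = cov_scale),
    class = "design_set")
}

#' Row index of a (individual, trait, time) record in the trait-major stacking
#' @param design a `design_set`.
#' @export
record_index <- function(design) {
  rows <- lapply(seq_len(design$N), function(i) {
    q <- design$q[i]
    data.frame(individual_id = design$individuals[i],
               slot = seq_len(q), time = design$times[[i]],
               within_trait_row = design$offsets[i] + seq_len(q))
  })
  base <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(seq_len(design$K), function(k) {
    d <- base
    d$trait_id <- design$traits[k]
    d$row <- (k - 1L) * design$n + d$within_trait_row
    obs <- logical(nrow(d))
    for (r in seq_len(nrow(d))) {
      i <- match(d$individual_id[r], design$individuals)
      obs[r] <- design$obs[[i]][k, d$slot[r]]
    }
    d$observed <- obs
    d
  }))
  rownames(out) <- NULL
  out[, c("individual_id", "trait_id", "time", "row", "observed")]
}

#' Materialize the stacked y, X and Z matrices
#'
#' Returns the trait-major stacked phenotype vector, the block-diagonal
#' fixed-effects matrix `I %x% X_k` and the block-diagonal random
#' intercept/slope matrix (each trait block `n x 2N`), as sparse matrices.
#' Intended for small problems (oracles, inspection); the association engine
#' works from the per-individual representation.
#'
#' @param design a `design_set`.
#' @export
design_matrices <- function(design) {
  K <- design$K; n <- design$n; N <- design$N
  yv <- numeric(n * K)
  Xk <- vector("list", K); Zk <- vector("list", K)
  for (k in seq_len(K)) {
    Xmat <- matrix(0, n, design$p_k[k])
    Ztrip <- list(i = integer(0), j = integer(0), x = numeric(0))
    for (i in seq_len(design$N)) {
      rows <- design$offsets[i] + seq_len(design$q[i])
      Xmat[rows, ] <- design$X[[i]][[k]]
      yv[(k - 1L) * n + rows] <- design$y[[i]][k, ]
      ob <- design$obs[[i]][k, ]
      t_i <- design$times[[i]]
      Ztrip$i <- c(Ztrip$i, rows[ob], rows[ob])
      Ztrip$j <- c(Ztrip$j, rep(2L * i - 1L, sum(ob)), rep(2L * i, sum(ob)))
      Ztrip$x <- c(Ztrip$x, rep(1, sum(ob)), t_i[ob])
    }
    Xk[[k]] <- Xmat
    Zk[[k]] <- Matrix::sparseMatrix(i = Ztrip$i, j = Ztrip$j, x = Ztrip$x,
                                    dims = c(n, 2L * N))
  }
  X <- Matrix::bdiag(lapply(Xk, Matrix::Matrix, sparse = TRUE))
  Z <- Matrix::bdiag(Zk)
  missing_mask <- !unlist(lapply(seq_len(K), function(k)
    unlist(lapply(seq_len(design$N), function(i) design$obs[[i]][k, ]))))
  list(y = yv, X = X, Z = Z, n = n, missing_mask = missing_mask)
}

#' Residual precision `E^{-1} %x% I_n` in Kronecker-factored form
#'
#' @param E K x K symmetric positive definite residual covariance.
#' @param n records per trait.
#' @return A [kron_factors()] object holding `E^{-1}` (never densified).
#' @export
build_R_inverse <- function(E, n) {
  E <- as.matrix(E)
  check_spd(E, "residual covariance E")
  kron_inverse(kron_factors(E, n))
}

#' Structured genetic precision from the CS/LT covariance C
#'
#' `G^{-1}` has (k,k') super-blocks `I_N %x% C^{kk'}` where `C^{kk'}` is the
#' 2x2 block of `C^{-1}` for traits k, k'. Under the individual-major
#' permutation this is `I_N %x% C^{-1}` with contiguous 2K x 2K atomic blocks,
#' which is the layout the recursive inversion consumes.
#'
#' @param C 2K x 2K genetic covariance among CS and LT effects of all traits
#'   (per-trait interleaved layout: rows 2k-1, 2k are trait k's CS and LT).
#' @param N number of individuals.
#' @return Object of class `g_inverse` with elements `Cinv`, `N`, `K`.
#' @export
build_G_inverse <- function(C, N) {
  C <- as.matrix(C)
  check_spd(C, "genetic covariance C")
  structure(list(Cinv = solve(C), N = as.integer(N), K = nrow(C) %/% 2L),
            class = "g_inverse")
}

#' 2x2 super-block `C^{kk'}` of the genetic precision
#' @param g a `g_inverse` object.
#' @param k,kp trait indices.
#' @export
g_inverse_superblock <- function(g, k, kp) {
  g$Cinv[(2L * k - 1L):(2L * k), (2L * kp - 1L):(2L * kp), drop = FALSE]
}

#' Individual-major block representation of `G^{-1}`
#' @param g a `g_inverse` object.
#' @export
g_inverse_block_matrix <- function(g) {
  m <- block_matrix(rep(2L * g$K, g$N), inner_block_order = 2L * g$K)
  for (i in seq_len(g$N)) bm_set_block(m, i, i, g$Cinv)
  m
}

check_spd <- function(m, what) {
  if (max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m))))
    stop(what, " is not symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3g)",
                 what, min(ev)))
  invisible(TRUE)
}

#' Per-variant design block `W = I %x% W_k`
#'
#' For one variant, each trait's `W_k` has the individual's dosage repeated
#' over their rows in column 1 and column 1 multiplied by time in column 2;
#' rows zeroed in the phenotype design are zeroed here as well.
#'
#' @param dosages named (or design-ordered) numeric vector of dosages in
#'   `[0, 2]`, one per retained individual.
#' @param design a `design_set`.
#' @return Object of class `snp_design`: sparse `W` plus the dosage vector.
#' @export
build_snp_design <- function(dosages, design) {
  d <- align_dosages(dosages, design)
  n <- design$n; K <- design$K
  Wk <- vector("list", K)
  for (k in seq_len(K)) {
    Wmat <- matrix(0, n, 2L)
    for (i in seq_len(design$N)) {
      rows <- design$offsets[i] + seq_len(design$q[i])
      ob <- design$obs[[i]][k, ]
      Wmat[rows[ob], 1L] <- d[i]
      Wmat[rows[ob], 2L] <- d[i] * design$times[[i]][ob]
    }
    Wk[[k]] <- Matrix::Matrix(Wmat, sparse = TRUE)
  }
  structure(list(W = Matrix::bdiag(Wk), dosages = d), class = "snp_design")
}

align_dosages <- function(dosages, design) {
  if (!is.null(names(dosages))) {
    miss <- setdiff(design$individuals, names(dosages))
    if (length(miss)) stop("dosage missing for individual(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    dosages <- dosages[design$individuals]
  }
  if (length(dosages) != design$N)
    stop("need one dosage per retained individual")
  if (any(!is.finite(dosages)) || any(dosages < 0 | dosages > 2))
    stop("dosages must lie in [0, 2]")
  as.numeric(dosages)
}
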