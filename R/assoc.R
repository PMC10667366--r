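# The association engine: precompute the transformed null mixed-model system
# once, then test each variant by bordering it with the variant's 2K
# cross-sectional/longitudinal equations and solving only for those.
#
# Everything reduces to per-individual quantities. With the residual
# precision E^{-1} %x% I_n and the genetic precision I_N %x% C^{-1}, the
# random-effects coefficient block Z'R^{-1}Z + G^{-1} decouples into one
# 2K x 2K atomic block per individual under the individual-major permutation,
# which is exactly the structure the recursive-partitioning inversion
# consumes. The bordered Schur system for a variant with dosage vector g then
# collapses to
#   S(g)  = sum_i g_i^2 (A_i - A_i B_i A_i) - Kbar(g) F Kbar(g)',
#   r(g)  = sum_i g_i h_i,   Kbar(g) = sum_i g_i (BX_i - A_i B_i BX_i),
# with per-individual precomputed blocks, so a whole genotype matrix is
# scanned with a handful of BLAS products plus batched 2K x 2K solves.

#' Variance components container
#'
#' @param C 2K x 2K genetic covariance among cross-sectional (CS) and
#'   longitudinal (LT) effects of all traits; rows/cols ordered
#'   (trait1:CS, trait1:LT, trait2:CS, ...).
#' @param E K x K residual covariance between traits.
#' @param traits trait names (length K).
#' @param provenance optional record of how entries were assembled.
#' @export
variance_components <- function(C, E, traits, provenance = NULL) {
  C <- as.matrix(C); E <- as.matrix(E)
  K <- length(traits)
  stopifnot(nrow(C) == 2L * K, nrow(E) == K)
  check_spd(C, "genetic covariance C")
  check_spd(E, "residual covariance E")
  lab <- as.vector(t(outer(traits, c("CS", "LT"), paste, sep = ":")))
  dimnames(C) <- list(lab, lab); dimnames(E) <- list(traits, traits)
  structure(list(C = C, E = E, traits = traits, provenance = provenance),
            class = "variance_components")
}

#' Restrict variance components to a subset of traits
#' @param vc a [variance_components()] object.
#' @param traits trait names to keep.
#' @export
vc_subset <- function(vc, traits) {
  kk <- match(traits, vc$traits)
  if (anyNA(kk)) stop("unknown trait(s): ", paste(traits[is.na(kk)], collapse = ", "))
  ridx <- as.vector(rbind(2L * kk - 1L, 2L * kk))
  variance_components(vc$C[ridx, ridx, drop = FALSE],
                      vc$E[kk, kk, drop = FALSE], traits)
}

#' Precompute the transformed null system
#'
#' Builds the mixed-model equations for the null (no-variant) model, inverts
#' the random-effects block `Z'R^{-1}Z + G^{-1}` with
#' [recursive_partition_inverse()], pre-multiplies the system so that block
#' becomes an identity, and stores the null solutions together with the small
#' dense inverse of the fixed-effects core — everything a per-variant test
#' reuses.
#'
#' @param design a [build_design()] result.
#' @param vc a [variance_components()] object for the design's traits.
#' @return Object of class `null_system`.
#' @export
build_null_system <- function(design, vc) {
  stopifnot(inherits(design, "design_set"), inherits(vc, "variance_components"))
  if (!identical(design$traits, vc$traits))
    stop("variance components traits do not match design traits")
  K <- design$K; N <- design$N
  m <- 2L * K
  p_k <- design$p_k; p <- sum(p_k)
  Einv <- solve(vc$E)
  rk <- rep(seq_len(K), each = 2L)              # trait index of CS/LT rows
  ck <- rep(seq_len(K), times = p_k)            # trait index of fixed-effect cols
  EW_A <- Einv[rk, rk]                          # weights for A blocks
  EW_BX <- Einv[rk, ck, drop = FALSE]
  EW_XX <- Einv[ck, ck, drop = FALSE]
  Ey <- Einv[rk, , drop = FALSE]
  Eyx <- Einv[ck, , drop = FALSE]

  Amat <- matrix(0, m * m, N)
  BXmat <- matrix(0, m * p, N)
  cmat <- matrix(0, m, N)
  M11 <- matrix(0, p, p)
  r1 <- numeric(p)

  Msys <- block_matrix(rep(m, N), inner_block_order = m, symmetric = TRUE)
  Cinv <- solve(vc$C)

  for (i in seq_len(N)) {
    q <- design$q[i]
    Ti <- cbind(1, design$times[[i]])
    U <- matrix(0, q, m)
    for (k in seq_len(K)) {
      ob <- design$obs[[i]][k, ]
      if (any(ob)) U[ob, (2L * k - 1L):(2L * k)] <- Ti[ob, , drop = FALSE]
    }
    Xall <- do.call(cbind, design$X[[i]])       # q x p
    yt <- t(design$y[[i]])                      # q x K
    A_i <- crossprod(U) * EW_A
    BX_i <- crossprod(U, Xall) * EW_BX
    c_i <- rowSums(crossprod(U, yt) * Ey)
    Amat[, i] <- A_i
    BXmat[, i] <- BX_i
    cmat[, i] <- c_i
    M11 <- M11 + crossprod(Xall) * EW_XX
    r1 <- r1 + rowSums(crossprod(Xall, yt) * Eyx)
    bm_set_block(Msys, i, i, A_i + Cinv)
  }

  Binv <- recursive_partition_inverse(Msys)
  Bmat <- matrix(0, m * m, N)
  for (i in seq_len(N)) Bmat[, i] <- bm_get_block(Binv, i, i)

  # r2_i = B_i c_i ; M12'M21 core ; null solutions
  r2mat <- matrix(0, m, N)
  M12M21 <- matrix(0, p, p)
  BBXmat <- matrix(0, m * p, N)                 # B_i BX_i
  for (i in seq_len(N)) {
    B_i <- matrix(Bmat[, i], m, m)
    BX_i <- matrix(BXmat[, i], m, p)
    BBX <- B_i %*% BX_i
    BBXmat[, i] <- BBX
    r2mat[, i] <- B_i %*% cmat[, i]
    M12M21 <- M12M21 + crossprod(BX_i, BBX)
  }
  fixed_core <- M11 - M12M21
  qrfc <- qr(fixed_core)
  if (qrfc$rank < p) {
    cols <- unlist(design$x_columns)
    dep <- cols[setdiff(seq_len(p), qrfc$pivot[seq_len(qrfc$rank)])]
    stop("fixed-effects core is singular; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  F_inv <- solve(fixed_core)
  rhs_b <- r1 - rowSums(vapply(seq_len(N), function(i)
    crossprod(matrix(BXmat[, i], m, p), r2mat[, i]), numeric(p)))
  bhat <- drop(F_inv %*% rhs_b)
  umat <- r2mat - matrix(
    vapply(seq_len(N), function(i)
      matrix(BBXmat[, i], m, p) %*% bhat, numeric(m)), m, N)

  # per-variant scan blocks
  Dfull <- matrix(0, m * m, N)                  # A_i B_i A_i
  Kmat <- matrix(0, m * p, N)                   # BX_i - A_i B_i BX_i
  hmat <- matrix(0, m, N)                       # c_i - BX_i bhat - A_i uhat_i
  for (i in seq_len(N)) {
    A_i <- matrix(Amat[, i], m, m)
    B_i <- matrix(Bmat[, i], m, m)
    BX_i <- matrix(BXmat[, i], m, p)
    AB <- A_i %*% B_i
    Dfull[, i] <- AB %*% A_i
    Kmat[, i] <- BX_i - AB %*% BX_i
    hmat[, i] <- cmat[, i] - BX_i %*% bhat - A_i %*% umat[, i]
  }

  # internal consistency of the transformed system (relative residual)
  res1 <- r1 - M11 %*% bhat - rowSums(vapply(seq_len(N), function(i)
    crossprod(matrix(BXmat[, i], m, p), umat[, i]), numeric(p)))
  rel <- sqrt(sum(res1^2)) / max(1, sqrt(sum(r1^2)))
  if (!is.finite(rel) || rel > 1e-8)
    warning(sprintf("null-system residual %.3g exceeds 1e-8", rel))

  n_used <- vapply(seq_len(K), function(k)
    sum(vapply(seq_len(N), function(i) any(design$obs[[i]][k, ]), logical(1))),
    integer(1))

  structure(
    list(design = design, vc = vc, K = K, N = N, p = p,
         M11 = M11, r1 = r1, B = Binv,
         Amat = Amat, Bmat = Bmat, BXmat = BXmat, cmat = cmat,
         r2 = r2mat, bhat = bhat, uhat = umat,
         fixed_core_inv = F_inv, null_residual = rel,
         scanA = Amat - Dfull, scanK = Kmat, scanh = hmat,
         n_used = n_used),
    class = "null_system")
}

#' Two-sided Wald p-value from a standard-normal reference
#'
#' Twice the upper standard-normal tail beyond `|beta/se|`, floored at the
#' smallest positive representable double.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @export
pvalue <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  pmax(2 * stats::pnorm(-abs(beta / se)), 4.940656e-324)
}

#' Scan a dosage matrix against a precomputed null system
#'
#' For each variant passing the minor-allele-count filter, solves the
#' bordered system for the 2K CS/LT effects, their standard errors (square
#' roots of the diagonal of the inverted SNP Schur complement) and two-sided
#' Wald p-values. The full matrix is processed with batched linear algebra;
#' results are bit-identical under any variant or individual ordering after
#' sorting.
#'
#' @param ns a [build_null_system()] object.
#' @param geno `genotype_dosage` object or N x V dosage matrix with rownames
#'   matching the design individuals.
#' @param mac_min minimum count per genotype-by-time category (see
#'   [apply_mac_filter()]); `0` disables the filter.
#' @param mac_rule filter reading, see [apply_mac_filter()].
#' @param maf_min optional minor-allele-frequency floor (0 disables).
#' @return Object of class `snp_scan`; use `as.data.frame()` for tidy summary
#'   statistics.
#' @export
scan_genotypes <- function(ns, geno, mac_min = 3, mac_rule = "geno_time_cells",
                           maf_min = 0) {
  stopifnot(inherits(ns, "null_system"))
  geno <- as_genotype_dosage(geno)
  G <- align_genotypes(geno, ns$design)
  if (is.integer(G)) storage.mode(G) <- "double"
  V <- ncol(G)
  m <- 2L * ns$K
  G2 <- G * G
  intervals <- vapply(ns$design$times, max, numeric(1))
  tested <- if (mac_min > 0)
    apply_mac_filter(G, intervals, min_count = mac_min, rule = mac_rule, G2 = G2)
  else rep(TRUE, V)
  mu <- colMeans(G)
  tested <- tested & (colMeans(G2) - mu * mu > 0)
  if (maf_min > 0) tested <- tested & (pmin(mu / 2, 1 - mu / 2) >= maf_min)

  beta <- se <- p <- matrix(NA_real_, m, V)
  idx <- which(tested)
  if (length(idx)) {
    Gs <- G[, idx, drop = FALSE]
    Q <- ns$scanA %*% G2[, idx, drop = FALSE]   # (m*m) x Vt
    Kall <- ns$scanK %*% Gs                     # (m*p) x Vt
    rhs <- ns$scanh %*% Gs                      # m x Vt
    S <- Q - batched_kfk(Kall, ns$fixed_core_inv, m, ns$p)
    sol <- batched_spd_solve(S, rhs, m)
    bad <- !sol$ok
    b <- sol$x; d <- sol$diag_inv
    b[, bad] <- NA_real_; d[, bad] <- NA_real_
    beta[, idx] <- b
    se[, idx] <- sqrt(d)
    p[, idx] <- pmax(2 * stats::pnorm(-abs(b / sqrt(d))), 4.940656e-324)
    tested[idx[bad]] <- FALSE
  }
  structure(
    list(beta = beta, se = se, p = p, tested = tested,
         info = geno$info, traits = ns$design$traits, n_used = ns$n_used),
    class = "snp_scan")
}

# sum over Kbar F Kbar' for all variants: Kall is (m*p) x V column-stacked
batched_kfk <- function(Kall, F_inv, m, p) {
  V <- ncol(Kall)
  Karr <- array(Kall, dim = c(m, p, V))
  out <- matrix(0, m * m, V)
  KFa <- vector("list", m)                       # rows a of Kbar F, as V x p
  for (a in seq_len(m)) {
    Ka <- t(Karr[a, , , drop = TRUE])            # V x p (p>=2 in this model)
    KFa[[a]] <- Ka %*% F_inv
  }
  for (a in seq_len(m)) {
    Ka_raw <- t(Karr[a, , , drop = TRUE])
    for (b in seq_len(a)) {
      v <- rowSums(KFa[[b]] * Ka_raw)
      out[(b - 1L) * m + a, ] <- v
      if (a != b) out[(a - 1L) * m + b, ] <- v
    }
  }
  out
}

matrixStats_colSds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(pmax(colMeans(x * x) - mu^2, 0) * n / (n - 1L))
}

#' Tidy per-variant, per-trait summary statistics
#'
#' @param x a `snp_scan` object.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return One row per variant x trait x effect type with columns
#'   `variant_id, chrom, pos, ref, alt, trait, effect, beta, se, p, n_used,
#'   filter_status`, sorted by (chrom, pos, variant_id).
#' @export
as.data.frame.snp_scan <- function(x, row.names = NULL, optional = FALSE, ...) {
  K <- length(x$traits); V <- ncol(x$beta)
  info <- x$info
  rows <- expand.grid(effect = c("CS", "LT"), trait = seq_len(K),
                      variant = seq_len(V), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  comp <- 2L * (rows$trait - 1L) + ifelse(rows$effect == "CS", 1L, 2L)
  flat <- cbind(comp, rows$variant)
  out <- data.frame(
    variant_id = info$variant_id[rows$variant],
    chrom = info$chrom[rows$variant],
    pos = info$pos[rows$variant],
    ref = info$ref[rows$variant],
    alt = info$alt[rows$variant],
    trait = x$traits[rows$trait],
    effect = rows$effect,
    beta = x$beta[flat],
    se = x$se[flat],
    p = x$p[flat],
    n_used = x$n_used[rows$trait],
    filter_status = ifelse(x$tested[rows$variant], "tested", "failed_mac"),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$variant_id, out$trait, out$effect), ,
      drop = FALSE]
}

#' Test a single variant against the null system
#'
#' Borders the transformed null system with one variant's 2K equations and
#' solves only for the variant's CS and LT effects.
#'
#' @param ns a [build_null_system()] object.
#' @param w a [build_snp_design()] object or a dosage vector.
#' @param mac_min,mac_rule see [scan_genotypes()].
#' @return Tidy data.frame as in [as.data.frame.snp_scan()].
#' @export
test_snp <- function(ns, w, mac_min = 0, mac_rule = "geno_time_cells") {
  d <- if (inherits(w, "snp_design")) w$dosages else align_dosages(w, ns$design)
  g <- genotype_dosage(matrix(d, ncol = 1,
                              dimnames = list(ns$design$individuals, "snp1")))
  as.data.frame(scan_genotypes(ns, g, mac_min = mac_min, mac_rule = mac_rule))
}

#' Single-trait longitudinal scan (K = 1 reduction)
#'
#' Runs the identical mixed-model pipeline restricted to one trait:
#' per-individual random intercept and slope, bordered per-variant solve.
#' Individuals without any record for the trait are dropped.
#'
#' @param pheno a [pheno_long()] table.
#' @param geno genotype dosages.
#' @param vc [variance_components()] covering at least `trait`.
#' @param trait trait to analyse.
#' @param ... passed to [scan_genotypes()].
#' @inheritParams build_design
#' @export
single_trait_scan <- function(pheno, geno, vc, trait, fixed_effects = NULL, ...) {
  stopifnot(inherits(pheno, "pheno_long"))
  sub <- pheno[pheno$trait_id == trait, , drop = FALSE]
  sub <- pheno_long(as.data.frame(sub), covariates = attr(pheno, "covariates"),
                    traits = trait)
  des <- build_design(sub, fixed_effects = fixed_effects)
  ns <- build_null_system(des, vc_subset(vc, trait))
  scan_genotypes(ns, geno, ...)
}

#' Rate-of-change GWAS comparator
#'
#' Collapses each individual's two measurements of a trait into
#' `(second - baseline) / interval` and runs an ordinary least-squares GWAS
#' on the derived rate, with the scaled baseline measurement as a covariate
#' and no time term. Individuals without exactly two time points, or with a
#' zero interval, are excluded (counts reported via attributes).
#'
#' @param pheno a [pheno_long()] table with two time points per individual.
#' @param geno genotype dosages.
#' @param covariates covariate columns to adjust for (default: all).
#' @return data.frame of per-variant, per-trait effects (`effect = "RATE"`),
#'   with attribute `n_dropped` per trait.
#' @export
rate_of_change_gwas <- function(pheno, geno, covariates = NULL) {
  stopifnot(inherits(pheno, "pheno_long"))
  geno <- as_genotype_dosage(geno)
  traits <- attr(pheno, "traits")
  if (is.null(covariates)) covariates <- attr(pheno, "covariates")
  out <- list(); dropped <- stats::setNames(integer(length(traits)), traits)
  for (tr in traits) {
    sub <- pheno[pheno$trait_id == tr, , drop = FALSE]
    sp <- split(seq_len(nrow(sub)), sub$individual_id)
    keep <- names(sp)[vapply(sp, length, integer(1)) == 2L]
    dropped[tr] <- length(sp) - length(keep)
    rows2 <- lapply(sp[keep], function(ii) ii[order(sub$time[ii])])
    dt <- vapply(rows2, function(ii) diff(sub$time[ii]), numeric(1))
    nz <- dt > 0
    dropped[tr] <- dropped[tr] + sum(!nz)
    rows2 <- rows2[nz]; dt <- dt[nz]
    ids <- keep[nz]
    if (length(ids) < 10L) stop("too few complete individuals for trait ", tr)
    base <- vapply(rows2, function(ii) sub$value[ii[1L]], numeric(1))
    rate <- (vapply(rows2, function(ii) sub$value[ii[2L]], numeric(1)) - base) / dt
    cv <- if (length(covariates)) {
      v <- vapply(rows2, function(ii)
        unlist(sub[ii[1L], covariates, drop = FALSE]),
        numeric(length(covariates)))
      t(matrix(v, nrow = length(covariates)))
    } else matrix(0, length(ids), 0L)
    sscale <- function(x) {
      s <- apply(as.matrix(x), 2L, stats::sd)
      scale(x, scale = ifelse(is.finite(s) & s > 0, s, 1))
    }
    Q <- cbind(1, if (ncol(cv)) sscale(cv), sscale(base))
    G <- align_genotypes(geno, list(individuals = ids, N = length(ids)))
    # Frisch-Waugh: residualize rate and genotypes on Q, then per-variant OLS
    qrq <- qr(Q)
    ry <- qr.resid(qrq, rate)
    rg <- qr.resid(qrq, G)
    gg <- colSums(rg * rg)
    ok <- gg > 0
    bhat <- ifelse(ok, colSums(rg * ry) / gg, NA_real_)
    df <- length(ids) - ncol(Q) - 1L
    rss <- sum(ry * ry) - bhat^2 * gg
    sehat <- sqrt(pmax(rss, 0) / df / gg)
    tv <- bhat / sehat
    out[[tr]] <- data.frame(
      variant_id = geno$info$variant_id, chrom = geno$info$chrom,
      pos = geno$info$pos, ref = geno$info$ref, alt = geno$info$alt,
      trait = tr, effect = "RATE",
      beta = bhat, se = sehat,
      p = pmax(2 * stats::pt(-abs(tv), df), 4.940656e-324),
      n_used = length(ids),
      filter_status = ifelse(ok, "tested", "failed_monomorphic"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped") <- dropped
  res
}

align_genotypes <- function(geno, design) {
  G <- geno$dosage
  if (!is.null(rownames(G))) {
    miss <- setdiff(design$individuals, rownames(G))
    if (length(miss)) stop("dosages missing for individual(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    if (!identical(rownames(G), design$individuals))
      G <- G[design$individuals, , drop = FALSE]
  } else if (nrow(G) != design$N) {
    stop("genotype matrix rows do not match retained individuals")
  }
  G
}
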