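# Variance-component estimation: bivariate AI-REML on the null model for
# every pair of traits, assembly of the 2K x 2K genetic (CS/LT) covariance C
# and the K x K residual covariance E across pairs, and polygenic
# heritabilities. REML works on the observed-data likelihood: zero-filled
# alignment rows carry no information and are excluded here; they matter only
# for the association system's row alignment.

#' Enumerate the bivariate analyses needed for K traits
#'
#' @param traits character vector of trait names.
#' @return data.frame with columns `trait1`, `trait2`, one row per unordered
#'   pair (K(K-1)/2 rows).
#' @export
plan_pairs <- function(traits) {
  K <- length(traits)
  if (K < 2L) stop("need at least two traits for pairwise estimation")
  cb <- utils::combn(traits, 2L)
  data.frame(trait1 = cb[1L, ], trait2 = cb[2L, ], stringsAsFactors = FALSE)
}

#' Bivariate AI-REML for one trait pair
#'
#' Fits the null (no-variant) bivariate mixed model with per-individual
#' random intercepts and slopes for both traits (4 correlated random effects
#' per individual) and a 2 x 2 residual covariance shared by same-time
#' records. Parameters are the 10 entries of the 4 x 4 genetic block and the
#' 3 entries of the residual block, updated by average-information Newton
#' steps; a step is halved toward the previous iterate whenever it would
#' leave the positive-definite cone or decrease the restricted likelihood,
#' so accepted iterations are monotone. Convergence requires both
#' `|change in restricted log-likelihood| < tol` and
#' `max |change in theta| / (|theta| + 1) < tol`.
#'
#' @param pheno a [pheno_long()] table containing both traits.
#' @param traits length-2 character vector; the two traits must differ.
#' @param fixed_effects per-trait covariate specification, as in
#'   [build_design()].
#' @param control list: `max_iter` (100), `tol` (1e-6), `min_individuals`
#'   (50; minimum per trait with at least two time points), `verbose`.
#' @return list with `C` (4 x 4, rows `trait1:CS, trait1:LT, trait2:CS,
#'   trait2:LT`), `E` (2 x 2), `loglik_trace`, `iterations`, `converged`,
#'   `boundary` (logical: any variance pinned at its positivity floor),
#'   `pair`.
#' @export
fit_pairwise_aireml <- function(pheno, traits, fixed_effects = NULL,
                                control = list()) {
  ctl <- utils::modifyList(list(max_iter = 100L, tol = 1e-6,
                                min_individuals = 50L, verbose = FALSE),
                           control)
  if (length(traits) != 2L || traits[1L] == traits[2L])
    stop("pairwise estimation requires two distinct traits")
  stopifnot(inherits(pheno, "pheno_long"))
  sub <- as.data.frame(pheno)[pheno$trait_id %in% traits, , drop = FALSE]
  sub <- pheno_long(sub, covariates = attr(pheno, "covariates"), traits = traits)
  des <- build_design(sub, fixed_effects = fixed_effects)
  for (k in 1:2) {
    n2 <- sum(vapply(seq_len(des$N), function(i)
      sum(des$obs[[i]][k, ]) >= 2L, logical(1)))
    if (n2 < ctl$min_individuals)
      stop(sprintf("trait %s has only %d individuals with >= 2 time points (need %d)",
                   traits[k], n2, ctl$min_individuals))
  }

  # observed-row structures per individual
  N <- des$N; p <- sum(des$p_k)
  dat <- vector("list", N)
  s2k <- c(0, 0); nk <- c(0L, 0L); t2sum <- 0; t2n <- 0L
  for (i in seq_len(N)) {
    ob <- des$obs[[i]]
    rowk <- integer(0); rowslot <- integer(0)
    for (k in 1:2) { w <- which(ob[k, ]); rowk <- c(rowk, rep(k, length(w)))
                     rowslot <- c(rowslot, w) }
    m_i <- length(rowk)
    t_i <- des$times[[i]][rowslot]
    Z <- matrix(0, m_i, 4L)
    Z[cbind(seq_len(m_i), 2L * rowk - 1L)] <- 1
    Z[cbind(seq_len(m_i), 2L * rowk)] <- t_i
    X <- matrix(0, m_i, p)
    col0 <- c(0L, cumsum(des$p_k))
    for (r in seq_len(m_i))
      X[r, (col0[rowk[r]] + 1L):col0[rowk[r] + 1L]] <-
        des$X[[i]][[rowk[r]]][rowslot[r], ]
    yv <- des$y[[i]][cbind(rowk, rowslot)]
    dat[[i]] <- list(Z = Z, X = X, y = yv, rowk = rowk, rowslot = rowslot,
                     m = m_i)
    for (k in 1:2) { v <- yv[rowk == k]; s2k[k] <- s2k[k] + sum(v^2)
                     nk[k] <- nk[k] + length(v) }
    t2sum <- t2sum + sum(t_i^2); t2n <- t2n + sum(t_i > 0)
  }
  s2k <- pmax(s2k / pmax(nk, 1L), 1e-8)   # crude scale; centering ignored
  mt2 <- if (t2n > 0) t2sum / t2n else 1

  # parameter bookkeeping: vech of 4x4 C then vech of 2x2 E
  cpair <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  cpair <- cpair[order(cpair[, 2L], cpair[, 1L]), , drop = FALSE]  # (row<=col)
  epair <- which(upper.tri(matrix(0, 2, 2), diag = TRUE), arr.ind = TRUE)
  epair <- epair[order(epair[, 2L], epair[, 1L]), , drop = FALSE]
  nC <- nrow(cpair); nE <- nrow(epair); nth <- nC + nE
  th2mat <- function(th) {
    C0 <- matrix(0, 4, 4); E0 <- matrix(0, 2, 2)
    for (j in seq_len(nC)) { C0[cpair[j, 1L], cpair[j, 2L]] <- th[j]
                             C0[cpair[j, 2L], cpair[j, 1L]] <- th[j] }
    for (j in seq_len(nE)) { E0[epair[j, 1L], epair[j, 2L]] <- th[nC + j]
                             E0[epair[j, 2L], epair[j, 1L]] <- th[nC + j] }
    list(C = C0, E = E0)
  }
  pd_floor <- 1e-8 * max(s2k)
  feasible <- function(th) {
    m <- th2mat(th)
    min(eigen(m$C, symmetric = TRUE, only.values = TRUE)$values) > 0 &&
      min(eigen(m$E, symmetric = TRUE, only.values = TRUE)$values) > 0
  }

  theta <- numeric(nth)
  if (!is.null(ctl$init)) {
    Ci <- ctl$init$C; Ei <- ctl$init$E
    for (j in seq_len(nC)) theta[j] <- Ci[cpair[j, 1L], cpair[j, 2L]]
    for (j in seq_len(nE)) theta[nC + j] <- Ei[epair[j, 1L], epair[j, 2L]]
  } else {
    # moment-based init: per trait, residualize on the fixed effects, then
    # split baseline/follow-up residual (co)variances into CS / LT / E
    diagC <- numeric(4L); diagE <- numeric(2L)
    for (k in 1:2) {
      Xs <- list(); ys <- list(); r1 <- c(); r2 <- c()
      Xk <- do.call(rbind, lapply(dat, function(d)
        d$X[d$rowk == k, , drop = FALSE]))
      yk <- unlist(lapply(dat, function(d) d$y[d$rowk == k]))
      rk_res <- tryCatch(stats::lm.fit(Xk, yk)$residuals, error = function(e) yk)
      pos <- 0L
      for (d in dat) {
        rows <- which(d$rowk == k)
        ri <- rk_res[pos + seq_along(rows)]; pos <- pos + length(rows)
        if (length(rows) >= 2L) {
          o <- order(d$rowslot[rows])
          r1 <- c(r1, ri[o[1L]]); r2 <- c(r2, ri[o[length(o)]])
        }
      }
      cs0 <- if (length(r1) > 2L) stats::cov(r1, r2) else 0.3 * s2k[k]
      v1 <- if (length(r1) > 2L) stats::var(r1) else s2k[k]
      v2 <- if (length(r2) > 2L) stats::var(r2) else s2k[k]
      cs0 <- max(cs0, 0.05 * v1)
      e0 <- max(v1 - cs0, 0.1 * v1)
      lt0 <- max((v2 - cs0 - e0) / mt2, 0.01 * v1 / mt2)
      diagC[2L * k - 1L] <- cs0; diagC[2L * k] <- lt0; diagE[k] <- e0
    }
    for (j in seq_len(nC)) if (cpair[j, 1L] == cpair[j, 2L])
      theta[j] <- diagC[cpair[j, 1L]]
    for (j in seq_len(nE)) if (epair[j, 1L] == epair[j, 2L])
      theta[nC + j] <- diagE[epair[j, 1L]]
  }

  loglik_pass <- function(th, want_score = FALSE) {
    mats <- th2mat(th)
    C0 <- mats$C; E0 <- mats$E
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); logdetV <- 0
    chols <- vector("list", N)
    for (i in seq_len(N)) {
      d <- dat[[i]]
      Rsame <- outer(d$rowslot, d$rowslot, "==")
      Vi <- d$Z %*% C0 %*% t(d$Z) + E0[d$rowk, d$rowk] * Rsame
      ch <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      chols[[i]] <- ch
      logdetV <- logdetV + 2 * sum(log(diag(ch)))
      sol <- backsolve(ch, forwardsolve(t(ch), cbind(d$X, d$y)))
      XtVX <- XtVX + crossprod(d$X, sol[, seq_len(p), drop = FALSE])
      XtVy <- XtVy + crossprod(d$X, sol[, p + 1L])
    }
    chX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    bhat <- backsolve(chX, forwardsolve(t(chX), XtVy))
    logdetX <- 2 * sum(log(diag(chX)))
    XtVXinv <- chol2inv(chX)
    yPy <- 0
    if (!want_score) {
      for (i in seq_len(N)) {
        d <- dat[[i]]; r <- d$y - drop(d$X %*% bhat)
        Pyi <- backsolve(chols[[i]], forwardsolve(t(chols[[i]]), r))
        yPy <- yPy + sum(r * Pyi)
      }
      return(list(ll = -0.5 * (logdetV + logdetX + yPy)))
    }
    Qsum <- matrix(0, 4, 4); Ksum <- matrix(0, 4, 4); Wsum <- matrix(0, 4, 4)
    EQ <- matrix(0, 2, 2); EW <- matrix(0, 2, 2)
    EKacc <- vector("list", nE); for (j in seq_len(nE)) EKacc[[j]] <- matrix(0, p, p)
    FVF <- matrix(0, nth, nth); XtVF <- matrix(0, p, nth); FPy <- numeric(nth)
    for (i in seq_len(N)) {
      d <- dat[[i]]; ch <- chols[[i]]
      r <- d$y - drop(d$X %*% bhat)
      solAll <- backsolve(ch, forwardsolve(t(ch), cbind(r, d$Z, d$X)))
      Pyi <- solAll[, 1L]
      VinvZ <- solAll[, 2L:5L, drop = FALSE]
      VinvX <- solAll[, 6L:(5L + p), drop = FALSE]
      yPy <- yPy + sum(r * Pyi)
      w <- drop(crossprod(d$Z, Pyi))
      Wsum <- Wsum + tcrossprod(w)
      Qsum <- Qsum + crossprod(d$Z, VinvZ)
      Gx <- crossprod(d$X, VinvZ)                 # p x 4
      Ksum <- Ksum + crossprod(Gx, XtVXinv %*% Gx)
      # residual-parameter bookkeeping over same-slot row pairs
      Vinv_i <- chol2inv(ch)
      Fi <- matrix(0, d$m, nth)
      for (j in seq_len(nC)) {
        a <- cpair[j, 1L]; b <- cpair[j, 2L]
        uw <- numeric(4L)
        uw[a] <- uw[a] + w[b]; if (a != b) uw[b] <- uw[b] + w[a]
        Fi[, j] <- d$Z %*% uw
      }
      for (j in seq_len(nE)) {
        a <- epair[j, 1L]; b <- epair[j, 2L]
        ra <- which(d$rowk == a); rb <- which(d$rowk == b)
        for (r1 in ra) {
          match_b <- rb[d$rowslot[rb] == d$rowslot[r1]]
          for (r2 in match_b) {
            EQ[a, b] <- EQ[a, b] + Vinv_i[r1, r2]
            EW[a, b] <- EW[a, b] + Pyi[r1] * Pyi[r2]
            EKacc[[j]] <- EKacc[[j]] + tcrossprod(VinvX[r1, ], VinvX[r2, ])
            Fi[r1, nC + j] <- Fi[r1, nC + j] + Pyi[r2]
            if (a != b || r1 != r2)
              Fi[r2, nC + j] <- Fi[r2, nC + j] + Pyi[r1]
          }
        }
      }
      VinvF <- backsolve(ch, forwardsolve(t(ch), Fi))
      FVF <- FVF + crossprod(Fi, VinvF)
      XtVF <- XtVF + crossprod(d$X, VinvF)
      FPy <- FPy + drop(crossprod(Fi, Pyi))
    }
    ll <- -0.5 * (logdetV + logdetX + yPy)
    score <- numeric(nth)
    for (j in seq_len(nC)) {
      a <- cpair[j, 1L]; b <- cpair[j, 2L]
      mult <- if (a == b) 1 else 2
      trPVm <- mult * (Qsum[a, b] - Ksum[a, b])
      score[j] <- -0.5 * (trPVm - FPy[j])
    }
    for (j in seq_len(nE)) {
      a <- epair[j, 1L]; b <- epair[j, 2L]
      mult <- if (a == b) 1 else 2
      trPVm <- mult * (EQ[a, b] - sum(XtVXinv * EKacc[[j]]))
      score[nC + j] <- -0.5 * (trPVm - FPy[nC + j])
    }
    AI <- 0.5 * (FVF - crossprod(XtVF, XtVXinv %*% XtVF))
    list(ll = ll, score = score, AI = AI)
  }

  trace <- numeric(0)
  cur <- loglik_pass(theta, want_score = TRUE)
  if (is.null(cur)) stop("initial variance components infeasible")
  if (isTRUE(ctl$return_score))
    return(list(theta = theta, ll = cur$ll, score = cur$score, AI = cur$AI,
                cpair = cpair, epair = epair))
  converged <- FALSE; iter <- 0L; lambda <- 1e-6
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    trace <- c(trace, cur$ll)
    # Levenberg-Marquardt damped average-information step; on failure the
    # damping grows, pulling the step toward a (scaled) gradient ascent
    accepted <- FALSE; ll_new <- NA_real_; cand <- theta
    dAI <- pmax(diag(cur$AI), 1e-12 * max(diag(cur$AI)))
    for (h in seq_len(10L)) {
      AId <- cur$AI + lambda * diag(dAI, nth)
      delta <- tryCatch(solve(AId, cur$score), error = function(e) NULL)
      if (!is.null(delta) && sum(delta * cur$score) > 0) {
        for (s in 2^-(0:6)) {       # shorten along the step before re-damping
          cand <- theta + s * delta
          if (!feasible(cand)) next
          ev <- loglik_pass(cand, want_score = FALSE)
          if (!is.null(ev) && ev$ll >= cur$ll - 1e-10) {
            accepted <- TRUE; ll_new <- ev$ll; break
          }
        }
      }
      if (accepted) break
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE; break }  # stationary to numerical precision
    lambda <- max(lambda / 10, 1e-8)
    dll <- abs(ll_new - cur$ll)
    dth <- max(abs(cand - theta) / (abs(theta) + 1))
    theta <- cand
    cur <- loglik_pass(theta, want_score = TRUE)
    if (ctl$verbose)
      message(sprintf("iter %d: ll=%.6f lambda=%.3g dtheta=%.3g", iter, cur$ll, lambda, dth))
    if (dll < ctl$tol && dth < ctl$tol) { converged <- TRUE; break }
  }
  trace <- c(trace, cur$ll)
  if (!converged && iter >= ctl$max_iter)
    stop(errorCondition(
      sprintf("AI-REML did not converge in %d iterations for pair %s/%s",
              ctl$max_iter, traits[1L], traits[2L]),
      trace = trace, class = c("mtlgwas_aireml_nonconvergence", "error")))

  mats <- th2mat(theta)
  boundary <- any(diag(mats$C) < 10 * pd_floor) || any(diag(mats$E) < 10 * pd_floor)
  lab <- as.vector(t(outer(traits, c("CS", "LT"), paste, sep = ":")))
  dimnames(mats$C) <- list(lab, lab); dimnames(mats$E) <- list(traits, traits)
  list(C = mats$C, E = mats$E, loglik_trace = trace, iterations = iter,
       converged = TRUE, boundary = boundary, pair = traits)
}

#' Assemble full covariance matrices from pairwise fits
#'
#' Each trait's within-trait 2 x 2 CS/LT block (and residual variance) is the
#' average of its K-1 pairwise estimates; every cross-trait block is taken
#' from its unique pairwise fit. The assembled matrices are repaired to
#' positive definiteness by flooring eigenvalues at `1e-8` times the largest.
#'
#' @param fits list of [fit_pairwise_aireml()] results covering all pairs.
#' @param traits trait names in the desired order.
#' @return A [variance_components()] object; attribute `pd_adjustment` holds
#'   the largest absolute entry change of the repair, `provenance` the number
#'   of fits averaged per entry.
#' @export
assemble_covariances <- function(fits, traits) {
  K <- length(traits)
  pairs <- plan_pairs(traits)
  have <- vapply(fits, function(f) paste(sort(f$pair), collapse = "|"), character(1))
  want <- apply(pairs, 1L, function(r) paste(sort(r), collapse = "|"))
  missing <- setdiff(want, have)
  if (length(missing))
    stop("missing pairwise fit(s): ", paste(gsub("\\|", "/", missing), collapse = ", "))
  C <- matrix(0, 2L * K, 2L * K); E <- matrix(0, K, K)
  nc <- matrix(0L, 2L * K, 2L * K); ne <- matrix(0L, K, K)
  for (f in fits) {
    kk <- match(f$pair, traits)
    if (anyNA(kk)) stop("fit for unknown trait(s): ", paste(f$pair, collapse = "/"))
    bi <- function(k) (2L * k - 1L):(2L * k)
    for (a in 1:2) for (b in 1:2) {
      rows <- bi(kk[a]); cols <- bi(kk[b])
      C[rows, cols] <- C[rows, cols] + f$C[bi(a), bi(b)]
      nc[rows, cols] <- nc[rows, cols] + 1L
      E[kk[a], kk[b]] <- E[kk[a], kk[b]] + f$E[a, b]
      ne[kk[a], kk[b]] <- ne[kk[a], kk[b]] + 1L
    }
  }
  C <- C / pmax(nc, 1L); E <- E / pmax(ne, 1L)
  C[nc == 0L] <- 0; E[ne == 0L] <- 0
  Cr <- pd_repair(C); Er <- pd_repair(E)
  vc <- variance_components(Cr$m, Er$m, traits,
                            provenance = list(C_fits = nc, E_fits = ne))
  attr(vc, "pd_adjustment") <- max(Cr$adjust, Er$adjust)
  vc
}

pd_repair <- function(m, rel_floor = 1e-8) {
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  fl <- rel_floor * max(eg$values, 0)
  if (fl <= 0) fl <- rel_floor
  vals <- pmax(eg$values, fl)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  out <- (out + t(out)) / 2
  list(m = out, adjust = max(abs(out - m)))
}

#' Estimate variance components by pairwise AI-REML
#'
#' Runs [fit_pairwise_aireml()] for all K(K-1)/2 trait pairs and assembles
#' the results with [assemble_covariances()].
#'
#' @inheritParams fit_pairwise_aireml
#' @param traits traits to include (default: all in `pheno`).
#' @export
estimate_variance_components <- function(pheno, traits = NULL,
                                         fixed_effects = NULL, control = list()) {
  if (is.null(traits)) traits <- attr(pheno, "traits")
  pairs <- plan_pairs(traits)
  fits <- lapply(seq_len(nrow(pairs)), function(r)
    fit_pairwise_aireml(pheno, c(pairs$trait1[r], pairs$trait2[r]),
                        fixed_effects = fixed_effects, control = control))
  assemble_covariances(fits, traits)
}

#' Polygenic cross-sectional and longitudinal heritabilities
#'
#' Per trait, the share of total variance attributed to the CS and LT
#' polygenic components: `var_CS / (var_CS + var_LT + var_Residual)` and
#' `var_LT / (var_CS + var_LT + var_Residual)`.
#'
#' @param vc a [variance_components()] object.
#' @return data.frame with columns `trait`, `h2_cs`, `h2_lt`.
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  K <- length(vc$traits)
  cs <- diag(vc$C)[seq(1L, 2L * K, by = 2L)]
  lt <- diag(vc$C)[seq(2L, 2L * K, by = 2L)]
  tot <- cs + lt + diag(vc$E)
  if (any(tot <= 0)) stop("zero total variance for trait(s): ",
                          paste(vc$traits[tot <= 0], collapse = ", "))
  data.frame(trait = vc$traits, h2_cs = cs / tot, h2_lt = lt / tot,
             stringsAsFactors = FALSE)
}
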