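# Structured linear algebra for the multi-trait longitudinal mixed model:
# block-partitioned symmetric matrices, Kronecker-factored inverses, and the
# recursive-partitioning inversion of the random-effects coefficient block.

RCOND_TOL <- 1e-12

#' Block-partitioned matrix
#'
#' A square matrix stored as a sparse map of dense sub-blocks, keyed by
#' (block-row, block-column). Partitions are contiguous row/column ranges;
#' `inner_block_order` records the size of the atomic diagonal blocks that the
#' recursive inversion is allowed to invert directly (2 for a single trait's
#' intercept+slope pair, `2K` after the K traits of one individual are
#' interleaved).
#'
#' @param partition_sizes integer vector of row/column extents per block-row.
#' @param inner_block_order atomic diagonal block size; must divide every
#'   partition size. Defaults to the smallest partition.
#' @param symmetric logical; when `TRUE`, `block(i, j)` is kept equal to
#'   `t(block(j, i))` and only one off-diagonal product is formed during
#'   inversion.
#' @return An object of class `block_matrix`.
#' @seealso [recursive_partition_inverse()], [four_block_inverse()]
#' @export
block_matrix <- function(partition_sizes, inner_block_order = NULL,
                         symmetric = TRUE) {
  partition_sizes <- as.integer(partition_sizes)
  stopifnot(length(partition_sizes) >= 1L, all(partition_sizes > 0L))
  if (is.null(inner_block_order)) inner_block_order <- min(partition_sizes)
  inner_block_order <- as.integer(inner_block_order)
  if (any(partition_sizes %% inner_block_order != 0L))
    stop("inner_block_order must divide every partition size")
  structure(
    list(partition_sizes = partition_sizes,
         offsets = c(0L, cumsum(partition_sizes)),
         blocks = new.env(parent = emptyenv()),
         symmetric = isTRUE(symmetric),
         inner_block_order = inner_block_order),
    class = "block_matrix")
}

bm_key <- function(i, j) paste0(i, "|", j)

#' Set a sub-block of a block-partitioned matrix
#'
#' For symmetric matrices the mirrored block is stored automatically.
#'
#' @param x a `block_matrix`.
#' @param i,j block-row and block-column indices.
#' @param value dense matrix conforming to the partition extents.
#' @return `x`, invisibly (blocks live in an environment).
#' @export
bm_set_block <- function(x, i, j, value) {
  value <- as.matrix(value)
  if (nrow(value) != x$partition_sizes[i] || ncol(value) != x$partition_sizes[j])
    stop(sprintf("block (%d,%d) has wrong extent", i, j))
  assign(bm_key(i, j), value, envir = x$blocks)
  if (x$symmetric && i != j)
    assign(bm_key(j, i), t(value), envir = x$blocks)
  invisible(x)
}

#' Retrieve a sub-block (NULL when structurally absent)
#' @param x a `block_matrix`.
#' @param i,j block indices.
#' @export
bm_get_block <- function(x, i, j) {
  get0(bm_key(i, j), envir = x$blocks, inherits = FALSE)
}

#' Keys of structurally present blocks
#' @param x a `block_matrix`.
#' @return two-column integer matrix of (block-row, block-col) indices.
#' @export
bm_block_keys <- function(x) {
  ks <- ls(x$blocks)
  if (length(ks) == 0L) return(matrix(integer(), 0L, 2L))
  parts <- do.call(rbind, strsplit(ks, "|", fixed = TRUE))
  m <- cbind(as.integer(parts[, 1L]), as.integer(parts[, 2L]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Densify a block-partitioned matrix
#' @param x a `block_matrix`.
#' @export
bm_dense <- function(x) {
  n <- sum(x$partition_sizes)
  out <- matrix(0, n, n)
  keys <- bm_block_keys(x)
  for (r in seq_len(nrow(keys))) {
    i <- keys[r, 1L]; j <- keys[r, 2L]
    out[(x$offsets[i] + 1L):x$offsets[i + 1L],
        (x$offsets[j] + 1L):x$offsets[j + 1L]] <- bm_get_block(x, i, j)
  }
  out
}

#' Build a block-partitioned matrix from a dense matrix
#'
#' Blocks that are entirely zero are left structurally absent.
#'
#' @param m dense square matrix.
#' @inheritParams block_matrix
#' @export
as_block_matrix <- function(m, partition_sizes, inner_block_order = NULL,
                            symmetric = isSymmetric(m)) {
  x <- block_matrix(partition_sizes, inner_block_order, symmetric)
  P <- length(partition_sizes)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    blk <- m[(x$offsets[i] + 1L):x$offsets[i + 1L],
             (x$offsets[j] + 1L):x$offsets[j + 1L], drop = FALSE]
    if (any(blk != 0)) bm_set_block(x, i, j, blk)
  }
  x
}

inv_with_check <- function(a, what) {
  rc <- rcond_sym(a)
  if (!is.finite(rc) || rc < RCOND_TOL)
    stop(sprintf("singular %s (reciprocal condition number %.3g)", what, rc))
  solve(a)
}

rcond_sym <- function(a) {
  if (length(a) == 1L) return(if (a[1] == 0) 0 else 1)
  tryCatch(1 / kappa(a, exact = FALSE), error = function(e) 0)
}

# Invert a square matrix atom-by-atom along its diagonal; `atom` must divide
# its order. Off-atom structure is assumed (and for model matrices is) zero.
invert_atomwise <- function(a, atom, context = "matrix") {
  n <- nrow(a)
  if (n == atom) return(inv_with_check(a, sprintf("atomic block 1 of %s", context)))
  out <- matrix(0, n, n)
  for (b in seq_len(n %/% atom)) {
    idx <- ((b - 1L) * atom + 1L):(b * atom)
    blk <- a[idx, idx, drop = FALSE]
    rc <- rcond_sym(blk)
    if (!is.finite(rc) || rc < RCOND_TOL)
      stop(sprintf("singular atomic block %d of %s (rcond %.3g)", b, context, rc))
    out[idx, idx] <- solve(blk)
  }
  out
}

#' Kronecker factors of a (covariance) matrix `left %x% I`
#'
#' Represents `left` \eqn{\otimes} `I_right_order` without materializing the
#' product. Used for the residual precision `E^{-1} %x% I_n`.
#'
#' @param left dense square matrix (e.g. a K x K covariance).
#' @param right_order order of the identity factor.
#' @export
kron_factors <- function(left, right_order) {
  left <- as.matrix(left)
  stopifnot(nrow(left) == ncol(left), right_order >= 1L)
  structure(list(left = left, right_order = as.integer(right_order)),
            class = "kron_factors")
}

#' Inverse of a Kronecker product with an identity factor
#'
#' Uses `(A %x% B)^{-1} = A^{-1} %x% B^{-1}`: only the small left factor is
#' inverted and the result is returned in factored form.
#'
#' @param factors a [kron_factors()] object.
#' @return A `kron_factors` object holding `left^{-1}`.
#' @export
kron_inverse <- function(factors) {
  stopifnot(inherits(factors, "kron_factors"))
  inv <- inv_with_check(factors$left, "left Kronecker factor")
  kron_factors(inv, factors$right_order)
}

#' Densify Kronecker factors (small problems only)
#' @param factors a `kron_factors` object.
#' @export
kron_dense <- function(factors) {
  factors$left %x% diag(factors$right_order)
}

#' Apply `(left %x% I)` to a vector or matrix
#'
#' The operand is interpreted in "left-major" stacking: consecutive
#' `right_order` entries share the same left index.
#'
#' @param factors a `kron_factors` object.
#' @param x vector or matrix with `nrow(left) * right_order` rows.
#' @export
kron_apply <- function(factors, x) {
  K <- nrow(factors$left); n <- factors$right_order
  x <- as.matrix(x)
  stopifnot(nrow(x) == K * n)
  out <- matrix(0, K * n, ncol(x))
  for (cc in seq_len(ncol(x))) {
    v <- matrix(x[, cc], n, K)        # column k = entries of left-index k
    out[, cc] <- as.vector(v %*% t(factors$left))
  }
  out
}

#' Four-block (bordered) inverse via the Schur complement
#'
#' Inverts `M = [[A, B], [C, D]]` given `D^{-1}`, using
#' \deqn{M^{-1} = [[S^{-1}, -S^{-1} B D^{-1}],
#'                 [-D^{-1} C S^{-1}, D^{-1} + D^{-1} C S^{-1} B D^{-1}]]}
#' with `S = A - B D^{-1} C`. When the inputs carry the model's structure the
#' Schur complement is block-diagonal and is inverted atom-by-atom (`atom`),
#' and for symmetric input (`C = t(B)`) only one off-diagonal product is
#' computed and mirrored.
#'
#' @param A,B,C,D dense blocks (`D` may be `NULL` when `D_inv` is supplied).
#' @param D_inv inverse of `D`, possibly carried over from a previous round.
#' @param atom atomic diagonal block size used to invert the Schur complement.
#' @return Dense inverse of the assembled 2x2-block matrix.
#' @export
four_block_inverse <- function(A, B, C, D = NULL, D_inv = NULL,
                               atom = nrow(as.matrix(A))) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  if (is.null(D_inv)) {
    if (is.null(D)) stop("either D or D_inv must be supplied")
    D_inv <- invert_atomwise(as.matrix(D), atom = gcd_atom(nrow(as.matrix(D)), atom),
                             context = "D")
  }
  symmetric <- isTRUE(all.equal(C, t(B), tolerance = 1e-10, check.attributes = FALSE))
  BDinv <- B %*% D_inv
  S <- A - BDinv %*% C
  S_inv <- invert_atomwise(S, atom = atom, context = "Schur complement")
  top_right <- -S_inv %*% BDinv
  bottom_left <- if (symmetric) t(top_right) else -(D_inv %*% C) %*% S_inv
  bottom_right <- D_inv - bottom_left %*% BDinv
  rbind(cbind(S_inv, top_right), cbind(bottom_left, bottom_right))
}

gcd_atom <- function(n, atom) if (n %% atom == 0L) atom else n

#' Invert a block-partitioned symmetric matrix by recursive partitioning
#'
#' Applies the four-block Schur identity iteratively, peeling one partition
#' row/column per round starting from the lower-right corner; the inverse
#' accumulated in round `rho` replaces the grown `D` block of round `rho + 1`
#' (the original `D` is no longer needed, so storage is reused). All algebra
#' stays block-sparse: products are formed only between structurally present
#' blocks, the Schur complement of each round is inverted through its atomic
#' diagonal blocks, and only one off-diagonal combination is computed and
#' mirrored. For matrices with the model's coupling structure the structurally
#' nonzero block set of the inverse equals that of the input.
#'
#' @param M a symmetric [block_matrix()].
#' @param verbose emit per-round fill-in diagnostics via [message()].
#' @return A `block_matrix` holding the inverse, with the same partitioning.
#' @export
recursive_partition_inverse <- function(M, verbose = FALSE) {
  stopifnot(inherits(M, "block_matrix"))
  if (!M$symmetric)
    stop("recursive partitioning requires a symmetric block matrix")
  P <- length(M$partition_sizes)
  keys <- bm_block_keys(M)
  for (r in seq_len(nrow(keys))) {  # numeric symmetry of stored blocks
    i <- keys[r, 1L]; j <- keys[r, 2L]
    if (i < j) {
      bij <- bm_get_block(M, i, j); bji <- bm_get_block(M, j, i)
      if (is.null(bji) || max(abs(bij - t(bji))) > 1e-8 * (1 + max(abs(bij))))
        stop(sprintf("contract violation: block (%d,%d) is not the transpose of block (%d,%d)",
                     i, j, j, i))
    }
  }
  atom <- M$inner_block_order
  out <- block_matrix(M$partition_sizes, atom, symmetric = TRUE)

  # adjacency of M's upper-triangular off-diagonal blocks, by block-row
  adjM <- vector("list", P)
  for (r in seq_len(nrow(keys))) {
    i <- keys[r, 1L]; j <- keys[r, 2L]
    if (i < j) adjM[[i]] <- c(adjM[[i]], j)
  }
  # adjacency (incl. self) of the accumulated inverse, over processed partitions
  adjD <- vector("list", P)

  # round 0: invert the last diagonal partition atom-by-atom
  Dlast <- bm_get_block(M, P, P)
  if (is.null(Dlast)) stop(sprintf("diagonal partition %d is structurally zero", P))
  bm_set_block(out, P, P, invert_atomwise(Dlast, atom,
                                          context = sprintf("partition %d", P)))
  adjD[[P]] <- P
  if (P == 1L) return(out)

  for (p in (P - 1L):1L) {
    js <- adjM[[p]]
    A <- bm_get_block(M, p, p)
    if (is.null(A)) stop(sprintf("diagonal partition %d is structurally zero", p))

    # W_j = sum_l B_{p,l} Dinv_{l,j} over present blocks (B D^{-1}, one side only)
    W <- list()
    for (l in js) for (j in adjD[[l]]) {
      dlj <- bm_get_block(out, l, j)
      contrib <- bm_get_block(M, p, l) %*% dlj
      W[[as.character(j)]] <- if (is.null(W[[as.character(j)]])) contrib
                              else W[[as.character(j)]] + contrib
    }
    S <- A
    for (l in js) {
      wl <- W[[as.character(l)]]
      if (!is.null(wl)) S <- S - wl %*% t(bm_get_block(M, p, l))
    }
    S_inv <- invert_atomwise(S, atom, context = sprintf("partition %d Schur complement", p))
    bm_set_block(out, p, p, S_inv)
    wj_names <- names(W)
    for (j in wj_names) {
      jj <- as.integer(j)
      upj <- -S_inv %*% W[[j]]
      bm_set_block(out, p, jj, upj)   # mirror stored automatically
    }
    # D update: Dinv_{j,l} += W_j' S_inv W_l (only over affected blocks)
    for (j in wj_names) for (l in wj_names) {
      jj <- as.integer(j); ll <- as.integer(l)
      if (jj > ll) next               # symmetry: fill upper, mirror below
      upd <- t(W[[j]]) %*% S_inv %*% W[[l]]
      cur <- bm_get_block(out, jj, ll)
      bm_set_block(out, jj, ll, if (is.null(cur)) upd else cur + upd)
    }
    pj <- as.integer(wj_names)
    adjD[[p]] <- c(p, pj)
    for (j in pj) adjD[[j]] <- union(adjD[[j]], c(p, pj))
    if (verbose)
      message(sprintf("round %d: %d coupled partitions, %d stored blocks",
                      P - p, length(js), nrow(bm_block_keys(out))))
  }
  out
}

# ---- batched small-SPD solves across many right-hand sides -------------------
#
# S: (m*m) x V matrix of column-stacked symmetric positive-definite m x m
# systems; rhs: m x V. Returns solutions, the diagonals of the inverses
# (for Wald standard errors) and an `ok` mask flagging non-PD systems
# (e.g. monomorphic variants) instead of erroring. Pure vectorized Cholesky:
# every step is an O(V) vector operation.
batched_spd_solve <- function(S, rhs, m) {
  V <- ncol(S)
  stopifnot(nrow(S) == m * m, nrow(rhs) == m, ncol(rhs) == V)
  idx <- function(a, b) (b - 1L) * m + a
  L <- matrix(0, m * m, V)            # lower Cholesky factors, column-stacked
  ok <- rep(TRUE, V)
  for (j in seq_len(m)) {
    acc <- S[idx(j, j), ]
    if (j > 1L) for (k in seq_len(j - 1L)) acc <- acc - L[idx(j, k), ]^2
    bad <- !(acc > 0) | !is.finite(acc)
    ok <- ok & !bad
    acc[bad] <- 1
    L[idx(j, j), ] <- sqrt(acc)
    if (j < m) for (i in (j + 1L):m) {
      a2 <- S[idx(i, j), ]
      if (j > 1L) for (k in seq_len(j - 1L)) a2 <- a2 - L[idx(i, k), ] * L[idx(j, k), ]
      L[idx(i, j), ] <- a2 / L[idx(j, j), ]
    }
  }
  # forward solve L z = rhs
  z <- matrix(0, m, V)
  for (i in seq_len(m)) {
    acc <- rhs[i, ]
    if (i > 1L) for (k in seq_len(i - 1L)) acc <- acc - L[idx(i, k), ] * z[k, ]
    z[i, ] <- acc / L[idx(i, i), ]
  }
  # back solve L' x = z
  x <- matrix(0, m, V)
  for (i in m:1L) {
    acc <- z[i, ]
    if (i < m) for (k in (i + 1L):m) acc <- acc - L[idx(k, i), ] * x[k, ]
    x[i, ] <- acc / L[idx(i, i), ]
  }
  # inverse diagonal: diag(S^{-1})_i = sum_k (Linv[k,i])^2, Linv lower-triangular
  Linv <- matrix(0, m * m, V)
  for (i in seq_len(m)) {
    Linv[idx(i, i), ] <- 1 / L[idx(i, i), ]
    if (i < m) for (r in (i + 1L):m) {
      acc <- 0
      for (k in i:(r - 1L)) acc <- acc - L[idx(r, k), ] * Linv[idx(k, i), ]
      Linv[idx(r, i), ] <- acc / L[idx(r, r), ]
    }
  }
  dinv <- matrix(0, m, V)
  for (i in seq_len(m)) {
    acc <- 0
    for (k in i:m) acc <- acc + Linv[idx(k, i), ]^2
    dinv[i, ] <- acc
  }
  list(x = x, diag_inv = dinv, ok = ok)
}
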