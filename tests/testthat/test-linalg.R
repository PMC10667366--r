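test_that("kron_inverse handles identity, diagonal and dense SPD factors", {
  # identity factor
  expect_equal(kron_dense(kron_inverse(kron_factors(diag(2), 3))), diag(6))
  # diagonal factor: analytic reciprocal
  ki <- kron_inverse(kron_factors(diag(c(2, 4)), 2))
  expect_equal(diag(kron_dense(ki)), c(0.5, 0.5, 0.25, 0.25))
  # dense SPD factor vs dense solve
  set.seed(1)
  A <- random_spd(3)
  ki <- kron_inverse(kron_factors(A, 4))
  expect_lt(max(abs(kron_dense(ki) - solve(A %x% diag(4)))), 1e-10)
  # product with the forward operator is the identity
  prod <- kron_dense(ki) %*% (A %x% diag(4))
  expect_lt(max(abs(prod - diag(12))), 1e-10)
})

test_that("kron_inverse rejects singular factors with a diagnostic", {
  expect_error(kron_inverse(kron_factors(matrix(c(1, 1, 1, 1), 2), 3)),
               "singular.*condition")
})

test_that("kron_apply matches the dense Kronecker product", {
  set.seed(2)
  A <- matrix(rnorm(9), 3)
  x <- rnorm(12)
  expect_equal(drop(kron_apply(kron_factors(A, 4), x)),
               drop((A %x% diag(4)) %*% x))
})

test_that("four_block_inverse reproduces analytic and dense inverses", {
  expect_equal(four_block_inverse(diag(2), matrix(0, 2, 2), matrix(0, 2, 2),
                                  D_inv = diag(2)), diag(4))
  out <- four_block_inverse(matrix(2), matrix(1), matrix(1), D_inv = matrix(0.5))
  expect_equal(out, matrix(c(2 / 3, -1 / 3, -1 / 3, 2 / 3), 2), tolerance = 1e-12)
  # symmetric 8x8 built from 2x2 atomic diagonal blocks
  set.seed(3)
  mk <- function() { m <- matrix(0, 4, 4); m[1:2, 1:2] <- random_spd(2)
                     m[3:4, 3:4] <- random_spd(2); m }
  A <- mk(); D <- mk()
  B <- matrix(0, 4, 4); B[1:2, 1:2] <- matrix(rnorm(4), 2) * 0.3
  B[3:4, 3:4] <- matrix(rnorm(4), 2) * 0.3
  M <- rbind(cbind(A, B), cbind(t(B), D))
  out <- four_block_inverse(A, B, t(B), D = D, atom = 2)
  expect_lt(max(abs(out - solve(M))), 1e-10)
})

test_that("four_block_inverse names the singular atomic block", {
  A <- diag(4); A[3:4, 3:4] <- 0          # second atom of the Schur complement
  expect_error(
    four_block_inverse(A, matrix(0, 4, 2), matrix(0, 2, 4), D_inv = diag(2),
                       atom = 2),
    "atomic block 2")
})

test_that("recursive partitioning inverts identity and decoupled structures", {
  # identity
  M <- block_matrix(rep(2, 6), inner_block_order = 2)
  for (i in 1:6) bm_set_block(M, i, i, diag(2))
  expect_equal(bm_dense(recursive_partition_inverse(M)), diag(12))
  # single trait: independent per-individual 2x2 blocks invert blockwise
  set.seed(4)
  blocks <- replicate(5, random_spd(2), simplify = FALSE)
  M <- block_matrix(rep(2, 5), inner_block_order = 2)
  for (i in 1:5) bm_set_block(M, i, i, blocks[[i]])
  inv <- recursive_partition_inverse(M)
  for (i in 1:5)
    expect_equal(bm_get_block(inv, i, i), solve(blocks[[i]]), tolerance = 1e-10)
})

test_that("recursive partitioning matches dense inversion on model systems", {
  set.seed(5)
  for (rep in 1:5) {
    K <- sample(2:4, 1); N <- sample(3:20, 1)
    C <- random_spd(2 * K); E <- random_spd(K)
    ph <- random_pheno(N, K, miss_prob = 0.2)
    des <- build_design(ph)
    vc <- variance_components(C, E, des$traits)
    ns <- build_null_system(des, vc)
    M <- block_matrix(rep(2 * K, des$N), inner_block_order = 2 * K)
    for (i in seq_len(des$N))
      bm_set_block(M, i, i, matrix(ns$Amat[, i], 2 * K) + solve(C))
    inv <- recursive_partition_inverse(M)
    expect_lt(max(abs(bm_dense(inv) - solve(bm_dense(M)))), 1e-9)
  }
})

test_that("recursive partitioning handles banded coupling between partitions", {
  set.seed(6)
  P <- 6; atom <- 2
  M <- block_matrix(rep(atom, P), inner_block_order = atom)
  for (i in 1:P) bm_set_block(M, i, i, random_spd(atom, 4))
  for (i in 1:(P - 1)) bm_set_block(M, i, i + 1, matrix(rnorm(atom^2), atom) * 0.2)
  inv <- recursive_partition_inverse(M)
  expect_lt(max(abs(bm_dense(inv) - solve(bm_dense(M)))), 1e-9)
})

test_that("inverse preserves sparsity, symmetry and involutes", {
  set.seed(7)
  K <- 3; N <- 8
  M <- block_matrix(rep(2 * K, N), inner_block_order = 2 * K)
  for (i in seq_len(N)) bm_set_block(M, i, i, random_spd(2 * K))
  inv <- recursive_partition_inverse(M)
  # sparsity: identical structural key sets
  expect_identical(bm_block_keys(inv), bm_block_keys(M))
  # symmetry of every stored block pair
  dm <- bm_dense(inv)
  expect_lt(max(abs(dm - t(dm))), 1e-12)
  # involution: inverting the inverse returns the original
  back <- recursive_partition_inverse(inv)
  expect_lt(max(abs(bm_dense(back) - bm_dense(M))), 1e-8)
})

test_that("recursive partitioning enforces its contracts", {
  M <- block_matrix(rep(2, 2), inner_block_order = 2, symmetric = FALSE)
  bm_set_block(M, 1, 1, diag(2)); bm_set_block(M, 2, 2, diag(2))
  expect_error(recursive_partition_inverse(M), "symmetric")
  M2 <- block_matrix(rep(2, 2), inner_block_order = 2)
  bm_set_block(M2, 1, 1, diag(2)); bm_set_block(M2, 2, 2, matrix(0, 2, 2))
  expect_error(recursive_partition_inverse(M2), "singular|structurally zero")
})

test_that("batched small-SPD solves agree with per-system solve()", {
  set.seed(8)
  m <- 6; V <- 40
  S <- matrix(0, m * m, V); rhs <- matrix(rnorm(m * V), m)
  for (v in seq_len(V)) S[, v] <- random_spd(m)
  out <- mtlgwas:::batched_spd_solve(S, rhs, m)
  expect_true(all(out$ok))
  for (v in sample(V, 8)) {
    Sv <- matrix(S[, v], m)
    expect_equal(out$x[, v], solve(Sv, rhs[, v]), tolerance = 1e-9)
    expect_equal(out$diag_inv[, v], diag(solve(Sv)), tolerance = 1e-9)
  }
  # non-PD systems are flagged, not errored
  S[, 3] <- 0
  out2 <- mtlgwas:::batched_spd_solve(S, rhs, m)
  expect_false(out2$ok[3]); expect_true(out2$ok[4])
})
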