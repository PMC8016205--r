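# Two-step pivoted Cholesky factorization of the ERI matrix: basis
# selection, Q factor, direct MO construction, screening, and guarantees.

# provider over an explicit PSD matrix (for oracle comparisons)
matrix_provider <- function(M) {
  n2 <- nrow(M)
  list(n_ao = n2, pairs = cbind(seq_len(n2), seq_len(n2)), n_pairs = n2,
       diagonal = function() diag(M),
       column = function(k) M[, k],
       column_full = function(k) M[, k])
}

# dense full-pivoted Cholesky oracle: returns the pivot sequence
dense_pivoted_chol <- function(M, tau) {
  d <- diag(M)
  piv <- integer(0)
  L <- matrix(0, nrow(M), 0)
  while (max(d) > tau) {
    k <- which(d == max(d))[1]
    col <- M[, k] - if (ncol(L)) L %*% L[k, ] else 0
    L <- cbind(L, col / sqrt(d[k]))
    d <- pmax(d - L[, ncol(L)]^2, 0)
    piv <- c(piv, k)
  }
  piv
}

test_that("basis selection handles rank-1 and trivial-termination cases", {
  v <- c(1, 0.5, -0.25, 2)
  M <- tcrossprod(v)
  pr <- matrix_provider(M)
  b <- findCholeskyBasis(pr, tau = 1e-8)
  expect_equal(nrow(b$pivots), 1L)
  expect_equal(b$pivot_pair_index, 4L)  # largest diagonal
  b0 <- findCholeskyBasis(pr, tau = 10)
  expect_equal(nrow(b0$pivots), 0L)
})

test_that("pivot sequence equals the dense full-pivoted Cholesky oracle", {
  set.seed(21)
  A <- matrix(rnorm(144), 12)
  M <- crossprod(A) + diag(1e-6, 12)
  pr <- matrix_provider(M)
  b <- findCholeskyBasis(pr, tau = 1e-7, prescreen_drop = 0)
  expect_equal(b$pivot_pair_index, dense_pivoted_chol(M, 1e-7))
})

test_that("unscreened reconstruction error is bounded by tau", {
  st <- fix_water_dz()
  ints <- st$ints
  pr <- mlccx:::eri_pair_provider(ints)
  nj_prev <- 0
  for (tau in c(1e-2, 1e-4, 1e-6)) {
    basis <- findCholeskyBasis(pr, tau)
    qinv <- buildQInverse(basis, pr)
    cd <- buildMOVectors(basis, qinv, diag(ints$n_ao), pr)
    err <- max(abs(reconstructMOIntegrals(cd) - ints$g))
    expect_lte(err, tau)
    expect_gte(cd$n_J, nj_prev)  # N_J non-increasing in tau
    nj_prev <- cd$n_J
  }
})

test_that("the Q factor satisfies its defining contracts", {
  st <- fix_water_sto3g()
  pr <- mlccx:::eri_pair_provider(st$ints)
  basis <- findCholeskyBasis(pr, 1e-4)
  qinv <- buildQInverse(basis, pr)
  nj <- nrow(basis$pivots)
  expect_gt(nj, 0)
  # Q Q^T = S_KL and Qinv Q = I
  expect_lt(max(abs(qinv$Q %*% t(qinv$Q) - qinv$S_KL)), 1e-10)
  expect_lt(max(abs(qinv$Qinv %*% qinv$Q - diag(nj))), 1e-10)
  # single pivot: Qinv = 1/sqrt((K|K))
  b1 <- basis; b1$pivots <- basis$pivots[1, , drop = FALSE]
  b1$pivot_pair_index <- basis$pivot_pair_index[1]
  q1 <- buildQInverse(b1, pr)
  expect_equal(q1$Qinv[1, 1], 1 / sqrt(q1$S_KL[1, 1]), tolerance = 1e-12)
  # self-consistency on the Cholesky basis: sum_J L^J L^J = S_KL on pivots
  cd <- buildMOVectors(basis, qinv, diag(st$ints$n_ao), pr)
  gr <- reconstructMOIntegrals(cd)
  for (k in seq_len(min(nj, 8))) {
    a <- basis$pivots[k, 1]; b <- basis$pivots[k, 2]
    for (l in seq_len(min(nj, 8))) {
      c_ <- basis$pivots[l, 1]; d_ <- basis$pivots[l, 2]
      expect_equal(gr[a, b, c_, d_], qinv$S_KL[k, l], tolerance = 1e-10)
    }
  }
})

test_that("MO-vector construction is batching-invariant", {
  st <- fix_water_sto3g()
  pr <- mlccx:::eri_pair_provider(st$ints)
  basis <- findCholeskyBasis(pr, 1e-6)
  qinv <- buildQInverse(basis, pr)
  C <- st$part$C
  cd_all <- buildMOVectors(basis, qinv, C, pr, max_batch = ncol(C))
  cd_one <- buildMOVectors(basis, qinv, C, pr, max_batch = 1)
  expect_lt(max(abs(cd_all$L - cd_one$L)), 1e-12)
  # MO reconstruction against the brute-force dense transform
  gd <- dense_mo_integrals(st$ints, C)
  expect_lte(max(abs(reconstructMOIntegrals(cd_all) - gd)), 1e-4)
})

test_that("reconstruction symmetry and empty-factorization edge cases", {
  st <- fix_water_sto3g()
  cd <- st$cderi
  g <- reconstructMOIntegrals(cd)
  set.seed(4)
  for (k in 1:10) {
    id <- sample(cd$n_mo, 4, replace = TRUE)
    expect_equal(g[id[1], id[2], id[3], id[4]], g[id[3], id[4], id[1], id[2]],
                 tolerance = 1e-12)
    expect_equal(g[id[1], id[2], id[3], id[4]], g[id[2], id[1], id[4], id[3]],
                 tolerance = 1e-12)
  }
  cd0 <- cd; cd0$n_J <- 0L; cd0$L <- array(0, c(cd$n_mo, cd$n_mo, 0))
  expect_true(all(reconstructMOIntegrals(cd0) == 0))
})

test_that("MO screening shrinks the basis while keeping MO accuracy", {
  wc <- fix_water_cluster()
  ints <- wc$ints; ref <- wc$ref
  # reduced space: the orbitals of the solute water only
  ccr <- reduceReference(ref, ints, wc$system, 1:3, freeze_core = FALSE)
  C <- ccr$C
  tau <- 1e-4
  cd_u <- choleskyERI(ints, C, tau = tau, screen = FALSE)
  cd_s <- choleskyERI(ints, C, tau = tau, screen = TRUE)
  expect_lt(cd_s$n_J, cd_u$n_J)
  gd <- dense_mo_integrals(ints, C)
  err_s <- max(abs(reconstructMOIntegrals(cd_s) - gd))
  expect_lte(err_s, tau)  # the screened guarantee is on the MO error
  # the screened factors do NOT reproduce the AO matrix (large AO-basis
  # error is expected): check the AO diagonal error exceeds tau
  prov <- mlccx:::eri_pair_provider(ints)
  b_s <- findCholeskyBasis(prov, tau, screen_weights = screeningWeights(C))
  qinv <- buildQInverse(b_s, prov)
  cd_ao <- buildMOVectors(b_s, qinv, diag(ints$n_ao), prov)
  err_ao <- max(abs(reconstructMOIntegrals(cd_ao) - ints$g))
  expect_gt(err_ao, tau)
})

test_that("screening weights vanish off the support of a localized MO", {
  n <- 6
  C <- matrix(0, n, 1); C[3, 1] <- 1
  w <- screeningWeights(C)
  expect_equal(w[3], 1)
  expect_true(all(w[-3] == 0))
  expect_true(all(screeningWeights(matrix(0, n, 2)) == 0))
})
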