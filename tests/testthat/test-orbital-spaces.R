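# Active orbital spaces: Cholesky occupied orbitals, PAOs, CNTOs,
# selection rule, and semicanonicalization.

test_that("restricted-pivot Cholesky occupied orbitals span correctly", {
  wc <- fix_water_cluster()
  ints <- wc$ints; ref <- wc$ref
  S <- ints$S
  C_occ <- ref$C[, seq_len(ref$n_occ), drop = FALSE]
  P_occ <- tcrossprod(C_occ)
  # all AOs active, tiny pivot threshold: the full occupied space
  ch <- choleskyOccupiedOrbitals(ref$D, S, C_occ, seq_len(ints$n_ao),
                                 pivot_tol = 1e-10)
  expect_equal(ncol(ch$active), ref$n_occ)
  expect_lt(max(abs(tcrossprod(ch$active) - P_occ)), 1e-8)
  # no active AOs: empty active set
  ch0 <- choleskyOccupiedOrbitals(ref$D, S, C_occ, integer(0))
  expect_equal(ncol(ch0$active), 0L)
  expect_equal(ncol(ch0$inactive), ref$n_occ)
  # one active water: matches an independent pivoted-Cholesky-of-D oracle
  aos <- mlccx:::aos_on_atoms(ints, 1:3)
  ch1 <- choleskyOccupiedOrbitals(ref$D, S, C_occ, aos, pivot_tol = 1e-2)
  # oracle: textbook pivoted Cholesky on D with pivots restricted
  D <- ref$D; d <- diag(D); L <- matrix(0, ints$n_ao, 0)
  repeat {
    da <- d[aos]
    if (max(da) <= 1e-2) break
    k <- aos[which.max(da)]
    col <- D[, k] - if (ncol(L)) L %*% L[k, ] else 0
    L <- cbind(L, col / sqrt(d[k]))
    d <- pmax(d - L[, ncol(L)]^2, 0)
  }
  Lo <- mlccx:::s_orthonormalize(L, S)
  expect_equal(ncol(ch1$active), ncol(Lo))
  expect_lt(max(abs(tcrossprod(ch1$active) - tcrossprod(Lo))), 1e-8)
  # active + inactive together are S-orthonormal and span the occupied space
  Call <- cbind(ch1$active, ch1$inactive)
  expect_lt(max(abs(crossprod(Call, S %*% Call) - diag(ncol(Call)))), 1e-8)
  expect_lt(max(abs(tcrossprod(Call) - P_occ)), 1e-8)
})

test_that("PAOs span the virtual complement", {
  wc <- fix_water_cluster()
  ints <- wc$ints; ref <- wc$ref
  S <- ints$S
  C_occ <- ref$C[, seq_len(ref$n_occ), drop = FALSE]
  P_occ <- tcrossprod(C_occ)
  # all atoms active: the full virtual space, orthogonal to occupied
  pao <- constructPAOs(ref$D, S, seq_len(ints$n_ao), n_virt = ref$n_virt)
  expect_equal(ncol(pao$active), ref$n_virt)
  expect_lt(max(abs(crossprod(C_occ, S %*% pao$active))), 1e-10)
  # restricted active set: occupied-PAO overlap still vanishes, and
  # active+inactive projectors give the virtual resolution of the identity
  aos <- mlccx:::aos_on_atoms(ints, 1:3)
  pao1 <- constructPAOs(ref$D, S, aos, n_virt = ref$n_virt)
  expect_lt(max(abs(crossprod(C_occ, S %*% pao1$active))), 1e-10)
  Pv <- tcrossprod(pao1$active) + tcrossprod(pao1$inactive)
  X <- diag(ints$n_ao)
  Sinv <- solve(S)
  expect_lt(max(abs(Pv - (Sinv - P_occ))), 1e-8)
})

test_that("CCS excitation vectors match an independent dense CIS build", {
  st <- fix_water_sto3g()
  states <- ccsExcitationVectors(st$ccref, st$cderi, 3)
  # independent: dense MO integrals + explicit CIS matrix
  gd <- dense_mo_integrals(st$ints, st$part$C)
  o <- st$cc$o; v <- st$cc$v
  occ <- 1:o; virt <- o + 1:v
  Fmo <- crossprod(st$part$C, st$ccref$F_ao_eff %*% st$part$C)
  A <- matrix(0, v * o, v * o)
  for (a in 1:v) for (i in 1:o) for (b in 1:v) for (j in 1:o) {
    A[(i - 1) * v + a, (j - 1) * v + b] <-
      (i == j) * Fmo[virt[a], virt[b]] - (a == b) * Fmo[occ[i], occ[j]] +
      2 * gd[virt[a], occ[i], virt[b], occ[j]] -
      gd[virt[a], virt[b], occ[i], occ[j]]
  }
  ev <- sort(Re(eigen(A, only.values = TRUE)$values))
  for (k in 1:3) {
    expect_equal(states[[k]]$omega, ev[k], tolerance = 1e-8)
    expect_gt(states[[k]]$omega, 0)
    expect_equal(sum(states[[k]]$R1^2), 1, tolerance = 1e-10)
  }
})

test_that("approximate doubles are linear, symmetric, and loop-exact", {
  st <- fix_water_sto3g()
  states <- ccsExcitationVectors(st$ccref, st$cderi, 1)
  R1 <- states[[1]]$R1; om <- states[[1]]$omega
  # linearity: zero singles give zero doubles
  R2z <- approximateDoubles(R1 * 0, om, st$ccref, st$cderi)
  expect_true(all(R2z == 0))
  R2 <- approximateDoubles(R1, om, st$ccref, st$cderi)
  expect_lt(max(abs(R2 - aperm(R2, c(3, 4, 1, 2)))), 1e-12)
  # brute-force loop oracle for the dressed-integral contraction
  gd <- dense_mo_integrals(st$ints, st$part$C)
  o <- st$cc$o; v <- st$cc$v
  occ <- 1:o; virt <- o + 1:v
  eps <- st$part$eps
  R2o <- array(0, c(v, o, v, o))
  for (a in 1:v) for (i in 1:o) for (b in 1:v) for (j in 1:o) {
    gbar <- 0
    for (cc_ in 1:v) gbar <- gbar +
      gd[virt[a], virt[cc_], virt[b], occ[j]] * R1[cc_, i] +
      gd[virt[b], virt[cc_], virt[a], occ[i]] * R1[cc_, j]
    for (k in 1:o) gbar <- gbar -
      gd[occ[k], occ[i], virt[b], occ[j]] * R1[a, k] -
      gd[occ[k], occ[j], virt[a], occ[i]] * R1[b, k]
    den <- eps[virt[a]] + eps[virt[b]] - eps[occ[i]] - eps[occ[j]] - om
    R2o[a, i, b, j] <- -gbar / den
  }
  expect_lt(max(abs(R2 - R2o)), 1e-6)
})

test_that("CNTO matrices are PSD, additive, and trace-consistent", {
  st <- fix_water_sto3g()
  o <- st$cc$o; v <- st$cc$v
  # rank-1 construction
  R1 <- matrix(0, v, o); R1[1, 2] <- 1
  dens <- buildCNTOMatrices(list(list(R1 = R1)))
  expect_equal(sum(abs(eigen(dens$M)$values > 1e-12)), 1)
  eM <- eigen(dens$M, symmetric = TRUE)
  expect_equal(abs(eM$vectors[2, 1]), 1, tolerance = 1e-10)
  # additivity and the spectral trace identity
  states <- ccsExcitationVectors(st$ccref, st$cderi, 2)
  states <- lapply(states, function(s) {
    s$R2 <- approximateDoubles(s$R1, s$omega, st$ccref, st$cderi); s
  })
  d1 <- buildCNTOMatrices(states[1])
  d2 <- buildCNTOMatrices(states[2])
  d12 <- buildCNTOMatrices(states)
  expect_lt(max(abs(d12$M - d1$M - d2$M)), 1e-12)
  expect_lt(max(abs(d12$N - d1$N - d2$N)), 1e-12)
  evM <- eigen(d12$M, symmetric = TRUE, only.values = TRUE)$values
  evN <- eigen(d12$N, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(evM), -1e-12)
  expect_gte(min(evN), -1e-12)
  expect_equal(sum(diag(d12$M)), sum(evM), tolerance = 1e-12)
})

test_that("active-space selection follows the eigenvalues and ratio rule", {
  st <- fix_water_sto3g()
  states <- ccsExcitationVectors(st$ccref, st$cderi, 1)
  states[[1]]$R2 <- approximateDoubles(states[[1]]$R1, states[[1]]$omega,
                                       st$ccref, st$cderi)
  dens <- buildCNTOMatrices(states)
  o <- st$cc$o; v <- st$cc$v
  # full-count ratio rule gives the full space
  pfull <- selectActiveSpace(dens, st$ccref, o)
  expect_equal(pfull$n_o_a, o)
  expect_equal(pfull$n_v_a, v)
  # empty active space is still a valid partition
  p0 <- selectActiveSpace(dens, st$ccref, 0, 0)
  expect_equal(p0$n_o_a, 0L)
  expect_equal(p0$n_occ, o)
  # eigenvalue coverage is non-decreasing in the active count
  evs <- eigen(dens$M, symmetric = TRUE, only.values = TRUE)$values
  cov <- cumsum(evs) / sum(evs)
  expect_true(all(diff(cov) >= -1e-12))
})

test_that("semicanonicalization diagonalizes blocks and preserves spans", {
  st <- fix_water_sto3g()
  states <- ccsExcitationVectors(st$ccref, st$cderi, 1)
  states[[1]]$R2 <- approximateDoubles(states[[1]]$R1, states[[1]]$omega,
                                       st$ccref, st$cderi)
  dens <- buildCNTOMatrices(states)
  p <- selectActiveSpace(dens, st$ccref, 2, 1)
  psc <- semicanonicalize(st$ccref$F_ao_eff, p)
  F_p <- crossprod(psc$C, st$ccref$F_ao_eff %*% psc$C)
  blocks <- list(1:(p$n_occ - p$n_o_a),
                 (p$n_occ - p$n_o_a + 1):p$n_occ,
                 p$n_occ + 1:p$n_v_a,
                 (p$n_occ + p$n_v_a + 1):(p$n_occ + p$n_virt))
  for (b in blocks) {
    Fb <- F_p[b, b, drop = FALSE]
    expect_lt(max(abs(Fb - diag(diag(Fb), length(b)))), 1e-9)
    # block eigenvalues equal those of the pre-rotation block
    Cb <- p$C[, b, drop = FALSE]
    ev0 <- sort(eigen(crossprod(Cb, st$ccref$F_ao_eff %*% Cb),
                      symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(sort(diag(Fb)), ev0, tolerance = 1e-10)
  }
  # projectors before/after identical
  occ_idx <- 1:p$n_occ
  expect_lt(max(abs(tcrossprod(psc$C[, occ_idx]) -
                      tcrossprod(p$C[, occ_idx]))), 1e-10)
  # full active space recovers a fully diagonal Fock matrix
  pall <- semicanonicalize(st$ccref$F_ao_eff,
                           canonicalPartition(st$ccref, "all"))
  F_all <- crossprod(pall$C, st$ccref$F_ao_eff %*% pall$C)
  expect_lt(max(abs(F_all - diag(diag(F_all)))), 1e-8)
})

test_that("orbital export round-trips block labels and coefficients", {
  st <- fix_water_sto3g()
  p <- semicanonicalize(st$ccref$F_ao_eff, canonicalPartition(st$ccref, "all"))
  f <- tempfile(fileext = ".json")
  exportOrbitals(p, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(sum(x$block == "occ-active"), p$n_o_a)
  expect_equal(dim(x$coefficients), dim(p$C))
  expect_equal(x$coefficients[, 1], p$C[, 1], tolerance = 1e-12)
})
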