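# Shared coupled cluster machinery: the X1 (singles) similarity
# transformation of the Cholesky vectors and Fock matrix, block extraction
# of dressed two-electron integrals, and the CCS-level singles residual
# shared by MLCC2 and MLCCSD.
#
# Conventions: within the retained MO space, occupied orbitals come first
# (inactive then active), then virtuals (active then inactive).  t1 is
# n_virt x n_occ and unrestricted; doubles amplitudes are stored as full
# [va, oa, va, oa] arrays over the active space, symmetric under
# (ai) <-> (bj).  Dressed integrals are
# g~_pqrs = sum_J L~_pq^J L~_rs^J with L~^J = Lambda_p L^J Lambda_h^T,
# Lambda_p = [[I,0],[-t1,I]], Lambda_h = [[I,t1^T],[0,I]] in (occ|virt)
# block form.

# Problem container assembled from a (semicanonical) partition, the
# reference Fock matrix and Cholesky factors in the partition basis.
cc_problem <- function(partition, ccref, cderi) {
  if (!partition$semicanonical)
    stop("the partition must be semicanonicalized first")
  o <- partition$n_occ; v <- partition$n_virt
  stopifnot(cderi$n_mo == o + v)
  C <- partition$C
  F_mo <- crossprod(C, ccref$F_ao_eff %*% C)
  h_mo <- crossprod(C, ccref$h_eff %*% C)
  list(o = o, v = v, n = o + v,
       oa = partition$n_o_a, va = partition$n_v_a,
       act_o = part_act_o(partition),          # indices within occ block
       act_v = part_act_v(partition),          # indices within virt block
       occ = seq_len(o), virt = o + seq_len(v),
       eps_o = partition$eps[seq_len(o)],
       eps_v = partition$eps[o + seq_len(v)],
       F_mo = F_mo, h_mo = h_mo,
       L = cderi$L, n_J = cderi$n_J,
       partition = partition)
}

# first-index and second-index matricizations of the factor tensor
.m1 <- function(L) { d <- dim(L); matrix(L, d[1], d[2] * d[3]) }
.m2 <- function(L) { d <- dim(L); matrix(aperm(L, c(2, 1, 3)), d[2], d[1] * d[3]) }
.unm2 <- function(M, d) aperm(array(M, c(d[2], d[1], d[3])), c(2, 1, 3))

# X1-transformation of the Cholesky vectors (and one-electron part).
# Returns dressed factors Lt plus the half-dressed tensors needed for the
# Jacobian dressing derivative: Y1 = L Lambda_h^T, Y2 = Lambda_p L.
dress_cholesky <- function(cc, t1) {
  n <- cc$n; occ <- cc$occ; virt <- cc$virt
  L <- cc$L
  d <- dim(L)
  # Y1 = L Lambda_h^T : occupied columns gain sum_b L[,b] t1[b,i]
  Y1 <- L
  if (length(virt) && length(occ)) {
    M2 <- .m2(L)
    add <- crossprod(t1, M2[virt, , drop = FALSE])   # [i, (p,J)]
    M2[occ, ] <- M2[occ, , drop = FALSE] + add
    Y1 <- .unm2(M2, d)
    # Y2 = Lambda_p L : virtual rows gain -t1 %*% L[occ, ]
    M1 <- .m1(L)
    Y2 <- L
    M1v <- M1[virt, , drop = FALSE] - t1 %*% M1[occ, , drop = FALSE]
    M1[virt, ] <- M1v
    Y2 <- array(M1, d)
    # Lt = Lambda_p Y1
    M1 <- .m1(Y1)
    M1[virt, ] <- M1[virt, , drop = FALSE] - t1 %*% M1[occ, , drop = FALSE]
    Lt <- array(M1, d)
  } else {
    Y2 <- L
    Lt <- L
  }
  # dressed one-electron part (effective core Hamiltonian)
  h <- cc$h_mo
  ht <- h
  ht[, occ] <- ht[, occ, drop = FALSE] + ht[, virt, drop = FALSE] %*% t1
  ht[virt, ] <- ht[virt, , drop = FALSE] - t1 %*% ht[occ, , drop = FALSE]
  list(Lt = Lt, Y1 = Y1, Y2 = Y2, ht = ht, t1 = t1,
       Ft = dressed_fock(cc, Lt, ht))
}

# dressed Fock matrix from dressed factors and one-electron part
dressed_fock <- function(cc, Lt, ht) {
  n <- cc$n; occ <- cc$occ; nj <- cc$n_J
  if (nj == 0) return(ht)
  diag_idx <- (occ - 1L) * n + occ
  Lm <- matrix(Lt, n * n, nj)
  trJ <- colSums(matrix(Lm[diag_idx, , drop = FALSE], length(occ), nj))
  Ft <- ht + matrix(2 * (Lm %*% trJ), n, n)
  for (J in seq_len(nj))
    Ft <- Ft - Lt[, occ, J] %*% Lt[occ, , J]
  Ft
}

# derivative of the dressing along a singles direction r1 (at the current
# t1): dLt = dLambda_p Y1 + Y2 dLambda_h^T, plus dht and dFt
dress_derivative <- function(cc, dr, r1) {
  n <- cc$n; occ <- cc$occ; virt <- cc$virt
  d <- dim(dr$Lt)
  # dLambda_p Y1: virtual rows receive -r1 %*% Y1[occ, ]
  M1 <- matrix(0, n, n * cc$n_J)
  Y1m <- .m1(dr$Y1)
  M1[virt, ] <- -r1 %*% Y1m[occ, , drop = FALSE]
  dLt <- array(M1, d)
  # Y2 dLambda_h^T: occupied columns receive sum_b Y2[,b] r1[b,i]
  M2 <- matrix(0, n, n * cc$n_J)
  Y2m <- .m2(dr$Y2)
  M2[occ, ] <- crossprod(r1, Y2m[virt, , drop = FALSE])
  dLt <- dLt + .unm2(M2, d)
  # one-electron part: dh~ = dLambda_p (h Lambda_h^T) + (Lambda_p h) dLambda_h^T
  h <- cc$h_mo
  ht_half <- h
  ht_half[, occ] <- ht_half[, occ, drop = FALSE] +
    ht_half[, virt, drop = FALSE] %*% dr$t1
  dh2 <- matrix(0, n, n)
  dh2[virt, ] <- -r1 %*% ht_half[occ, , drop = FALSE]
  hp <- h
  hp[virt, ] <- hp[virt, , drop = FALSE] - dr$t1 %*% hp[occ, , drop = FALSE]
  dh3 <- matrix(0, n, n)
  dh3[, occ] <- hp[, virt, drop = FALSE] %*% r1
  dht <- dh2 + dh3
  # dressed Fock derivative
  nj <- cc$n_J
  dFt <- dht
  if (nj > 0) {
    diag_idx <- (occ - 1L) * n + occ
    Lm <- matrix(dr$Lt, n * n, nj)
    dLm <- matrix(dLt, n * n, nj)
    trJ <- colSums(matrix(Lm[diag_idx, , drop = FALSE], length(occ), nj))
    dtrJ <- colSums(matrix(dLm[diag_idx, , drop = FALSE], length(occ), nj))
    dFt <- dFt + matrix(2 * (dLm %*% trJ + Lm %*% dtrJ), n, n)
    for (J in seq_len(nj)) {
      dFt <- dFt - dLt[, occ, J] %*% dr$Lt[occ, , J] -
        dr$Lt[, occ, J] %*% dLt[occ, , J]
    }
  }
  list(dLt = dLt, dht = dht, dFt = dFt)
}

# dressed integral block g~[p in I1, q in I2, r in I3, s in I4] as a 4-d
# array, from one factor tensor (or two, for derivative blocks:
# d g~ = LA x LB + LB' x LA' handled by two calls)
gblock <- function(LA, I1, I2, I3, I4, LB = LA) {
  nj <- dim(LA)[3]
  d1 <- length(I1); d2 <- length(I2); d3 <- length(I3); d4 <- length(I4)
  if (min(d1, d2, d3, d4) == 0 || nj == 0)
    return(array(0, c(d1, d2, d3, d4)))
  M1 <- matrix(LA[I1, I2, , drop = FALSE], d1 * d2, nj)
  M2 <- matrix(LB[I3, I4, , drop = FALSE], d3 * d4, nj)
  array(tcrossprod(M1, M2), c(d1, d2, d3, d4))
}

# symmetrized derivative block: sum_J (dL x L + L x dL)
gblock_d <- function(Lt, dLt, I1, I2, I3, I4) {
  gblock(dLt, I1, I2, I3, I4, Lt) + gblock(Lt, I1, I2, I3, I4, dLt)
}

# u combination of an active doubles tensor: u[a,i,b,j] = 2 t[a,i,b,j]
# - t[a,j,b,i]
u_comb <- function(t2) {
  if (length(t2) == 0) return(t2)
  2 * t2 - aperm(t2, c(1, 4, 3, 2))
}

# CCS-level singles residual shared by MLCC2 and MLCCSD: dressed-Fock
# driving term plus the doubles coupling (A1/B1/C1); u is the u-combination
# of the active doubles, `gb` supplies dressed blocks, `Ft` the dressed
# Fock.  Restriction pattern: the A1 term contributes only to active
# occupied columns, B1 only to active virtual rows, C1 to active/active.
omega_singles <- function(cc, Ft, Lt, u, dLt = NULL) {
  o <- cc$o; v <- cc$v
  occ <- cc$occ; virt <- cc$virt
  ao <- cc$act_o; av <- cc$act_v
  gb <- if (is.null(dLt)) function(...) gblock(Lt, ...) else
    function(...) gblock_d(Lt, dLt, ...)
  Om <- Ft[virt, occ, drop = FALSE]
  if (length(u) && length(ao) && length(av)) {
    oa <- length(ao); va <- length(av)
    gv <- virt[av]; go <- occ[ao]
    # A1: Omega[a, i in act] += sum_{dkc} g~[a,d,k,c] u[c,k,d,i]
    G1 <- gb(virt, gv, go, gv)                  # [a,d,k,c]
    Mu <- matrix(aperm(u, c(3, 2, 1, 4)), va * oa * va, oa)
    Om[, ao] <- Om[, ao, drop = FALSE] +
      matrix(G1, v, va * oa * va) %*% Mu
    # B1: Omega[a in act, i] -= sum_{klc} g~[k,i,l,c] u[a,k,c,l]
    G2 <- gb(go, occ, go, gv)                   # [k,i,l,c]
    MG <- matrix(aperm(G2, c(1, 3, 4, 2)), oa * oa * va, o)
    Mu2 <- matrix(aperm(u, c(2, 4, 3, 1)), oa * oa * va, va)
    Om[av, ] <- Om[av, , drop = FALSE] - t(crossprod(MG, Mu2))
    # C1: Omega[a act, i act] += sum_{ck} u[a,i,c,k] F~[k,c]
    Fkc <- Ft[occ[ao], virt[av], drop = FALSE]  # [k, c]
    Om[av, ao] <- Om[av, ao, drop = FALSE] +
      matrix(matrix(u, va * oa, va * oa) %*% as.numeric(t(Fkc)), va, oa)
  }
  Om
}

# pack/unpack an active doubles tensor to/from the unique-pair vector
# (ai >= bj in the combined active pair index)
doubles_pack_index <- function(va, oa) {
  np <- va * oa
  which(lower.tri(matrix(0, np, np), diag = TRUE))
}

pack_doubles <- function(t2, idx) {
  if (length(t2) == 0) return(numeric(0))
  d <- dim(t2)
  m <- matrix(t2, d[1] * d[2], d[3] * d[4])
  m[idx]
}

unpack_doubles <- function(x, va, oa, idx) {
  np <- va * oa
  m <- matrix(0, np, np)
  m[idx] <- x
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  array(m, c(va, oa, va, oa))
}
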