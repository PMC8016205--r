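# Independent spin-orbital coupled cluster oracle.
#
# Completely separate code path from the package: dense 4-index integrals,
# antisymmetrized physicist notation over spin orbitals, the classic
# explicit-T1 CCSD working equations with F/W intermediates, and plain
# amplitude iteration.  Used to validate ground-state energies, residuals,
# and (through finite differences and dense diagonalization) excitation
# energies at small scale.

# Build the spin-orbital problem from spatial chemist integrals g[p,q,r,s],
# a spatial Fock matrix, and the number of retained occupied spatials.
# Spin orbitals: alpha block 1..n, beta block n+1..2n.
so_setup <- function(g_chem, F_mo, n_occ) {
  n <- dim(g_chem)[1]
  phys <- aperm(g_chem, c(1, 3, 2, 4))  # <pq|rs> = (pr|qs)
  ns <- 2L * n
  aa <- seq_len(n)
  Adir <- array(0, c(ns, ns, ns, ns))
  Adir[aa, aa, aa, aa] <- phys
  Adir[aa, n + aa, aa, n + aa] <- phys
  Adir[n + aa, aa, n + aa, aa] <- phys
  Adir[n + aa, n + aa, n + aa, n + aa] <- phys
  A <- Adir - aperm(Adir, c(1, 2, 4, 3))
  fso <- matrix(0, ns, ns)
  fso[aa, aa] <- F_mo
  fso[n + aa, n + aa] <- F_mo
  occ <- c(seq_len(n_occ), n + seq_len(n_occ))
  virt <- setdiff(seq_len(ns), occ)
  list(A = A, f = fso, occ = occ, virt = virt, ns = ns, n_spatial = n,
       n_occ_spatial = n_occ)
}

# Residuals Omega1[a,i], Omega2[a,b,i,j] (zero at the solution).
so_residual <- function(so, t1, t2, method = c("ccsd", "cc2")) {
  method <- match.arg(method)
  occ <- so$occ; virt <- so$virt
  no <- length(occ); nv <- length(virt)
  f <- so$f
  fov <- f[occ, virt, drop = FALSE]
  fvv <- f[virt, virt, drop = FALSE]
  foo <- f[occ, occ, drop = FALSE]
  eo <- diag(foo); ev <- diag(fvv)
  Avvvv <- so$A[virt, virt, virt, virt, drop = FALSE]
  Aoooo <- so$A[occ, occ, occ, occ, drop = FALSE]
  Aovvv <- so$A[occ, virt, virt, virt, drop = FALSE]
  Aooov <- so$A[occ, occ, occ, virt, drop = FALSE]
  Aoovv <- so$A[occ, occ, virt, virt, drop = FALSE]
  Aovvo <- so$A[occ, virt, virt, occ, drop = FALSE]
  Aovoo <- so$A[occ, virt, occ, occ, drop = FALSE]
  Avvvo <- so$A[virt, virt, virt, occ, drop = FALSE]
  Avvoo <- so$A[virt, virt, occ, occ, drop = FALSE]
  Aovov <- so$A[occ, virt, occ, virt, drop = FALSE]
  Aoovo <- so$A[occ, occ, virt, occ, drop = FALSE]
  P_ab <- function(X) X - aperm(X, c(2, 1, 3, 4))
  P_ij <- function(X) X - aperm(X, c(1, 2, 4, 3))
  D1 <- outer(ev, eo, "-")
  D2 <- outer(outer(ev, ev, "+"), outer(eo, eo, "+"), "-")
  dim(D2) <- c(nv, nv, no, no)

  x12 <- es("ai,bj->abij", t1, t1)
  tau_t <- t2 + 0.5 * (x12 - aperm(x12, c(2, 1, 3, 4)))
  tau <- t2 + x12 - aperm(x12, c(2, 1, 3, 4))

  Fae <- (fvv - diag(ev, nv)) -
    0.5 * t1 %*% fov +
    es("fm,mafe->ae", t1, Aovvv) -
    0.5 * es("afmn,mnef->ae", tau_t, Aoovv)
  Fmi <- (foo - diag(eo, no)) +
    0.5 * es("ei,me->mi", t1, fov) +
    es("en,mnie->mi", t1, Aooov) +
    0.5 * es("efin,mnef->mi", tau_t, Aoovv)
  Fme <- fov + es("fn,mnef->me", t1, Aoovv)

  r1 <- f[virt, occ, drop = FALSE] +
    es("ei,ae->ai", t1, Fae) -
    es("am,mi->ai", t1, Fmi) +
    es("aeim,me->ai", t2, Fme) -
    es("fn,naif->ai", t1, Aovov) -
    0.5 * es("efim,maef->ai", t2, Aovvv) -
    0.5 * es("aemn,nmei->ai", t2, Aoovo) +
    t1 * D1

  if (method == "cc2") {
    Lp <- diag(so$ns); Lh <- diag(so$ns)
    Lp[virt, occ] <- -t1
    Lh[occ, virt] <- t(t1)
    # only the vvoo block of the dressed tensor is needed
    Ad <- es("ap,pqrs->aqrs", Lp[virt, , drop = FALSE], so$A)
    Ad <- es("bq,aqrs->abrs", Lp[virt, , drop = FALSE], Ad)
    Ad <- es("ir,abrs->abis", Lh[occ, , drop = FALSE], Ad)
    Ad <- es("js,abis->abij", Lh[occ, , drop = FALSE], Ad)
    r2 <- Ad +
      P_ab(es("aeij,be->abij", t2, fvv - diag(ev, nv))) -
      P_ij(es("abim,mj->abij", t2, foo - diag(eo, no))) +
      t2 * D2
    return(list(r1 = r1, r2 = r2))
  }

  Wmnij <- Aoooo +
    P_ij(es("ej,mnie->mnij", t1, Aooov)) +
    0.25 * es("efij,mnef->mnij", tau, Aoovv)
  # <am||ef> = -<ma||ef>, so the -P(ab) t1 <am||ef> term flips sign
  Wabef <- Avvvv +
    P_ab(es("bm,maef->abef", t1, Aovvv)) +
    0.25 * es("abmn,mnef->abef", tau, Aoovv)
  Wmbej <- Aovvo +
    es("fj,mbef->mbej", t1, Aovvv) -
    es("bn,mnej->mbej", t1, Aoovo) -
    es("fbjn,mnef->mbej", 0.5 * t2 + es("fj,bn->fbjn", t1, t1), Aoovv)

  tmp <- es("am,mbej->abej", t1, Aovvo)        # [a,b,e,j]
  ring <- es("aeim,mbej->abij", t2, Wmbej) -
    es("ei,abej->abij", t1, tmp)

  r2 <- Avvoo +
    P_ab(es("aeij,be->abij", t2, Fae - 0.5 * es("bm,me->be", t1, Fme))) -
    P_ij(es("abim,mj->abij", t2, Fmi + 0.5 * es("ej,me->mj", t1, Fme))) +
    0.5 * es("abmn,mnij->abij", tau, Wmnij) +
    0.5 * es("efij,abef->abij", tau, Wabef) +
    P_ij(P_ab(ring)) +
    P_ij(es("ei,abej->abij", t1, Avvvo)) -
    P_ab(es("am,mbij->abij", t1, Aovoo)) +
    t2 * D2
  list(r1 = r1, r2 = r2)
}

so_energy <- function(so, t1, t2) {
  occ <- so$occ; virt <- so$virt
  Aoovv <- so$A[occ, occ, virt, virt, drop = FALSE]
  x <- es("ai,bj->ijab", t1, t1)
  0.25 * sum(Aoovv * (aperm(t2, c(3, 4, 1, 2)) + x - aperm(x, c(1, 2, 4, 3)))) +
    sum(so$f[so$occ, so$virt] * t(t1))
}

# quasi-Newton + DIIS iteration on the spin-orbital residuals
so_solve <- function(so, method = c("ccsd", "cc2"), tol = 1e-9,
                     max_iter = 200) {
  method <- match.arg(method)
  occ <- so$occ; virt <- so$virt
  no <- length(occ); nv <- length(virt)
  eo <- diag(so$f[occ, occ, drop = FALSE])
  ev <- diag(so$f[virt, virt, drop = FALSE])
  D1 <- outer(ev, eo, "-")
  D2 <- outer(outer(ev, ev, "+"), outer(eo, eo, "+"), "-")
  dim(D2) <- c(nv, nv, no, no)
  t1 <- matrix(0, nv, no)
  t2 <- array(0, c(nv, nv, no, no))
  diis <- mlccx::diis_new(8)
  for (it in seq_len(max_iter)) {
    r <- so_residual(so, t1, t2, method)
    rn <- sqrt(sum(r$r1^2) + sum(r$r2^2))
    if (rn < tol)
      return(list(energy_corr = so_energy(so, t1, t2), t1 = t1, t2 = t2,
                  iterations = it))
    t1n <- t1 - r$r1 / D1
    t2n <- t2 - r$r2 / D2
    st <- mlccx::diis_step(diis, c(as.numeric(t1n), as.numeric(t2n)),
                           c(as.numeric(r$r1), as.numeric(r$r2)))
    diis <- st$state
    t1 <- matrix(st$param[seq_len(nv * no)], nv, no)
    t2 <- array(st$param[nv * no + seq_len(nv * nv * no * no)],
                c(nv, nv, no, no))
  }
  stop("spin-orbital oracle failed to converge (", method, ")")
}

# --- closed-shell <-> spin-orbital amplitude maps ---------------------------

# expand closed-shell (t1[v,o], t2[va,oa,va,oa] over the FULL space) into
# spin-orbital blocks matching so_setup's ordering
cs_expand_t1 <- function(t1_cs, so) {
  no <- length(so$occ); nv <- length(so$virt)
  v <- nv / 2; o <- no / 2
  t1 <- matrix(0, nv, no)
  t1[seq_len(v), seq_len(o)] <- t1_cs
  t1[v + seq_len(v), o + seq_len(o)] <- t1_cs
  t1
}

cs_expand_t2 <- function(t2_cs, so) {
  no <- length(so$occ); nv <- length(so$virt)
  v <- nv / 2; o <- no / 2
  t2 <- array(0, c(nv, nv, no, no))
  tm <- aperm(t2_cs, c(1, 3, 2, 4))     # [a,b,i,j] spatial = t_cs[a,i,b,j]
  tx <- aperm(tm, c(1, 2, 4, 3))        # [a,b,i,j] -> t_cs[a,j,b,i]
  av <- seq_len(v); bv <- v + seq_len(v)
  ao <- seq_len(o); bo <- o + seq_len(o)
  t2[av, bv, ao, bo] <- tm              # alpha beta alpha beta
  t2[bv, av, bo, ao] <- tm
  t2[av, bv, bo, ao] <- -tx             # alpha beta beta alpha
  t2[bv, av, ao, bo] <- -tx
  t2[av, av, ao, ao] <- tm - tx         # same spin (antisymmetrized)
  t2[bv, bv, bo, bo] <- tm - tx
  t2
}

# read the closed-shell residual back from the spin-orbital one
so_readout_r1 <- function(r1_so, so) {
  no <- length(so$occ); nv <- length(so$virt)
  v <- nv / 2; o <- no / 2
  r1_so[seq_len(v), seq_len(o), drop = FALSE]
}

so_readout_r2 <- function(r2_so, so) {
  no <- length(so$occ); nv <- length(so$virt)
  v <- nv / 2; o <- no / 2
  aperm(r2_so[seq_len(v), v + seq_len(v), seq_len(o), o + seq_len(o),
              drop = FALSE], c(1, 3, 2, 4))
}

# --- spin-orbital EOM utilities --------------------------------------------

# antisymmetry-packed doubles index lists (a<b, i<j)
so_pack_scheme <- function(so) {
  nv <- length(so$virt); no <- length(so$occ)
  pv <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)  # a < b
  po <- which(upper.tri(matrix(0, no, no)), arr.ind = TRUE)  # i < j
  list(nv = nv, no = no, pv = pv, po = po,
       dim = nv * no + nrow(pv) * nrow(po))
}

so_pack <- function(sch, r1, r2) {
  x2 <- r2[cbind(rep(sch$pv[, 1], each = nrow(sch$po)),
                 rep(sch$pv[, 2], each = nrow(sch$po)),
                 rep(sch$po[, 1], times = nrow(sch$pv)),
                 rep(sch$po[, 2], times = nrow(sch$pv)))]
  c(as.numeric(r1), x2)
}

so_unpack <- function(sch, x) {
  nv <- sch$nv; no <- sch$no
  r1 <- matrix(x[seq_len(nv * no)], nv, no)
  r2 <- array(0, c(nv, nv, no, no))
  vals <- x[nv * no + seq_len(nrow(sch$pv) * nrow(sch$po))]
  k <- 0
  for (q in seq_len(nrow(sch$pv))) {
    a <- sch$pv[q, 1]; b <- sch$pv[q, 2]
    for (p in seq_len(nrow(sch$po))) {
      i <- sch$po[p, 1]; j <- sch$po[p, 2]
      k <- k + 1
      v <- vals[k]
      r2[a, b, i, j] <- v; r2[b, a, i, j] <- -v
      r2[a, b, j, i] <- -v; r2[b, a, j, i] <- v
    }
  }
  list(r1 = r1, r2 = r2)
}

# finite-difference Jacobian action around converged amplitudes
so_jacobian_action <- function(so, sol, method, h = 1e-5) {
  sch <- so_pack_scheme(so)
  function(x) {
    d <- so_unpack(sch, x)
    rp <- so_residual(so, sol$t1 + h * d$r1, sol$t2 + h * d$r2, method)
    rm <- so_residual(so, sol$t1 - h * d$r1, sol$t2 - h * d$r2, method)
    so_pack(sch, (rp$r1 - rm$r1) / (2 * h), (rp$r2 - rm$r2) / (2 * h))
  }
}

# dense FD Jacobian (small problems): returns real sorted eigenvalues and
# singlet-classified eigenvectors
so_eom_dense <- function(so, sol, method, h = 1e-5) {
  sch <- so_pack_scheme(so)
  act <- so_jacobian_action(so, sol, method, h)
  A <- vapply(seq_len(sch$dim), function(k) {
    x <- numeric(sch$dim); x[k] <- 1
    act(x)
  }, numeric(sch$dim))
  ev <- eigen(A)
  keep <- abs(Im(ev$values)) < 1e-6
  vals <- Re(ev$values[keep])
  vecs <- Re(ev$vectors[, keep, drop = FALSE])
  ord <- order(vals)
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE], sch = sch)
}

# singlet test: the symmetric alpha/beta combination dominates the singles
# block (degenerate triplet multiplets can mix their Ms components, so a
# projection score is used rather than a sign comparison)
so_is_singlet <- function(sch, vec, score_min = 0.5) {
  nv <- sch$nv; no <- sch$no
  v <- nv / 2; o <- no / 2
  r1 <- matrix(vec[seq_len(nv * no)], nv, no)
  raa <- r1[seq_len(v), seq_len(o)]
  rbb <- r1[v + seq_len(v), o + seq_len(o)]
  nrm2 <- sum(r1^2)
  if (nrm2 < 1e-12) return(NA)  # doubles-dominated; undecided
  score <- 0.5 * sum((raa + rbb)^2) / nrm2   # 1 for singlet, 0 for triplet
  score > score_min
}

# lowest n singlet eigenvalues from a dense FD EOM
so_singlet_omegas <- function(eom, n) {
  out <- numeric(0)
  for (k in seq_along(eom$values)) {
    s <- so_is_singlet(eom$sch, eom$vectors[, k])
    if (isTRUE(s)) out <- c(out, eom$values[k])
    if (length(out) >= n) break
  }
  out
}

# Davidson on the FD action (larger problems): returns the lowest
# n_singlets singlet excitation energies
so_eom_davidson <- function(so, sol, method, n_singlets, n_roots = NULL,
                            tol = 1e-6, seed = 1L) {
  sch <- so_pack_scheme(so)
  act <- so_jacobian_action(so, sol, method)
  eo <- diag(so$f[so$occ, so$occ, drop = FALSE])
  ev <- diag(so$f[so$virt, so$virt, drop = FALSE])
  d1 <- as.numeric(outer(ev, eo, "-"))
  D2 <- outer(outer(ev, ev, "+"), outer(eo, eo, "+"), "-")
  dim(D2) <- c(sch$nv, sch$nv, sch$no, sch$no)
  d2 <- so_pack(sch, matrix(0, sch$nv, sch$no), D2)[-seq_len(sch$nv * sch$no)]
  dA <- c(d1, d2)
  if (is.null(n_roots)) n_roots <- 4L * n_singlets
  res <- mlccx::davidson_nonsym(act, dA, n_roots, sch$dim, tol = tol,
                                seed = seed, max_iter = 500L)
  out <- numeric(0)
  for (k in seq_len(n_roots)) {
    s <- so_is_singlet(sch, res$vectors[, k])
    if (isTRUE(s)) out <- c(out, res$values[k])
    if (length(out) >= n_singlets) break
  }
  if (length(out) < n_singlets)
    stop("not enough singlet roots found among the requested eigenpairs")
  out
}

# Singlet-projected FD EOM: the action is evaluated in the closed-shell
# parametrization (expand -> spin-orbital FD residual difference -> read
# back).  The singlet subspace is invariant under the Jacobian, so the
# eigenvalues of the projected operator are the singlet excitation
# energies; Davidson then targets them directly.
so_eom_davidson_singlet <- function(so, sol, method, n_roots, tol = 1e-6,
                                    seed = 1L, h = 1e-5) {
  v <- length(so$virt) / 2
  o <- length(so$occ) / 2
  np <- v * o
  idx2 <- which(lower.tri(matrix(0, np, np), diag = TRUE))
  dim2 <- length(idx2)
  pack_cs <- function(r1, r2) {
    m <- matrix(r2, np, np)
    c(as.numeric(r1), m[idx2])
  }
  unpack_cs <- function(x) {
    r1 <- matrix(x[seq_len(np)], v, o)
    m <- matrix(0, np, np)
    m[idx2] <- x[np + seq_len(dim2)]
    m <- m + t(m); diag(m) <- diag(m) / 2
    list(r1 = r1, r2 = array(m, c(v, o, v, o)))
  }
  act <- function(x) {
    d <- unpack_cs(x)
    r1so <- cs_expand_t1(d$r1, so)
    r2so <- cs_expand_t2(d$r2, so)
    rp <- so_residual(so, sol$t1 + h * r1so, sol$t2 + h * r2so, method)
    rm <- so_residual(so, sol$t1 - h * r1so, sol$t2 - h * r2so, method)
    pack_cs(so_readout_r1((rp$r1 - rm$r1) / (2 * h), so),
            so_readout_r2((rp$r2 - rm$r2) / (2 * h), so))
  }
  eo <- diag(so$f[so$occ, so$occ, drop = FALSE])[seq_len(o)]
  ev <- diag(so$f[so$virt, so$virt, drop = FALSE])[seq_len(v)]
  d1 <- outer(ev, -eo, "+")
  D2 <- outer(as.numeric(d1), as.numeric(d1), "+")
  dA <- c(as.numeric(d1), D2[idx2])
  res <- mlccx::davidson_nonsym(act, dA, n_roots, np + dim2, tol = tol,
                                seed = seed, max_iter = 400L)
  res$values
}
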