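# Active orbital spaces: restricted-pivot Cholesky occupied orbitals,
# projected atomic orbitals (PAOs), correlated natural transition orbitals
# (CNTOs) from CCS excitation vectors with approximate doubles, active-space
# selection, and semicanonicalization.
#
# An orbital_partition holds S-orthonormal AO-basis coefficients ordered as
# (inactive-occ | active-occ | active-virt | inactive-virt).

# canonical Loewdin S-orthonormalization of the span of C; drops directions
# with metric eigenvalues below `tol` (relative); optionally keeps only the
# leading `keep` directions
s_orthonormalize <- function(C, S, tol = 1e-8, keep = NULL) {
  if (ncol(C) == 0) return(C)
  M <- crossprod(C, S %*% C)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)  # decreasing eigenvalues
  good <- e$values > tol * max(e$values, 0)
  if (!is.null(keep)) good <- good & seq_along(e$values) <= keep
  C %*% e$vectors[, good, drop = FALSE] %*%
    diag(1 / sqrt(e$values[good]), sum(good))
}

#' Cholesky occupied orbitals with pivots restricted to active atoms
#'
#' Pivoted Cholesky decomposition of the idempotent Hartree-Fock density
#' with pivots restricted to AOs centered on active atoms; the resulting
#' active occupied orbitals span the density's projection onto the active
#' AOs, and the inactive set completes the occupied space.
#'
#' @param D AO density (`C_occ C_occ^T` convention)
#' @param S AO overlap
#' @param C_occ occupied MO coefficients (defines the occupied space for the
#'   inactive complement)
#' @param active_aos AO indices allowed as pivots
#' @param pivot_tol stop when the largest remaining active diagonal is at or
#'   below this value
#' @return list with `active` and `inactive` S-orthonormal coefficient
#'   matrices
#' @export
choleskyOccupiedOrbitals <- function(D, S, C_occ, active_aos,
                                     pivot_tol = 1e-2) {
  n <- nrow(D)
  n_occ <- ncol(C_occ)
  d <- diag(D)
  L <- matrix(0, n, 0)
  if (length(active_aos)) {
    repeat {
      da <- d[active_aos]
      mx <- max(da)
      if (mx <= pivot_tol) break
      k <- active_aos[which(da == mx)[1]]
      col <- D[, k]
      if (ncol(L) > 0) col <- col - L %*% L[k, ]
      L <- cbind(L, col / sqrt(mx))
      d <- pmax(d - L[, ncol(L)]^2, 0)
      if (ncol(L) > n_occ)
        stop("pivot_tol too small: Cholesky rank exceeds the occupied count")
    }
  }
  C_act <- s_orthonormalize(L, S)
  # inactive occupied: occupied space with the active span projected out
  B <- C_occ
  if (ncol(C_act)) B <- B - C_act %*% crossprod(C_act, S %*% B)
  C_inact <- s_orthonormalize(B, S, keep = n_occ - ncol(C_act))
  list(active = C_act, inactive = C_inact)
}

#' Projected atomic orbitals for the active virtual space
#'
#' Active virtuals are the Loewdin-orthonormalized span of the active-atom
#' AOs with the occupied orbitals projected out (`C_PAO = (I - D S)`
#' restricted to active columns).  Inactive virtuals additionally project
#' out the active virtuals and complete the virtual space.
#'
#' @param D idempotent AO density
#' @param S AO overlap
#' @param active_aos AO indices of the active atoms (non-empty)
#' @param n_virt total virtual count to preserve
#' @param lindep_tol relative linear-dependence threshold for the canonical
#'   orthonormalization
#' @return list with `active` and `inactive` coefficient matrices
#' @export
constructPAOs <- function(D, S, active_aos, n_virt, lindep_tol = 1e-6) {
  if (!length(active_aos)) stop("constructPAOs requires active AOs")
  n <- nrow(D)
  P <- diag(n) - D %*% S
  C_raw <- P[, active_aos, drop = FALSE]
  C_act <- s_orthonormalize(C_raw, S, tol = lindep_tol)
  if (!ncol(C_act))
    stop("all projected AOs are linearly dependent below lindep_tol; ",
         "the active virtual space is empty")
  if (ncol(C_act) > n_virt) C_act <- C_act[, seq_len(n_virt), drop = FALSE]
  # inactive virtuals: project occupied and active virtuals out of all AOs
  X <- P - C_act %*% crossprod(C_act, S)
  C_inact <- s_orthonormalize(X, S, tol = lindep_tol,
                              keep = n_virt - ncol(C_act))
  list(active = C_act, inactive = C_inact)
}

#' Assemble an orbital partition
#'
#' @param occ_inactive,occ_active,virt_active,virt_inactive AO-basis
#'   coefficient blocks
#' @param provenance label (`"cnto"`, `"cholesky-pao"`, `"canonical"`)
#' @return an `orbital_partition`
#' @export
orbitalPartition <- function(occ_inactive, occ_active, virt_active,
                             virt_inactive, provenance = "canonical") {
  C <- cbind(occ_inactive, occ_active, virt_active, virt_inactive)
  n_occ <- ncol(occ_inactive) + ncol(occ_active)
  n_virt <- ncol(virt_active) + ncol(virt_inactive)
  structure(list(C = C, n_occ = n_occ, n_virt = n_virt,
                 n_o_a = ncol(occ_active), n_v_a = ncol(virt_active),
                 semicanonical = FALSE, provenance = provenance,
                 eps = NULL),
            class = "orbital_partition")
}

#' @export
print.orbital_partition <- function(x, ...) {
  cat("orbital partition (", x$provenance, "): ", x$n_occ, " occ (",
      x$n_o_a, " active) / ", x$n_virt, " virt (", x$n_v_a, " active)",
      if (x$semicanonical) ", semicanonical" else "", "\n", sep = "")
  invisible(x)
}

# index helpers: positions of the active blocks
part_act_o <- function(p) {
  if (p$n_o_a == 0) integer(0) else (p$n_occ - p$n_o_a + 1L):p$n_occ
}
part_act_v <- function(p) if (p$n_v_a > 0) seq_len(p$n_v_a) else integer(0)

#' Semicanonicalize a partition
#'
#' Block-rotations within each of the four blocks so the active-active and
#' inactive-inactive occupied-occupied and virtual-virtual Fock blocks
#' become diagonal; spans (and hence projectors) are unchanged.
#'
#' @param F_ao effective Fock matrix in the AO basis
#' @param partition an `orbital_partition`
#' @return the partition with rotated coefficients, `semicanonical = TRUE`
#'   and orbital energies `eps`
#' @export
semicanonicalize <- function(F_ao, partition) {
  p <- partition
  blocks <- list(
    oi = seq_len(p$n_occ - p$n_o_a),
    oa = part_act_o(p),
    va = p$n_occ + part_act_v(p),
    vi = if (p$n_virt - p$n_v_a > 0)
      (p$n_occ + p$n_v_a + 1L):(p$n_occ + p$n_virt) else integer(0))
  C <- p$C
  eps <- numeric(p$n_occ + p$n_virt)
  for (b in blocks) {
    if (!length(b)) next
    Cb <- C[, b, drop = FALSE]
    Fb <- crossprod(Cb, F_ao %*% Cb)
    e <- eigen_asc(Fb)
    C[, b] <- Cb %*% e$vectors
    eps[b] <- e$values
  }
  p$C <- C
  p$eps <- eps
  p$semicanonical <- TRUE
  p
}

# ---------------------------------------------------------------------------
# CNTOs
# ---------------------------------------------------------------------------

# dense singlet CIS/CCS Jacobian in the (canonical) reference basis
dense_ccs_matrix <- function(ccref, cderi) {
  o <- ccref$n_occ; v <- ccref$n_virt; n <- o + v
  occ <- seq_len(o); virt <- o + seq_len(v)
  L <- cderi$L
  Lvo <- matrix(L[virt, occ, , drop = FALSE], v * o, cderi$n_J)
  g_vo_vo <- tcrossprod(Lvo)                       # (ai|bj) at [(a,i),(b,j)]
  Lvv <- matrix(L[virt, virt, , drop = FALSE], v * v, cderi$n_J)
  Loo <- matrix(L[occ, occ, , drop = FALSE], o * o, cderi$n_J)
  g_vv_oo <- tcrossprod(Lvv, Loo)                  # (ab|ij) at [(a,b),(i,j)]
  gx <- array(g_vv_oo, c(v, v, o, o))
  gx <- aperm(gx, c(1, 3, 2, 4))                   # [(a,i),(b,j)] of (ab|ij)
  A <- 2 * g_vo_vo - matrix(gx, v * o, v * o)
  Fo <- ccref$F_mo[occ, occ]; Fv <- ccref$F_mo[virt, virt]
  A <- A + kronecker(diag(o), Fv) - kronecker(t(Fo), diag(v))
  A
}

#' CCS excitation energies and vectors
#'
#' Lowest eigenpairs of the CCS Jacobian (singles-singles block at the
#' Hartree-Fock reference); equals singlet CIS.  Solved densely for small
#' problems, by the Davidson solver otherwise.
#'
#' @param ccref a `cc_reference`
#' @param cderi Cholesky factors in the reference basis
#' @param n_states number of states
#' @param dense_limit use dense diagonalization up to this singles dimension
#' @param seed Davidson seed
#' @return list of states, each with `omega` and singles vector `R1`
#'   (`n_virt x n_occ`, normalized)
#' @export
ccsExcitationVectors <- function(ccref, cderi, n_states, dense_limit = 4000,
                                 seed = 1L) {
  o <- ccref$n_occ; v <- ccref$n_virt
  dim1 <- o * v
  if (n_states > dim1) stop("more states requested than singles dimension")
  A <- dense_ccs_matrix(ccref, cderi)
  if (dim1 <= dense_limit) {
    e <- eigen(A)
    if (any(abs(Im(e$values)) > 1e-7))
      stop("complex CCS eigenvalues encountered")
    idx <- order(Re(e$values))[seq_len(n_states)]
    vals <- Re(e$values[idx]); vecs <- Re(e$vectors[, idx, drop = FALSE])
  } else {
    res <- davidson_nonsym(function(x) A %*% x, diag(A), n_states, dim1,
                           tol = 1e-7, seed = seed)
    vals <- res$values; vecs <- res$vectors
  }
  lapply(seq_len(n_states), function(k) {
    R1 <- matrix(vecs[, k], v, o)
    list(omega = vals[k], R1 = R1 / sqrt(sum(R1^2)))
  })
}

#' Approximate double excitation vectors from CCS singles
#'
#' CIS(D)-style doubles built from the singles-dressed two-electron
#' integrals: `R2_aibj = -gbar_aibj / (eps_a+eps_b-eps_i-eps_j - omega)`,
#' where `gbar` is the one-index (R1) transformation of (ai|bj) assembled
#' from the Cholesky factors.
#'
#' @param R1 singles vector (`n_virt x n_occ`)
#' @param omega CCS excitation energy of the state
#' @param ccref a `cc_reference` (canonical orbital energies)
#' @param cderi Cholesky factors in the reference basis
#' @param shift_tol denominators below this magnitude are level-shifted
#' @return doubles array `R2[a,i,b,j]`, symmetric under (ai)<->(bj)
#' @export
approximateDoubles <- function(R1, omega, ccref, cderi, shift_tol = 1e-6) {
  o <- ccref$n_occ; v <- ccref$n_virt
  occ <- seq_len(o); virt <- o + seq_len(v)
  nj <- cderi$n_J
  L <- cderi$L
  Lvo <- matrix(L[virt, occ, , drop = FALSE], v * o, nj)
  # dL_vo^J = -R1 L_oo^J + L_vv^J R1 (one-index transformation along R1)
  dL <- matrix(0, v * o, nj)
  for (J in seq_len(nj)) {
    dL[, J] <- as.numeric(L[virt, virt, J] %*% R1 - R1 %*% L[occ, occ, J])
  }
  gbar <- tcrossprod(dL, Lvo) + tcrossprod(Lvo, dL)
  gbar <- array(gbar, c(v, o, v, o))
  eo <- ccref$eps[occ]; ev <- ccref$eps[virt]
  den <- outer(ev, -eo, "+")
  Den <- outer(as.numeric(den), as.numeric(den), "+") - omega
  small <- abs(Den) < shift_tol
  if (any(small)) {
    warning("near-singular CIS(D) denominators; applying a level shift")
    Den[small] <- sign(Den[small] + shift_tol) * shift_tol
  }
  array(-as.numeric(gbar) / as.numeric(Den), c(v, o, v, o))
}

#' Build CNTO occupied/virtual density-like matrices
#'
#' `M = R1^T R1 + 1/2 (doubles contraction)` over occupied indices and the
#' mirrored construction for virtuals; for several states the matrices are
#' element-wise sums over states.
#'
#' @param states list of states, each with `R1` (`v x o`) and optionally
#'   `R2` (`v x o x v x o`)
#' @return a `cnto_densities` list with symmetric PSD matrices `M`
#'   (occupied) and `N` (virtual)
#' @export
buildCNTOMatrices <- function(states) {
  stopifnot(length(states) >= 1)
  v <- nrow(states[[1]]$R1); o <- ncol(states[[1]]$R1)
  M <- matrix(0, o, o); N <- matrix(0, v, v)
  for (st in states) {
    M <- M + crossprod(st$R1)
    N <- N + tcrossprod(st$R1)
    if (!is.null(st$R2)) {
      # occupied: sum_{abk} R2[a,i,b,k] R2[a,j,b,k]
      Ro <- matrix(aperm(st$R2, c(1, 3, 4, 2)), v * v * o, o)
      M <- M + 0.5 * crossprod(Ro)
      Rv <- matrix(aperm(st$R2, c(2, 3, 4, 1)), o * v * o, v)
      N <- N + 0.5 * crossprod(Rv)
    }
  }
  structure(list(M = (M + t(M)) / 2, N = (N + t(N)) / 2,
                 n_occ = o, n_virt = v),
            class = "cnto_densities")
}

#' Select an active space from CNTO eigenvalues
#'
#' Active occupied/virtual orbitals are the eigenvectors of `M`/`N` with the
#' largest eigenvalues.  With `n_v_a = NULL` the ratio rule
#' `n_v_a = round(n_o_a * N_v / N_o)` (round-half-up) applies.  Eigenvalue
#' ties at the cut include the tied orbitals (with a warning).
#'
#' @param densities a `cnto_densities`
#' @param ccref the `cc_reference` whose basis the densities refer to
#' @param n_o_a number of active occupied orbitals
#' @param n_v_a number of active virtual orbitals, or `NULL` for the ratio
#'   rule
#' @return an `orbital_partition` (not yet semicanonical)
#' @export
selectActiveSpace <- function(densities, ccref, n_o_a, n_v_a = NULL) {
  o <- densities$n_occ; v <- densities$n_virt
  stopifnot(n_o_a >= 0, n_o_a <= o)
  if (is.null(n_v_a)) n_v_a <- floor(n_o_a * v / o + 0.5)  # round half up
  stopifnot(n_v_a >= 0, n_v_a <= v)
  eM <- eigen(densities$M, symmetric = TRUE)  # decreasing
  eN <- eigen(densities$N, symmetric = TRUE)
  tie_extend <- function(vals, k, n) {
    if (k == 0 || k == n) return(k)
    while (k < n &&
           abs(vals[k + 1] - vals[k]) <= 1e-10 * max(abs(vals[k]), 1e-30)) {
      warning("eigenvalue tie at the active-space cut; including both orbitals")
      k <- k + 1L
    }
    k
  }
  n_o_a <- tie_extend(eM$values, n_o_a, o)
  n_v_a <- tie_extend(eN$values, n_v_a, v)
  occ <- seq_len(o); virt <- o + seq_len(v)
  C_occ <- ccref$C[, occ, drop = FALSE] %*% eM$vectors
  C_virt <- ccref$C[, virt, drop = FALSE] %*% eN$vectors
  act_o <- seq_len(n_o_a)
  act_v <- seq_len(n_v_a)
  orbitalPartition(
    occ_inactive = C_occ[, setdiff(occ, act_o), drop = FALSE],
    occ_active = C_occ[, act_o, drop = FALSE],
    virt_active = C_virt[, act_v, drop = FALSE],
    virt_inactive = C_virt[, setdiff(seq_len(v), act_v), drop = FALSE],
    provenance = "cnto")
}

#' Canonical full- or empty-active partition
#'
#' @param ccref a `cc_reference`
#' @param active `"all"` or `"none"`
#' @return an `orbital_partition` over the canonical orbitals
#' @export
canonicalPartition <- function(ccref, active = c("all", "none")) {
  active <- match.arg(active)
  o <- ccref$n_occ; v <- ccref$n_virt
  Co <- ccref$C[, seq_len(o), drop = FALSE]
  Cv <- ccref$C[, o + seq_len(v), drop = FALSE]
  if (active == "all")
    orbitalPartition(Co[, 0, drop = FALSE], Co, Cv, Cv[, 0, drop = FALSE])
  else
    orbitalPartition(Co, Co[, 0, drop = FALSE], Cv[, 0, drop = FALSE], Cv)
}

#' Export partition orbital coefficients
#'
#' Writes the AO-basis coefficients of a partition as a plain JSON container
#' with block labels, for external visualization tools.
#'
#' @param partition an `orbital_partition`
#' @param path output path (JSON)
#' @return `path`, invisibly
#' @export
exportOrbitals <- function(partition, path) {
  p <- partition
  labels <- c(rep("occ-inactive", p$n_occ - p$n_o_a),
              rep("occ-active", p$n_o_a),
              rep("virt-active", p$n_v_a),
              rep("virt-inactive", p$n_virt - p$n_v_a))
  out <- list(provenance = p$provenance,
              semicanonical = p$semicanonical,
              block = labels,
              orbital_energies = p$eps,
              coefficients = unname(p$C))  # n_ao x n_mo nested array
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# rotate Cholesky factors into a new MO basis of the same span:
# U[p_old, q_new] = C_old^T S C_new
rotate_cholesky <- function(cderi, U) {
  n <- cderi$n_mo
  nj <- cderi$n_J
  L <- cderi$L
  out <- array(0, c(ncol(U), ncol(U), nj))
  for (J in seq_len(nj)) out[, , J] <- crossprod(U, L[, , J] %*% U)
  cderi$L <- out
  cderi$n_mo <- ncol(U)
  cderi
}
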