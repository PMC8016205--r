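# Restricted Hartree-Fock reference and frozen-Fock reduced-space embedding.
#
# Density convention: D = C_occ C_occ^T (idempotent under D S D = D); the
# factors of 2 live in the Fock and energy expressions, F = h + 2J(D) - K(D),
# E_el = tr[D (h + F)].

# Coulomb/exchange build from the in-core ERI tensor.  The K contraction
# needs the (mu lambda | nu sigma) ordering; the permuted copy is cached on
# the integral set's environment the first time it is needed.
.jk_env <- new.env(parent = emptyenv())

.g_matrix <- function(ints) {
  key <- paste0("gm_", data_key(ints))
  if (is.null(.jk_env[[key]])) {
    n <- ints$n_ao
    .jk_env[[key]] <- matrix(ints$g, n * n, n * n)
  }
  .jk_env[[key]]
}

.gk_matrix <- function(ints) {
  key <- paste0("gk_", data_key(ints))
  if (is.null(.jk_env[[key]])) {
    n <- ints$n_ao
    .jk_env[[key]] <- matrix(aperm(ints$g, c(1, 3, 2, 4)), n * n, n * n)
  }
  .jk_env[[key]]
}

data_key <- function(ints) {
  # cheap content hash: dimensions plus a few deterministic probes
  n <- ints$n_ao
  probes <- ints$g[seq(1, length(ints$g), length.out = 17)]
  paste0(n, "_", format(sum(abs(probes)), digits = 15), "_",
         format(ints$e_nuc, digits = 15))
}

# symmetric eigensolver with eigenvalues in ascending order
eigen_asc <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- order(e$values)
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

build_JK <- function(ints, D) {
  n <- ints$n_ao
  J <- matrix(.g_matrix(ints) %*% as.numeric(D), n, n)
  K <- matrix(.gk_matrix(ints) %*% as.numeric(D), n, n)
  list(J = J, K = K)
}

# two-electron part of the Fock matrix for a given density
g_of_D <- function(ints, D) {
  jk <- build_JK(ints, D)
  2 * jk$J - jk$K
}

#' Restricted Hartree-Fock
#'
#' DIIS-accelerated RHF on the AO-gradient FDS - SDF, core-Hamiltonian
#' initial guess.
#'
#' @param ints an `ao_integral_set`
#' @param system the `molecular_system`
#' @param gradient_tol convergence threshold on the orbital gradient norm
#' @param max_iter maximum number of SCF iterations
#' @param diis_size DIIS subspace size
#' @return an `scf_reference`: MO coefficients `C`, orbital energies `eps`,
#'   AO Fock matrix `F`, density `D`, total `energy`, occupied/virtual counts,
#'   an (initially empty) frozen-occupied set and its effective Fock
#'   contribution `F_f`, and the effective core Hamiltonian `h_eff`
#' @export
runRHF <- function(ints, system, gradient_tol = 1e-8, max_iter = 100,
                   diis_size = 8) {
  ne <- nElectrons(system)
  if (ne %% 2 != 0) stop("closed-shell RHF requires an even electron count")
  n_occ <- ne %/% 2L
  n <- ints$n_ao
  if (n_occ > n) stop("basis too small for the electron count")
  S <- ints$S
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  h <- ints$h
  Fao <- h
  D <- NULL
  diis <- diis_new(diis_size)
  energy <- NA_real_
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    Fo <- crossprod(X, Fao %*% X)
    ef <- eigen_asc(Fo)
    C <- X %*% ef$vectors
    eps <- ef$values
    Co <- C[, seq_len(n_occ), drop = FALSE]
    D <- tcrossprod(Co)
    Fao <- h + g_of_D(ints, D)
    energy <- sum(D * (h + Fao)) + ints$e_nuc
    grad <- Fao %*% D %*% S - S %*% D %*% Fao
    grad_norm <- sqrt(sum(crossprod(X, grad %*% X)^2))
    if (grad_norm <= gradient_tol) {
      # final diagonalization so C, eps, F are mutually consistent
      Fo <- crossprod(X, Fao %*% X)
      ef <- eigen_asc(Fo)
      C <- X %*% ef$vectors
      eps <- ef$values
      D <- tcrossprod(C[, seq_len(n_occ), drop = FALSE])
      nmo <- ncol(C)
      return(structure(list(C = C, eps = eps, F = Fao, D = D,
                            energy = energy, n_occ = n_occ,
                            n_virt = nmo - n_occ, n_mo = nmo,
                            frozen_occ = integer(0),
                            F_f = matrix(0, n, n), h_eff = h,
                            iterations = it, grad_norm = grad_norm),
                       class = "scf_reference"))
    }
    step <- diis_step(diis, as.numeric(Fao), as.numeric(crossprod(X, grad %*% X)))
    diis <- step$state
    Fao <- matrix(step$param, n, n)
  }
  stop("SCF failed to converge in ", max_iter,
       " iterations (last gradient norm ", format(grad_norm, digits = 4), ")")
}

#' @export
print.scf_reference <- function(x, ...) {
  cat("RHF reference: E =", format(x$energy, digits = 12), "hartree,",
      x$n_occ, "occupied /", x$n_virt, "virtual MOs")
  if (length(x$frozen_occ)) cat(",", length(x$frozen_occ), "frozen")
  cat("\n")
  invisible(x)
}

#' Effective Fock matrix of a frozen-occupied set
#'
#' The frozen orbitals enter the correlated equations only through their
#' mean-field (Coulomb minus exchange) contribution `F_f`; the returned Fock
#' matrix is `h + G(D_retained) + F_f`, which equals the Fock matrix of the
#' total density.
#'
#' @param reference a converged `scf_reference`
#' @param ints the `ao_integral_set`
#' @param frozen_occ indices (within the occupied block) of frozen orbitals
#' @return list with `F_f` (frozen contribution, AO basis), `F` (total
#'   effective Fock), `D_frozen`, `D_retained`
#' @export
buildFrozenFock <- function(reference, ints, frozen_occ) {
  occ <- seq_len(reference$n_occ)
  if (length(frozen_occ) && !all(frozen_occ %in% occ))
    stop("frozen indices must lie in the occupied block")
  if (length(frozen_occ) >= reference$n_occ && reference$n_occ > 0)
    stop("cannot freeze every occupied orbital")
  Cf <- reference$C[, frozen_occ, drop = FALSE]
  Df <- if (length(frozen_occ)) tcrossprod(Cf) else
    matrix(0, ints$n_ao, ints$n_ao)
  Dr <- reference$D - Df
  F_f <- if (length(frozen_occ)) g_of_D(ints, Df) else
    matrix(0, ints$n_ao, ints$n_ao)
  Ffull <- ints$h + g_of_D(ints, Dr) + F_f
  list(F_f = F_f, F = Ffull, D_frozen = Df, D_retained = Dr)
}

#' Apply the frozen-core approximation
#'
#' Freezes the lowest-energy core orbitals (element core counts: none for
#' H/He, one for first-row, five for second-row atoms) and folds their
#' mean-field contribution into the effective Fock matrix.
#'
#' @param reference a converged `scf_reference`
#' @param ints the `ao_integral_set`
#' @param system the `molecular_system`
#' @return the reference with `frozen_occ`, `F_f` and `h_eff` updated
#' @export
freezeCore <- function(reference, ints, system) {
  n_core <- sum(element_core_count(system$atoms))
  if (n_core == 0) return(reference)
  if (n_core >= reference$n_occ)
    stop("frozen-core count (", n_core, ") must be below the occupied count (",
         reference$n_occ, ")")
  ord <- order(reference$eps[seq_len(reference$n_occ)])
  frozen <- sort(ord[seq_len(n_core)])
  fb <- buildFrozenFock(reference, ints, frozen)
  reference$frozen_occ <- frozen
  reference$F_f <- fb$F_f
  reference$h_eff <- ints$h + fb$F_f
  reference
}

#' Correlation-treatment reference in the retained MO space
#'
#' Collects the retained (non-frozen) MOs, the effective MO-basis Fock
#' matrix and the effective core Hamiltonian into the object consumed by the
#' coupled cluster modules.
#'
#' @param reference an `scf_reference` (frozen set already applied, if any)
#' @param ints the `ao_integral_set`
#' @return a `cc_reference`: `C` (AO x n_mo retained, occupied first),
#'   `n_occ`, `n_virt`, `F_mo`, `eps`, `h_eff`, `S`
#' @export
ccReference <- function(reference, ints) {
  occ <- setdiff(seq_len(reference$n_occ), reference$frozen_occ)
  virt <- reference$n_occ + seq_len(reference$n_virt)
  C <- reference$C[, c(occ, virt), drop = FALSE]
  fb <- buildFrozenFock(reference, ints, reference$frozen_occ)
  F_mo <- crossprod(C, fb$F %*% C)
  structure(list(C = C, n_occ = length(occ), n_virt = length(virt),
                 F_mo = F_mo, eps = diag(F_mo), h_eff = ints$h + fb$F_f,
                 F_ao_eff = fb$F, S = ints$S, e_nuc = ints$e_nuc,
                 scf_energy = reference$energy),
            class = "cc_reference")
}
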