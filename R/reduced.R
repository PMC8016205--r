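# Reduced-space embedding and partition workflows.
#
# In a reduced-space run only the orbitals of a selected molecular region
# enter the coupled cluster treatment: occupied Cholesky orbitals (pivots on
# region AOs) span the correlated occupied space, PAOs on the region atoms
# span the correlated virtual space, and every remaining occupied orbital is
# frozen, contributing only its mean-field term to the Fock matrix.

#' Reduced-space correlation reference
#'
#' Builds the retained MO space for a frozen-Fock reduced-space calculation:
#' occupied Cholesky orbitals and PAOs of the selected region, with all
#' remaining occupied orbitals frozen.  With `freeze_core`, the lowest
#' (core-count) orbitals of the semicanonicalized retained occupied block
#' are moved to the frozen set as well.
#'
#' @param reference converged `scf_reference`
#' @param ints `ao_integral_set`
#' @param system the `molecular_system`
#' @param region_atoms atom indices of the coupled cluster region
#' @param pivot_tol pivot threshold for the occupied Cholesky decomposition
#' @param lindep_tol linear-dependence threshold for the PAO
#'   orthonormalization
#' @param freeze_core freeze core orbitals of the region atoms
#' @return a `cc_reference` over the retained space (occupied first); the
#'   Fock matrix is block non-diagonal
#' @export
reduceReference <- function(reference, ints, system, region_atoms,
                            pivot_tol = 1e-2, lindep_tol = 1e-6,
                            freeze_core = TRUE) {
  S <- ints$S
  n_occ <- reference$n_occ
  C_occ <- reference$C[, seq_len(n_occ), drop = FALSE]
  aos <- aos_on_atoms(ints, region_atoms)
  if (!length(aos)) stop("the selected region covers no AOs")
  ch <- choleskyOccupiedOrbitals(reference$D, S, C_occ, aos,
                                 pivot_tol = pivot_tol)
  C_ro <- ch$active
  if (!ncol(C_ro)) stop("no occupied orbitals selected for the region")
  # semicanonicalize the retained occupied block; optionally freeze cores
  Fo <- crossprod(C_ro, reference$F %*% C_ro)
  eo <- eigen_asc(Fo)
  C_ro <- C_ro %*% eo$vectors
  if (freeze_core) {
    n_core <- sum(element_core_count(system$atoms[region_atoms]))
    n_core <- min(n_core, ncol(C_ro) - 1L)
    if (n_core > 0) C_ro <- C_ro[, -seq_len(n_core), drop = FALSE]
  }
  pao <- constructPAOs(reference$D, S, aos, n_virt = reference$n_virt,
                       lindep_tol = lindep_tol)
  C_rv <- pao$active
  C <- cbind(C_ro, C_rv)
  # frozen density = total occupied minus retained occupied
  D_ret_occ <- tcrossprod(C_ro)
  D_f <- reference$D - D_ret_occ
  F_f <- g_of_D(ints, D_f)
  h_eff <- ints$h + F_f
  F_ao <- h_eff + g_of_D(ints, D_ret_occ)
  F_mo <- crossprod(C, F_ao %*% C)
  structure(list(C = C, n_occ = ncol(C_ro), n_virt = ncol(C_rv),
                 F_mo = F_mo, eps = diag(F_mo), h_eff = h_eff,
                 F_ao_eff = F_ao, S = S, e_nuc = ints$e_nuc,
                 scf_energy = reference$energy,
                 region_atoms = sort(region_atoms)),
            class = "cc_reference")
}

#' Cholesky/PAO orbital partition of a correlation reference
#'
#' Splits the (possibly reduced) occupied and virtual spaces into active and
#' inactive sets by a restricted-pivot Cholesky decomposition of the
#' retained occupied density and PAOs of the active atoms.
#'
#' @param ccref a `cc_reference`
#' @param ints `ao_integral_set`
#' @param active_atoms atom indices of the higher-level region
#' @param pivot_tol occupied Cholesky pivot threshold
#' @param lindep_tol PAO orthonormalization threshold
#' @return an `orbital_partition` (provenance `"cholesky-pao"`)
#' @export
partitionLocalized <- function(ccref, ints, active_atoms, pivot_tol = 1e-2,
                               lindep_tol = 1e-6) {
  S <- ccref$S
  o <- ccref$n_occ; v <- ccref$n_virt
  C_occ <- ccref$C[, seq_len(o), drop = FALSE]
  C_virt <- ccref$C[, o + seq_len(v), drop = FALSE]
  aos <- aos_on_atoms(ints, active_atoms)
  D_occ <- tcrossprod(C_occ)
  ch <- choleskyOccupiedOrbitals(D_occ, S, C_occ, aos, pivot_tol = pivot_tol)
  # active virtuals: PAOs of the active atoms projected into the retained
  # virtual span
  P_vret <- tcrossprod(C_virt)
  pao_cols <- (diag(ints$n_ao) - tcrossprod(C_occ) %*% S)[, aos, drop = FALSE]
  pao_cols <- P_vret %*% S %*% pao_cols
  C_av <- s_orthonormalize(pao_cols, S, tol = lindep_tol)
  if (ncol(C_av) > v) C_av <- C_av[, seq_len(v), drop = FALSE]
  # inactive virtuals: complement within the retained virtual span
  X <- C_virt - C_av %*% crossprod(C_av, S %*% C_virt)
  C_iv <- s_orthonormalize(X, S, keep = v - ncol(C_av))
  orbitalPartition(ch$inactive, ch$active, C_av, C_iv,
                   provenance = "cholesky-pao")
}

#' CNTO orbital partition
#'
#' Runs CCS on the reference, builds approximate doubles and the CNTO
#' occupied/virtual matrices summed over the requested states, and selects
#' the active space by eigenvalue.
#'
#' @param ccref a `cc_reference`
#' @param cderi Cholesky factors in the reference basis
#' @param n_states number of CCS states entering the CNTOs
#' @param n_o_a active occupied count
#' @param n_v_a active virtual count, or `NULL` for the ratio rule
#' @param seed Davidson seed for large CCS problems
#' @return an `orbital_partition` (provenance `"cnto"`)
#' @export
partitionCNTO <- function(ccref, cderi, n_states, n_o_a, n_v_a = NULL,
                          seed = 1L) {
  states <- ccsExcitationVectors(ccref, cderi, n_states, seed = seed)
  states <- lapply(states, function(st) {
    st$R2 <- approximateDoubles(st$R1, st$omega, ccref, cderi)
    st
  })
  dens <- buildCNTOMatrices(states)
  selectActiveSpace(dens, ccref, n_o_a, n_v_a)
}

# basis-change matrix between two S-orthonormal MO sets of the same span
mo_rotation <- function(C_old, C_new, S) crossprod(C_old, S %*% C_new)
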