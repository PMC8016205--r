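# AO integral provider.  The built-in McMurchie-Davidson engine produces
# overlap, core-Hamiltonian and the full in-core ERI tensor (chemist
# notation, 8-fold symmetric) over contracted Cartesian Gaussians.  AOs are
# normalized through the overlap diagonal so every Cartesian component has
# unit self-overlap.

#' Compute AO integrals for a molecular system
#'
#' @param system a `molecular_system`
#' @param schwarz_tol Schwarz screening threshold for shell quartets
#' @return an `ao_integral_set`: overlap `S`, kinetic `T`, nuclear attraction
#'   `V`, core Hamiltonian `h`, ERI tensor `g` (`n_ao^4` array, chemist
#'   (pq|rs)), nuclear repulsion `e_nuc`, AO-to-atom map `ao_atom`, and the
#'   shell list
#' @export
computeAOIntegrals <- function(system, schwarz_tol = 1e-14) {
  sh <- build_shells(system)
  coords_bohr <- system$coords * BOHR_PER_ANGSTROM
  Z <- element_number(system$atoms)
  one <- .cpp_one_electron(sh$shells, coords_bohr, as.numeric(Z))
  g <- .cpp_eri_full(sh$shells, schwarz_tol)
  # per-AO normalization via the overlap diagonal
  nrm <- 1 / sqrt(diag(one$S))
  S <- one$S * outer(nrm, nrm)
  T_ <- one$T * outer(nrm, nrm)
  V <- one$V * outer(nrm, nrm)
  n <- sh$n_ao
  g <- g * nrm  # first index
  g <- g * rep(nrm, each = n)  # second
  g <- g * rep(nrm, each = n * n)  # third
  g <- g * rep(nrm, each = n * n * n)  # fourth
  dim(g) <- c(n, n, n, n)
  # nuclear repulsion
  e_nuc <- 0
  natom <- nrow(coords_bohr)
  if (natom > 1) {
    for (i in 1:(natom - 1)) for (j in (i + 1):natom) {
      e_nuc <- e_nuc + Z[i] * Z[j] /
        sqrt(sum((coords_bohr[i, ] - coords_bohr[j, ])^2))
    }
  }
  structure(list(S = S, T = T_, V = V, h = T_ + V, g = g, e_nuc = e_nuc,
                 n_ao = n, ao_atom = sh$ao_atom, ao_l = sh$ao_l,
                 shells = sh$shells, ao_norm = nrm),
            class = "ao_integral_set")
}

#' @export
print.ao_integral_set <- function(x, ...) {
  cat("AO integral set:", x$n_ao, "basis functions,",
      length(x$shells), "shells\n")
  invisible(x)
}

#' Independent ERI diagonal (ab|ab)
#'
#' Computed by a separate provider routine, bypassing the full-tensor
#' symmetry bookkeeping; used for cross-checks and by the Cholesky prescreen.
#'
#' @param ints an `ao_integral_set`
#' @return `n_ao x n_ao` matrix of diagonal elements (ab|ab)
#' @export
eriDiagonal <- function(ints) {
  d <- .cpp_eri_diagonal(ints$shells)
  d * outer(ints$ao_norm^2, ints$ao_norm^2)
}

# AO indices centered on a set of atoms
aos_on_atoms <- function(ints, atom_idx) which(ints$ao_atom %in% atom_idx)
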