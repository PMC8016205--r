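# Multilevel CC2: unrestricted singles X1 plus perturbative doubles S2
# restricted to the active orbital space.  The doubles equation is solved
# analytically each iteration in the semicanonical basis; the singles
# equation with a DIIS-accelerated quasi-Newton solver.  Excitation
# energies are right eigenvalues of the matrix-free Jacobian.

# active-space denominator tensor eps_a + eps_b - eps_i - eps_j
active_denominator <- function(cc) {
  av <- cc$act_v; ao <- cc$act_o
  if (!length(av) || !length(ao)) return(array(0, c(0, 0, 0, 0)))
  d1 <- outer(cc$eps_v[av], -cc$eps_o[ao], "+")
  array(outer(as.numeric(d1), as.numeric(d1), "+"),
        c(length(av), length(ao), length(av), length(ao)))
}

# analytic S2 solve: s2 = -g~_aibj / D over active indices
solve_s2 <- function(cc, dr, omega_shift = 0) {
  av <- cc$act_v; ao <- cc$act_o
  if (!length(av) || !length(ao)) return(array(0, c(0, 0, 0, 0)))
  g <- gblock(dr$Lt, cc$virt[av], cc$occ[ao], cc$virt[av], cc$occ[ao])
  D <- active_denominator(cc)
  if (any(abs(D - omega_shift) < 1e-10))
    stop("vanishing doubles denominator; check semicanonical degeneracies")
  -g / (D - omega_shift)
}

# CC2 doubles residual at given amplitudes (used by tests / FD oracles)
omega2_cc2 <- function(cc, dr, s2) {
  av <- cc$act_v; ao <- cc$act_o
  if (!length(av) || !length(ao)) return(array(0, c(0, 0, 0, 0)))
  g <- gblock(dr$Lt, cc$virt[av], cc$occ[ao], cc$virt[av], cc$occ[ao])
  g + active_denominator(cc) * s2
}

# correlation energy from (t1, t2) with undressed integrals:
# E = sum (t2 + t1 t1) L_iajb + 2 sum F_ia t1
cc_energy <- function(cc, t1, t2) {
  occ <- cc$occ; virt <- cc$virt
  o <- cc$o; v <- cc$v
  Lvo <- matrix(cc$L[virt, occ, , drop = FALSE], v * o, cc$n_J)
  g_vovo <- array(tcrossprod(Lvo), c(v, o, v, o))
  Lfull <- 2 * g_vovo - aperm(g_vovo, c(1, 4, 3, 2))
  e <- sum(as.numeric(t1) * (matrix(Lfull, v * o, v * o) %*% as.numeric(t1)))
  if (length(t2)) {
    av <- cc$act_v; ao <- cc$act_o
    e <- e + sum(t2 * Lfull[av, ao, av, ao, drop = FALSE])
  }
  e + 2 * sum(cc$F_mo[virt, occ] * t1)
}

#' MLCC2 ground state
#'
#' @param cc a problem container from `cc_problem`
#' @param tol convergence threshold on the residual norm |Omega|
#' @param max_iter maximum iterations
#' @param diis_size DIIS subspace
#' @return list with correlation and total energies, amplitudes `t1`, `s2`,
#'   the dressing at convergence, and the residual history
#' @export
mlcc2GroundState <- function(cc, tol = 1e-6, max_iter = 100, diis_size = 8) {
  o <- cc$o; v <- cc$v
  t1 <- matrix(0, v, o)
  den1 <- outer(cc$eps_v, -cc$eps_o, "+")
  diis <- diis_new(diis_size)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    dr <- dress_cholesky(cc, t1)
    s2 <- solve_s2(cc, dr)
    Om <- omega_singles(cc, dr$Ft, dr$Lt, u_comb(s2))
    rn <- sqrt(sum(Om^2))
    hist <- c(hist, rn)
    if (rn <= tol) {
      ecorr <- cc_energy(cc, t1, s2)
      return(list(energy_corr = ecorr, t1 = t1, s2 = s2, dress = dr,
                  iterations = it, residuals = hist, converged = TRUE))
    }
    step <- diis_step(diis, as.numeric(t1 - Om / den1), as.numeric(Om))
    diis <- step$state
    t1 <- matrix(step$param, v, o)
  }
  stop("MLCC2 ground state failed to converge; residual history: ",
       paste(format(tail(hist, 5), digits = 3), collapse = ", "))
}

#' MLCC2 Jacobian action
#'
#' Matrix-free action of the MLCC2 Jacobian on a trial vector
#' `(r1, r2-active)`; the derivative of the residuals at the converged
#' ground state.
#'
#' @param cc problem container
#' @param gs converged ground state from [mlcc2GroundState()]
#' @param r1 singles trial block (`v x o`)
#' @param r2 active doubles trial block
#' @return list with transformed blocks `rho1`, `rho2`
#' @export
mlcc2JacobianApply <- function(cc, gs, r1, r2) {
  dr <- gs$dress
  dd <- dress_derivative(cc, dr, r1)
  u_t <- u_comb(gs$s2)
  # singles: dressing derivative at fixed s2, plus the u(r2) coupling
  rho1 <- omega_singles(cc, dd$dFt, dr$Lt, u_t, dLt = dd$dLt)
  if (length(r2)) {
    # t2-derivative part: A1/B1/C1 with u(r2); no Fock driving term
    rho1 <- rho1 + omega_singles(cc, dr$Ft, dr$Lt, u_comb(r2)) -
      dr$Ft[cc$virt, cc$occ, drop = FALSE]
  }
  # doubles: dressing derivative of g~_aibj plus the diagonal F part
  av <- cc$act_v; ao <- cc$act_o
  rho2 <- array(0, c(length(av), length(ao), length(av), length(ao)))
  if (length(av) && length(ao)) {
    rho2 <- gblock_d(dr$Lt, dd$dLt,
                     cc$virt[av], cc$occ[ao], cc$virt[av], cc$occ[ao])
    rho2 <- rho2 + active_denominator(cc) * r2
  }
  list(rho1 = rho1, rho2 = rho2)
}

# full residual evaluation for finite-difference tests: Omega at arbitrary
# (t1, s2), both blocks
mlcc2_omega_full <- function(cc, t1, s2) {
  dr <- dress_cholesky(cc, t1)
  list(omega1 = omega_singles(cc, dr$Ft, dr$Lt, u_comb(s2)),
       omega2 = omega2_cc2(cc, dr, s2))
}

# shared Davidson driver over packed (r1, packed r2) vectors
cc_excited_states <- function(cc, gs, jac_apply, n_states, tol = 1e-4,
                              seed = 1L, max_iter = 300L) {
  o <- cc$o; v <- cc$v
  oa <- length(cc$act_o); va <- length(cc$act_v)
  idx2 <- if (oa && va) doubles_pack_index(va, oa) else integer(0)
  dim1 <- v * o
  dim2 <- length(idx2)
  pack <- function(r1, r2) c(as.numeric(r1),
                             if (dim2) pack_doubles(r2, idx2) else numeric(0))
  unpack <- function(x) {
    r1 <- matrix(x[seq_len(dim1)], v, o)
    r2 <- if (dim2) unpack_doubles(x[dim1 + seq_len(dim2)], va, oa, idx2) else
      array(0, c(va, oa, va, oa))
    list(r1 = r1, r2 = r2)
  }
  apply_A <- function(x) {
    tr <- unpack(x)
    res <- jac_apply(cc, gs, tr$r1, tr$r2)
    pack(res$rho1, res$rho2)
  }
  d1 <- as.numeric(outer(cc$eps_v, -cc$eps_o, "+"))
  dA <- c(d1, if (dim2) pack_doubles(active_denominator(cc), idx2) else
    numeric(0))
  sol <- davidson_nonsym(apply_A, dA, n_states, dim1 + dim2, tol = tol,
                         seed = seed, max_iter = max_iter)
  states <- lapply(seq_len(n_states), function(k) {
    tr <- unpack(sol$vectors[, k])
    list(omega = sol$values[k], R1 = tr$r1, R2 = tr$r2,
         residual = sol$residuals[k])
  })
  states
}

#' MLCC2 excitation energies
#'
#' Lowest right eigenpairs of the MLCC2 Jacobian by the non-symmetric
#' Davidson solver.
#'
#' @param cc problem container
#' @param gs converged ground state
#' @param n_states number of states
#' @param tol per-state residual threshold
#' @param seed Davidson seed
#' @return list of states with `omega` (hartree), `R1`, `R2`, `residual`
#' @export
mlcc2ExcitedStates <- function(cc, gs, n_states, tol = 1e-4, seed = 1L) {
  cc_excited_states(cc, gs, mlcc2JacobianApply, n_states, tol = tol,
                    seed = seed)
}
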