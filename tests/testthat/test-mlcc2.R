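# MLCC2: dressing, analytic S2 solve, ground state, Jacobian, excitation
# energies, and the CCS/CC2 limit identities.

test_that("the X1 transformation dresses and un-dresses exactly", {
  st <- fix_water_sto3g()
  cc <- st$cc
  set.seed(2)
  t1 <- matrix(rnorm(cc$v * cc$o, sd = 0.05), cc$v, cc$o)
  dr0 <- mlccx:::dress_cholesky(cc, t1 * 0)
  expect_identical(dr0$Lt, cc$L)
  # dressing with t1 then -t1 returns the original factors
  dr <- mlccx:::dress_cholesky(cc, t1)
  cc_mod <- cc; cc_mod$L <- dr$Lt
  back <- mlccx:::dress_cholesky(cc_mod, -t1)
  expect_lt(max(abs(back$Lt - cc$L)), 1e-12)
  # dressed 4-index integrals equal the brute-force similarity transform
  n <- cc$n
  Lp <- diag(n); Lh <- diag(n)
  Lp[cc$virt, cc$occ] <- -t1
  Lh[cc$occ, cc$virt] <- t(t1)
  gd <- dense_mo_integrals(st$ints, st$part$C)
  gt <- es("ap,pqrs->aqrs", Lp, gd)
  gt <- es("bq,aqrs->abrs", Lh, gt)
  gt <- es("cr,abrs->abcs", Lp, gt)
  gt <- es("ds,abcs->abcd", Lh, gt)
  g_pkg <- array(tcrossprod(matrix(dr$Lt, n * n, cc$n_J)), c(n, n, n, n))
  expect_lt(max(abs(g_pkg - gt)), 1e-9)
})

test_that("the analytic S2 solve satisfies its defining equation", {
  st <- fix_water_sto3g()
  cc <- st$cc
  set.seed(3)
  t1 <- matrix(rnorm(cc$v * cc$o, sd = 0.05), cc$v, cc$o)
  dr <- mlccx:::dress_cholesky(cc, t1)
  s2 <- mlccx:::solve_s2(cc, dr)
  res <- mlccx:::omega2_cc2(cc, dr, s2)
  expect_lt(max(abs(res)), 1e-10)
  # at x1 = 0 this is the MP2-like amplitude equation: loop oracle
  dr0 <- mlccx:::dress_cholesky(cc, t1 * 0)
  s2_0 <- mlccx:::solve_s2(cc, dr0)
  gd <- dense_mo_integrals(st$ints, st$part$C)
  eps <- st$part$eps
  o <- cc$o; v <- cc$v
  for (probe in 1:10) {
    id <- c(sample(v, 1), sample(o, 1), sample(v, 1), sample(o, 1))
    den <- eps[o + id[1]] + eps[o + id[3]] - eps[id[2]] - eps[id[4]]
    ref <- -gd[o + id[1], id[2], o + id[3], id[4]] / den
    expect_equal(s2_0[id[1], id[2], id[3], id[4]], ref, tolerance = 1e-9)
  }
  # empty active space: no doubles
  p0 <- semicanonicalize(st$ccref$F_ao_eff,
                         canonicalPartition(st$ccref, "none"))
  cderi0 <- mlccx:::rotate_cholesky(st$cderi,
                                    mlccx:::mo_rotation(st$part$C, p0$C,
                                                        st$ccref$S))
  cc0 <- mlccx:::cc_problem(p0, st$ccref, cderi0)
  dr00 <- mlccx:::dress_cholesky(cc0, matrix(0, cc0$v, cc0$o))
  expect_equal(length(mlccx:::solve_s2(cc0, dr00)), 0L)
})

test_that("MLCC2 limits: CCS gives zero correlation, full space gives CC2", {
  st <- fix_water_sto3g()
  # empty active space (CCS): zero correlation and x1 = 0 by Brillouin
  p0 <- semicanonicalize(st$ccref$F_ao_eff,
                         canonicalPartition(st$ccref, "none"))
  cderi0 <- mlccx:::rotate_cholesky(st$cderi,
                                    mlccx:::mo_rotation(st$part$C, p0$C,
                                                        st$ccref$S))
  cc0 <- mlccx:::cc_problem(p0, st$ccref, cderi0)
  gs0 <- mlcc2GroundState(cc0, tol = 1e-8)
  expect_lt(abs(gs0$energy_corr), 1e-9)
  expect_lt(max(abs(gs0$t1)), 1e-6)
  # full active space equals the independent spin-orbital CC2 oracle
  gs <- mlcc2GroundState(st$cc, tol = 1e-9)
  so <- so_problem(st)
  sol <- so_solve(so, "cc2", tol = 1e-10)
  expect_equal(gs$energy_corr, sol$energy_corr, tolerance = 1e-8)
})

test_that("residuals equal the independent oracle at arbitrary amplitudes", {
  st <- fix_water_sto3g()
  cc <- st$cc
  so <- so_problem(st)
  set.seed(5)
  for (k in 1:2) {
    t1 <- matrix(rnorm(cc$v * cc$o, sd = 0.05), cc$v, cc$o)
    t2r <- array(rnorm((cc$v * cc$o)^2, sd = 0.05),
                 c(cc$v, cc$o, cc$v, cc$o))
    t2 <- (t2r + aperm(t2r, c(3, 4, 1, 2))) / 2
    om <- mlccx:::mlcc2_omega_full(cc, t1, t2)
    rso <- so_residual(so, cs_expand_t1(t1, so), cs_expand_t2(t2, so), "cc2")
    expect_lt(max(abs(om$omega1 - so_readout_r1(rso$r1, so))), 1e-10)
    expect_lt(max(abs(om$omega2 - so_readout_r2(rso$r2, so))), 1e-10)
  }
})

test_that("the MLCC2 ground state is invariant to inactive-occupied rotations", {
  st <- fix_water_sto3g()
  # partition with 2 active occupied orbitals
  states <- ccsExcitationVectors(st$ccref, st$cderi, 1)
  states[[1]]$R2 <- approximateDoubles(states[[1]]$R1, states[[1]]$omega,
                                       st$ccref, st$cderi)
  dens <- buildCNTOMatrices(states)
  p <- semicanonicalize(st$ccref$F_ao_eff,
                        selectActiveSpace(dens, st$ccref, 2, 1))
  run_part <- function(part) {
    cd <- mlccx:::rotate_cholesky(st$cderi,
                                  mlccx:::mo_rotation(st$part$C, part$C,
                                                      st$ccref$S))
    mlcc2GroundState(mlccx:::cc_problem(part, st$ccref, cd),
                     tol = 1e-9)$energy_corr
  }
  e1 <- run_part(p)
  # rotate the two inactive occupied orbitals among themselves
  p2 <- p
  th <- 0.37
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  p2$C[, 1:2] <- p2$C[, 1:2] %*% R
  p2 <- semicanonicalize(st$ccref$F_ao_eff, p2)
  e2 <- run_part(p2)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("the Jacobian action is linear and matches finite differences", {
  st <- fix_water_sto3g()
  cc <- st$cc
  gs <- mlcc2GroundState(cc, tol = 1e-10)
  z <- mlcc2JacobianApply(cc, gs, matrix(0, cc$v, cc$o),
                          array(0, c(cc$v, cc$o, cc$v, cc$o)))
  expect_true(all(z$rho1 == 0))
  expect_true(all(z$rho2 == 0))
  set.seed(6)
  h <- 1e-5
  for (k in 1:2) {
    r1 <- matrix(rnorm(cc$v * cc$o), cc$v, cc$o)
    r2r <- array(rnorm((cc$v * cc$o)^2), c(cc$v, cc$o, cc$v, cc$o))
    r2 <- (r2r + aperm(r2r, c(3, 4, 1, 2))) / 2
    op <- mlccx:::mlcc2_omega_full(cc, gs$t1 + h * r1, gs$s2 + h * r2)
    om <- mlccx:::mlcc2_omega_full(cc, gs$t1 - h * r1, gs$s2 - h * r2)
    an <- mlcc2JacobianApply(cc, gs, r1, r2)
    expect_lt(max(abs(an$rho1 - (op$omega1 - om$omega1) / (2 * h))), 1e-6)
    expect_lt(max(abs(an$rho2 - (op$omega2 - om$omega2) / (2 * h))), 1e-6)
  }
})

test_that("excitation energies match the spin-orbital EOM and CIS limits", {
  st <- fix_water_sto3g()
  gs <- mlcc2GroundState(st$cc, tol = 1e-10)
  states <- mlcc2ExcitedStates(st$cc, gs, 2, tol = 1e-7)
  so <- so_problem(st)
  sol <- so_solve(so, "cc2", tol = 1e-11)
  eom <- so_eom_dense(so, sol, "cc2")
  om_so <- so_singlet_omegas(eom, 2)
  for (k in 1:2)
    expect_equal(states[[k]]$omega, om_so[k], tolerance = 1e-6)
  # empty active space: CIS energies from dense diagonalization
  p0 <- semicanonicalize(st$ccref$F_ao_eff,
                         canonicalPartition(st$ccref, "none"))
  cderi0 <- mlccx:::rotate_cholesky(st$cderi,
                                    mlccx:::mo_rotation(st$part$C, p0$C,
                                                        st$ccref$S))
  cc0 <- mlccx:::cc_problem(p0, st$ccref, cderi0)
  gs0 <- mlcc2GroundState(cc0, tol = 1e-10)
  st0 <- mlcc2ExcitedStates(cc0, gs0, 2, tol = 1e-9)
  A <- mlccx:::dense_ccs_matrix(st$ccref, st$cderi)
  cis <- sort(Re(eigen(A, only.values = TRUE)$values))
  for (k in 1:2)
    expect_equal(st0[[k]]$omega, cis[k], tolerance = 1e-8)
  # Davidson start-seed invariance
  states_b <- mlcc2ExcitedStates(st$cc, gs, 2, tol = 1e-7, seed = 99L)
  for (k in 1:2)
    expect_equal(states[[k]]$omega, states_b[[k]]$omega, tolerance = 1e-7)
})
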