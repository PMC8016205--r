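# Session-cached fixtures shared across test files (testthat runs the whole
# directory in one session, so expensive integrals are computed once).

.fix_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix_cache[[name]])) .fix_cache[[name]] <- build()
  .fix_cache[[name]]
}

# full problem stack for a system: integrals, RHF, frozen-core reference,
# canonical full-active partition, tight Cholesky factors, problem container
cc_stack <- function(system, tau = 1e-10, frozen_core = TRUE) {
  ints <- computeAOIntegrals(system)
  ref <- runRHF(ints, system)
  if (frozen_core) ref <- freezeCore(ref, ints, system)
  ccref <- ccReference(ref, ints)
  part <- semicanonicalize(ccref$F_ao_eff, canonicalPartition(ccref, "all"))
  cderi <- choleskyERI(ints, part$C, tau = tau)
  cc <- mlccx:::cc_problem(part, ccref, cderi)
  list(system = system, ints = ints, ref = ref, ccref = ccref,
       part = part, cderi = cderi, cc = cc)
}

fix_water_sto3g <- function() {
  fixture("water_sto3g", function() cc_stack(geomWater("sto-3g")))
}

fix_water_dz <- function() {
  fixture("water_dz", function() cc_stack(geomWater("cc-pvdz"), tau = 1e-8))
}

fix_water_cluster <- function() {
  # 1 + 3 waters, STO-3G
  fixture("water_cluster", function() {
    sys <- generateSolvatedFixture(3, seed = 42, solute = geomWater("sto-3g"))
    ints <- computeAOIntegrals(sys)
    ref <- runRHF(ints, sys)
    list(system = sys, ints = ints, ref = ref)
  })
}

# dense MO integrals by straightforward AO->MO transformation (independent
# of the Cholesky code path)
dense_mo_integrals <- function(ints, C) {
  n <- ints$n_ao
  CC <- kronecker(C, C)
  gm <- crossprod(CC, matrix(ints$g, n * n, n * n) %*% CC)
  array(gm, c(ncol(C), ncol(C), ncol(C), ncol(C)))
}

# spin-orbital problem for a cc_stack (shares only the integral values)
so_problem <- function(st, dense = TRUE) {
  gmo <- if (dense) dense_mo_integrals(st$ints, st$part$C) else
    reconstructMOIntegrals(st$cderi)
  Fmo <- crossprod(st$part$C, st$ccref$F_ao_eff %*% st$part$C)
  so_setup(gmo, Fmo, st$cc$o)
}
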