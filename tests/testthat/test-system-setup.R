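# Geometry ingestion, integral provider, RHF reference, frozen core and
# frozen-Fock embedding.

test_that("XYZ parsing reads, rejects, and round-trips geometries", {
  txt <- "3\nwater\nO 0.0 0.0 0.1173\nH 0.0 0.7572 -0.4692\nH 0.0 -0.7572 -0.4692"
  sys <- parseXYZ(txt)
  expect_equal(length(sys$atoms), 3L)
  expect_equal(sys$atoms[1], "O")
  expect_error(parseXYZ("0\nempty"), "at least one atom")
  expect_error(parseXYZ("2\nx\nO 0 0 0"), "expected 4 lines")
  expect_error(parseXYZ("1\nx\nXx 0 0 0"), "unknown element")
  expect_error(parseXYZ("1\nx\nO 0 zero 0"), "non-numeric")
  # round trip to 1e-10 Angstrom
  sys2 <- parseXYZ(writeXYZ(sys))
  expect_lt(max(abs(sys2$coords - sys$coords)), 1e-10)
  expect_identical(sys2$atoms, sys$atoms)
  # open-shell input is rejected
  expect_error(molecularSystem("O", matrix(0, 1, 3), charge = 1),
               "open-shell")
})

test_that("radius-based region selection matches a brute-force scan", {
  solute <- geomWater("sto-3g")
  sysw <- generateSolvatedFixture(20, seed = 9, solute = solute)
  grp <- mlccx:::molecule_groups(sysw)
  # limiting cases
  expect_equal(selectRegionByRadius(sysw, 1:3, 1e4),
               seq_along(sysw$atoms))
  expect_warning(sel0 <- selectRegionByRadius(sysw, 1:3, 1e-6),
                 "only the center atoms")
  expect_equal(sel0, 1:3)
  # brute-force oracle: molecule is in iff its oxygen lies within the
  # radius of any center atom (heavy-atom rule; fragments kept whole)
  radius <- 3.5
  centers <- 1:3
  keep_grp <- unique(grp[centers])
  for (g in unique(grp)) {
    members <- which(grp == g)
    heavy <- members[sysw$atoms[members] != "H"]
    d <- sapply(centers, function(cc)
      min(sqrt(rowSums((sysw$coords[heavy, , drop = FALSE] -
        matrix(sysw$coords[cc, ], length(heavy), 3, byrow = TRUE))^2))))
    if (min(d) <= radius) keep_grp <- union(keep_grp, g)
  }
  oracle <- sort(which(grp %in% keep_grp))
  expect_equal(selectRegionByRadius(sysw, centers, radius), oracle)
  # nested-region invariant (an empty shell selection only warns)
  inner <- suppressWarnings(selectRegionByRadius(sysw, centers, 2.5))
  expect_true(all(inner %in% oracle))
})

test_that("solvated fixture generation is deterministic and clash-free", {
  solute <- geomWater("sto-3g")
  expect_identical(generateSolvatedFixture(0, 1, solute), solute)
  a <- generateSolvatedFixture(5, seed = 3, solute = solute)
  b <- generateSolvatedFixture(5, seed = 3, solute = solute)
  expect_identical(a$coords, b$coords)
  # pairwise scan over intermolecular distances (bonded O-H pairs within a
  # fragment are of course shorter)
  grp <- mlccx:::molecule_groups(a)
  d <- as.matrix(dist(a$coords))
  inter <- outer(grp, grp, "!=")
  expect_gte(min(d[inter]), 1.5)
})

test_that("AO integrals satisfy provider contracts", {
  st <- fix_water_dz()
  ints <- st$ints
  expect_gt(min(eigen(ints$S, symmetric = TRUE, only.values = TRUE)$values),
            0)
  g <- ints$g
  set.seed(1)
  for (k in 1:20) {
    id <- sample(ints$n_ao, 4, replace = TRUE)
    v <- g[id[1], id[2], id[3], id[4]]
    expect_equal(g[id[3], id[4], id[1], id[2]], v, tolerance = 1e-12)
    expect_equal(g[id[2], id[1], id[3], id[4]], v, tolerance = 1e-12)
    expect_equal(g[id[1], id[2], id[4], id[3]], v, tolerance = 1e-12)
  }
  # independent diagonal routine agrees with the full tensor
  d <- eriDiagonal(ints)
  dref <- matrix(0, ints$n_ao, ints$n_ao)
  for (a in seq_len(ints$n_ao)) for (b in seq_len(ints$n_ao))
    dref[a, b] <- g[a, b, a, b]
  expect_lt(max(abs(d - dref)), 1e-12)
  expect_gte(min(d), 0)
})

test_that("RHF matches a dense fixed-point SCF oracle and is invariant", {
  h2 <- molecularSystem(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)),
                        basis = "sto-3g")
  ints <- computeAOIntegrals(h2)
  ref <- runRHF(ints, h2)
  expect_lt(ref$energy, -1.0)
  # independent plain fixed-point SCF (no DIIS, explicit loops)
  S <- ints$S; h <- ints$h; g <- ints$g
  es_ <- eigen(S, symmetric = TRUE)
  X <- es_$vectors %*% diag(1 / sqrt(es_$values))
  D <- matrix(0, 2, 2); E <- 0
  for (it in 1:60) {
    J <- matrix(0, 2, 2); K <- matrix(0, 2, 2)
    for (p in 1:2) for (q in 1:2) for (r in 1:2) for (s in 1:2) {
      J[p, q] <- J[p, q] + g[p, q, r, s] * D[r, s]
      K[p, q] <- K[p, q] + g[p, r, q, s] * D[r, s]
    }
    Fm <- h + 2 * J - K
    ef <- eigen(crossprod(X, Fm %*% X), symmetric = TRUE)
    C <- X %*% ef$vectors[, order(ef$values), drop = FALSE]
    D <- tcrossprod(C[, 1, drop = FALSE])
    E <- sum(D * (h + Fm)) + ints$e_nuc
  }
  expect_equal(ref$energy, E, tolerance = 1e-9)
  # Brillouin condition
  st <- fix_water_sto3g()
  Cw <- st$ref$C
  Fov <- crossprod(Cw[, 1:st$ref$n_occ],
                   st$ref$F %*% Cw[, st$ref$n_occ + 1:st$ref$n_virt])
  expect_lt(max(abs(Fov)), 1e-7)
  # rotational invariance
  th <- 0.613
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sys2 <- molecularSystem(st$system$atoms, st$system$coords %*% t(R),
                          basis = st$system$basis)
  ref2 <- runRHF(computeAOIntegrals(sys2), sys2)
  expect_equal(ref2$energy, st$ref$energy, tolerance = 1e-9)
})

test_that("frozen core counts follow the element table", {
  h2 <- molecularSystem(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)),
                        basis = "sto-3g")
  ih <- computeAOIntegrals(h2)
  rh <- runRHF(ih, h2)
  expect_identical(freezeCore(rh, ih, h2)$frozen_occ, integer(0))
  st <- fix_water_sto3g()
  expect_equal(length(st$ref$frozen_occ), 1L)
})

test_that("frozen-core embedding equals orbital deletion in the oracle", {
  st <- fix_water_sto3g()
  # package: frozen-Fock embedding (h_eff = h + F^f) on retained orbitals
  gs <- mlcc2GroundState(st$cc, tol = 1e-9)
  # oracle: delete the core row/columns, use the effective Fock directly
  so <- so_problem(st)
  sol <- so_solve(so, "cc2", tol = 1e-10)
  expect_equal(gs$energy_corr, sol$energy_corr, tolerance = 1e-8)
})

test_that("the frozen Fock matrix reproduces the total-density Fock", {
  wc <- fix_water_cluster()
  ref <- wc$ref; ints <- wc$ints
  # empty frozen set: F^f = 0 and F is the standard Fock matrix
  fb0 <- buildFrozenFock(ref, ints, integer(0))
  expect_lt(max(abs(fb0$F_f)), 1e-14)
  expect_lt(max(abs(fb0$F - ref$F)), 1e-8)
  # freeze the occupieds of two solvent waters (by energy order they are
  # well-defined); brute force: Fock from the total density
  frozen <- c(2L, 3L, 6L, 7L, 8L, 9L, 10L, 11L)
  fb <- buildFrozenFock(ref, ints, frozen)
  F_total <- ints$h + mlccx:::g_of_D(ints, ref$D)
  expect_lt(max(abs(fb$F - F_total)), 1e-10)
  expect_error(buildFrozenFock(ref, ints, seq_len(ref$n_occ)),
               "cannot freeze")
})
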