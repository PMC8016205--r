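# Molecular systems: XYZ ingestion, active-region selection and the seeded
# solvated fixture generator.

#' Create a molecular system
#'
#' @param atoms character vector of element symbols
#' @param coords numeric matrix (n x 3) of Cartesian positions in Angstrom
#' @param charge total molecular charge (integer); the electron count must be
#'   even (closed-shell restriction)
#' @param basis basis-set label, or per-atom character vector for mixed-basis
#'   runs
#' @param region_levels optional named list of nested atom-index sets, outer
#'   to inner (e.g. HF-active, CC-active, CCSD-active); each set must contain
#'   the next
#' @return an object of class `molecular_system`
#' @export
molecularSystem <- function(atoms, coords, charge = 0L, basis = "sto-3g",
                            region_levels = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(atoms))
    stop("coords must be an n x 3 matrix matching atoms")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  element_number(atoms)  # validates symbols
  ne <- sum(element_number(atoms)) - charge
  if (ne < 0) stop("negative electron count")
  if (ne %% 2 != 0)
    stop("open-shell systems are not supported (odd electron count ", ne, ")")
  if (length(region_levels) > 1) {
    for (k in seq_len(length(region_levels) - 1)) {
      if (!all(region_levels[[k + 1]] %in% region_levels[[k]]))
        stop("region levels must be nested (level ", k + 1,
             " is not contained in level ", k, ")")
    }
  }
  structure(list(atoms = as.character(atoms), coords = unname(coords),
                 charge = as.integer(charge), basis = basis,
                 region_levels = region_levels),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular system:", length(x$atoms), "atoms, charge", x$charge,
      ", basis", paste(unique(x$basis), collapse = "/"), "\n")
  invisible(x)
}

#' Number of electrons of a system
#' @param system a `molecular_system`
#' @return integer electron count
#' @export
nElectrons <- function(system) {
  sum(element_number(system$atoms)) - system$charge
}

#' Parse an XYZ-format geometry
#'
#' Standard two-header-line dialect: atom count, comment line, then one
#' `"El x y z"` line per atom with coordinates in Angstrom.
#'
#' @param text a single string or character vector of lines
#' @param ... passed to [molecularSystem()] (charge, basis, region_levels)
#' @return a `molecular_system`
#' @export
parseXYZ <- function(text, ...) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("\\s+$", "", text)
  if (length(text) < 1L) stop("XYZ parse error: empty input")
  n <- suppressWarnings(as.integer(trimws(text[1])))
  if (is.na(n)) stop("XYZ parse error: line 1: malformed atom-count header")
  if (n < 1) stop("XYZ parse error: line 1: system must contain at least one atom")
  if (length(text) < n + 2)
    stop("XYZ parse error: expected ", n + 2, " lines, got ", length(text))
  atoms <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- n_line <- k + 2L
    toks <- strsplit(trimws(text[ln]), "\\s+")[[1]]
    if (length(toks) < 4)
      stop("XYZ parse error: line ", ln, ": expected 'El x y z'")
    atoms[k] <- toks[1]
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error: line ", ln, ": non-numeric coordinate")
    coords[k, ] <- xyz
  }
  bad <- which(is.na(match(atoms, .element_table$symbol)))
  if (length(bad))
    stop("XYZ parse error: line ", bad[1] + 2L, ": unknown element '",
         atoms[bad[1]], "'")
  molecularSystem(atoms, coords, ...)
}

#' Write a system in XYZ format
#' @param system a `molecular_system`
#' @param comment comment-line text
#' @return a single string (two header lines plus one line per atom)
#' @export
writeXYZ <- function(system, comment = "") {
  body <- sprintf("%-3s %18.12f %18.12f %18.12f", system$atoms,
                  system$coords[, 1], system$coords[, 2], system$coords[, 3])
  paste(c(length(system$atoms), comment, body), collapse = "\n")
}

# Connected molecular fragments from covalent radii (bond if the pair
# distance is below 1.3 x sum of covalent radii).
molecule_groups <- function(system) {
  n <- length(system$atoms)
  r <- element_covalent_radius(system$atoms)
  d <- as.matrix(stats::dist(system$coords))
  bonded <- d < 1.3 * outer(r, r, "+") & d > 0
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(bonded[i, ])
      if (length(nb)) {
        m <- min(grp[c(i, nb)])
        if (any(grp[c(i, nb)] != m)) { grp[c(i, nb)] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

#' Select active atoms within a radius of a set of center atoms
#'
#' Solvent (and any other) molecules are kept or dropped atomically: a
#' fragment enters the selection when any of its heavy atoms (all atoms, for
#' fragments without heavy atoms) lies within `radius` of any center atom.
#' Fragments containing a center atom are always kept.
#'
#' @param system a `molecular_system`
#' @param center_atoms integer indices of the center atoms
#' @param radius selection radius in Angstrom (> 0)
#' @return sorted integer vector of selected atom indices
#' @export
selectRegionByRadius <- function(system, center_atoms, radius) {
  n <- length(system$atoms)
  if (!length(center_atoms) || any(center_atoms < 1 | center_atoms > n))
    stop("center atoms out of range")
  if (radius <= 0) stop("radius must be positive")
  grp <- molecule_groups(system)
  ctr <- system$coords[center_atoms, , drop = FALSE]
  sel_groups <- unique(grp[center_atoms])
  for (g in unique(grp)) {
    members <- which(grp == g)
    heavy <- members[system$atoms[members] != "H"]
    if (!length(heavy)) heavy <- members
    dmin <- min(apply(ctr, 1, function(c0)
      sqrt(rowSums((system$coords[heavy, , drop = FALSE] -
                      matrix(c0, length(heavy), 3, byrow = TRUE))^2))))
    if (dmin <= radius) sel_groups <- union(sel_groups, g)
  }
  sel <- sort(which(grp %in% sel_groups))
  if (length(sel) == length(center_atoms) && all(sort(center_atoms) == sel))
    warning("radius selection returned only the center atoms")
  sel
}

# rigid water fragment (Angstrom), O at origin
.water_fragment <- function() {
  list(atoms = c("O", "H", "H"),
       coords = rbind(c(0, 0, 0),
                      c(0.7572, 0, 0.5865),
                      c(-0.7572, 0, 0.5865)))
}

.random_rotation <- function() {
  # QR of a random normal matrix, sign-fixed: Haar-ish, good enough here
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a seeded solvated fixture
#'
#' Packs `n_waters` rigid water molecules in a shell around the solute with a
#' simple rejection scheme; deterministic for a fixed seed.
#'
#' @param n_waters number of water molecules (>= 0)
#' @param seed RNG seed
#' @param solute a `molecular_system` (its basis and charge are kept)
#' @param clash minimum allowed interatomic distance in Angstrom
#' @return a `molecular_system` of solute plus waters
#' @export
generateSolvatedFixture <- function(n_waters, seed, solute, clash = 1.5) {
  stopifnot(n_waters >= 0)
  if (n_waters == 0) return(solute)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  atoms <- solute$atoms
  coords <- solute$coords
  centroid <- colMeans(solute$coords)
  r_solute <- max(sqrt(rowSums(sweep(solute$coords, 2, centroid)^2)))
  frag <- .water_fragment()
  placed <- 0
  r_shell <- r_solute + 2.6
  attempts <- 0
  while (placed < n_waters) {
    attempts <- attempts + 1
    if (attempts > 5000 * n_waters)
      stop("failed to pack ", n_waters, " waters for seed ", seed)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rad <- r_shell + runif(1) * (1.2 + 0.35 * placed)
    o_pos <- centroid + rad * u
    rot <- .random_rotation()
    w <- frag$coords %*% t(rot) + matrix(o_pos, 3, 3, byrow = TRUE)
    d2 <- outer(rowSums(w^2), rowSums(coords^2), "+") - 2 * w %*% t(coords)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin < clash * 1.2) next
    atoms <- c(atoms, frag$atoms)
    coords <- rbind(coords, w)
    placed <- placed + 1
  }
  molecularSystem(atoms, coords, charge = solute$charge, basis = solute$basis,
                  region_levels = solute$region_levels)
}
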