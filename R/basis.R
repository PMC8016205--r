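# Gaussian basis sets: plain-text registry bundled under inst/extdata/basis.
# Shells are contracted Cartesian Gaussians; the engine normalizes each
# Cartesian component through the overlap diagonal after integral evaluation,
# so contraction coefficients here follow the usual convention of referring
# to normalized primitives.

.basis_cache <- new.env(parent = emptyenv())

#' Load a bundled Gaussian basis set
#'
#' @param name basis-set label, e.g. `"sto-3g"`, `"cc-pvdz"`, `"aug-cc-pvdz"`
#'   (case-insensitive).
#' @return a named list (one entry per element symbol) of shells; each shell
#'   has fields `l` (angular momentum), `exps` and `coefs`.
#' @export
loadBasis <- function(name) {
  key <- tolower(name)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  path <- system.file("extdata", "basis", paste0(key, ".dat"), package = "mlccx")
  if (path == "")
    stop("unsupported basis set '", name, "': no bundled data file")
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  basis <- list()
  i <- 1L
  cur_el <- NULL
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)
  while (i <= length(lines)) {
    toks <- strsplit(lines[i], "\\s+")[[1]]
    if (toks[1] == "AUGMENT") {
      parent <- loadBasis(toks[2])
      basis <- parent
      i <- i + 1L
    } else if (toks[1] == "ELEMENT") {
      cur_el <- toks[2]
      if (is.null(basis[[cur_el]])) basis[[cur_el]] <- list()
      i <- i + 1L
    } else if (toks[1] == "SHELL") {
      l <- lmap[[toks[2]]]
      np <- as.integer(toks[3])
      prim <- matrix(0, np, 2)
      for (k in seq_len(np)) {
        v <- as.numeric(strsplit(lines[i + k], "\\s+")[[1]])
        prim[k, ] <- v[1:2]
      }
      basis[[cur_el]] <- c(basis[[cur_el]],
                           list(list(l = l, exps = prim[, 1], coefs = prim[, 2])))
      i <- i + np + 1L
    } else {
      stop("malformed basis file line: ", lines[i])
    }
  }
  .basis_cache[[key]] <- basis
  basis
}

# number of Cartesian components of a shell
.ncart <- function(l) (l + 1L) * (l + 2L) / 2L

# Build the shell list consumed by the C++ engine.  `basis` in the system may
# be a single label or a per-atom character vector (mixed-basis runs assign
# the larger basis to atoms of the higher-level region).
build_shells <- function(system) {
  basis_names <- system$basis
  if (length(basis_names) == 1L) basis_names <- rep(basis_names, length(system$atoms))
  stopifnot(length(basis_names) == length(system$atoms))
  shells <- list()
  ao_atom <- integer(0)
  ao_l <- integer(0)
  coords_bohr <- system$coords * BOHR_PER_ANGSTROM
  for (ia in seq_along(system$atoms)) {
    el <- system$atoms[ia]
    bs <- loadBasis(basis_names[ia])
    if (is.null(bs[[el]]))
      stop("basis '", basis_names[ia], "' has no data for element ", el)
    for (sh in bs[[el]]) {
      # primitive normalization with the (l,0,0) Cartesian convention
      l <- sh$l
      dfact <- if (l < 1) 1 else prod(seq(2 * l - 1, 1, by = -2))
      nrm <- (2 * sh$exps / pi)^0.75 * (4 * sh$exps)^(l / 2) / sqrt(dfact)
      shells[[length(shells) + 1L]] <- list(
        l = l, atom = ia, center = coords_bohr[ia, ],
        exps = sh$exps, coefs = sh$coefs * nrm)
      ao_atom <- c(ao_atom, rep(ia, .ncart(l)))
      ao_l <- c(ao_l, rep(l, .ncart(l)))
    }
  }
  list(shells = shells, ao_atom = ao_atom, ao_l = ao_l, n_ao = length(ao_atom))
}
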