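# Bundled equilibrium-like geometries (Angstrom) used by examples and tests.
# The para-nitroaniline geometry is a synthetic idealized planar structure.

#' Bundled example geometries
#'
#' @param basis basis-set label passed to [molecularSystem()]
#' @return a `molecular_system`
#' @name geometries
NULL

#' @rdname geometries
#' @export
geomWater <- function(basis = "sto-3g") {
  molecularSystem(c("O", "H", "H"),
                  rbind(c(0, 0, 0.1173),
                        c(0, 0.7572, -0.4692),
                        c(0, -0.7572, -0.4692)),
                  basis = basis)
}

#' @rdname geometries
#' @export
geomFormaldehyde <- function(basis = "sto-3g") {
  molecularSystem(c("C", "O", "H", "H"),
                  rbind(c(0, 0, 0),
                        c(0, 0, 1.208),
                        c(0, 0.943, -0.587),
                        c(0, -0.943, -0.587)),
                  basis = basis)
}

#' @rdname geometries
#' @export
geomEthene <- function(basis = "sto-3g") {
  molecularSystem(c("C", "C", "H", "H", "H", "H"),
                  rbind(c(0, 0, 0.6695),
                        c(0, 0, -0.6695),
                        c(0, 0.9289, 1.2321),
                        c(0, -0.9289, 1.2321),
                        c(0, 0.9289, -1.2321),
                        c(0, -0.9289, -1.2321)),
                  basis = basis)
}

#' @rdname geometries
#' @export
geomParaNitroaniline <- function(basis = "sto-3g") {
  # idealized planar ring in the xz plane; NH2 at +z, NO2 at -z
  molecularSystem(
    c("C", "C", "C", "C", "C", "C", "H", "H", "H", "H",
      "N", "H", "H", "N", "O", "O"),
    rbind(c(0.0000, 0, 1.3950),
          c(1.2081, 0, 0.6975),
          c(1.2081, 0, -0.6975),
          c(0.0000, 0, -1.3950),
          c(-1.2081, 0, -0.6975),
          c(-1.2081, 0, 0.6975),
          c(2.1476, 0, 1.2400),
          c(2.1476, 0, -1.2400),
          c(-2.1476, 0, -1.2400),
          c(-2.1476, 0, 1.2400),
          c(0.0000, 0, 2.7470),
          c(0.8249, 0, 3.3030),
          c(-0.8249, 0, 3.3030),
          c(0.0000, 0, -2.8630),
          c(1.0860, 0, -3.4400),
          c(-1.0860, 0, -3.4400)),
    basis = basis)
}
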