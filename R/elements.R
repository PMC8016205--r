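# Element data: atomic numbers, covalent radii (Angstrom, for molecule
# detection), and frozen-core orbital counts per element.

.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  number = 1:18,
  covalent_radius = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57,
                      0.58, 1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06),
  n_core = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 5, 5, 5, 5, 5, 5, 5, 5),
  stringsAsFactors = FALSE
)

element_number <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .element_table$number[idx]
}

element_covalent_radius <- function(symbols) {
  .element_table$covalent_radius[match(symbols, .element_table$symbol)]
}

element_core_count <- function(symbols) {
  .element_table$n_core[match(symbols, .element_table$symbol)]
}
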