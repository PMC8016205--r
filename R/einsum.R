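# Minimal two-operand einsum used by the coupled cluster contractions:
# es("mnef,afmn->ae", X, Y) contracts indices shared between operands and
# absent from the output; no repeated indices within one operand.

es <- function(spec, A, B) {
  m <- regmatches(spec, regexec("^([a-z]+),([a-z]+)->([a-z]*)$", spec))[[1]]
  stopifnot(length(m) == 4)
  ia <- strsplit(m[2], "")[[1]]
  ib <- strsplit(m[3], "")[[1]]
  io <- strsplit(m[4], "")[[1]]
  da <- dim(A) %||% length(A)
  db <- dim(B) %||% length(B)
  stopifnot(length(da) == length(ia), length(db) == length(ib))
  contract <- setdiff(intersect(ia, ib), io)
  keepA <- setdiff(ia, contract)
  keepB <- setdiff(ib, contract)
  stopifnot(setequal(io, c(keepA, keepB)))
  pa <- c(match(keepA, ia), match(contract, ia))
  pb <- c(match(contract, ib), match(keepB, ib))
  Ap <- aperm(A, pa)
  Bp <- aperm(B, pb)
  dka <- da[match(keepA, ia)]
  dkb <- db[match(keepB, ib)]
  dc <- da[match(contract, ia)]
  stopifnot(all(dc == db[match(contract, ib)]))
  M <- matrix(Ap, prod(dka), prod(dc)) %*% matrix(Bp, prod(dc), prod(dkb))
  out <- array(M, c(dka, dkb))
  cur <- c(keepA, keepB)
  aperm(out, match(io, cur))
}

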