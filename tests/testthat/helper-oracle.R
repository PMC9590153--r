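# Independent brute-force oracles, kept deliberately naive: enumerate every
# k-tuple over the haplotype codes, keep the nondecreasing ones, and filter
# by recomputing dosages from first principles with intToBits().

oracle_hap_bits <- function(code, nmrk) {
  as.integer(intToBits(code))[seq_len(nmrk)]
}

oracle_dosage <- function(hc, nmrk) {
  Reduce(`+`, lapply(hc, oracle_hap_bits, nmrk = nmrk))
}

# all multisets of size k over 0..(2^nmrk - 1), as a list of sorted vectors
oracle_multisets <- function(nmrk, k) {
  nhap <- 2^nmrk
  grid <- do.call(expand.grid, rep(list(0:(nhap - 1)), k))
  keep <- apply(grid, 1L, function(v) all(diff(v) >= 0))
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}

# all haplotype combinations matching g at non-missing markers
oracle_enumerate <- function(g, ploidy) {
  nmrk <- length(g)
  obs <- which(!is.na(g))
  ms <- oracle_multisets(nmrk, ploidy)
  keep <- vapply(ms, function(hc) {
    d <- oracle_dosage(hc, nmrk)
    all(d[obs] == g[obs])
  }, logical(1L))
  ms[keep]
}

# canonical string form for set comparison
comb_strings <- function(m) {
  if (is.list(m)) vapply(m, paste, character(1L), collapse = "+")
  else apply(m, 2L, paste, collapse = "+")
}
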