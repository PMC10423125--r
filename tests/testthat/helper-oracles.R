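# Independent brute-force oracles and shared fixtures.

# Full 6-bit isometry group, built once per session (cached in the
# global env because helpers are re-sourced per test file).
full_group <- function() {
  g <- get0(".codonsym_test_full_group", envir = globalenv())
  if (is.null(g)) {
    g <- isometry_group(6, "full")
    assign(".codonsym_test_full_group", g, envir = globalenv())
  }
  g
}

# Brute-force affine test on 0-based indices: some translation of the
# set contains 0 and is closed under XOR (all pairs checked).
oracle_is_affine <- function(idx) {
  for (t in idx) {
    s <- sort(bitwXor(idx, t))
    if (s[1] != 0) next
    if (all(outer(s, s, bitwXor) %in% s)) return(TRUE)
  }
  FALSE
}

# Brute-force coordinate-alignment test: the set equals the full slice
# obtained by fixing its constant bit coordinates.
oracle_is_aligned <- function(idx, n = 6) {
  bits <- t(vapply(idx, function(i) as.integer(intToBits(i)[n:1]), integer(n)))
  fixed <- which(apply(bits, 2, function(c) length(unique(c)) == 1))
  length(idx) == 2^(n - length(fixed))
}

# Naive per-element stabilizer filter: compare each element's sorted
# image of the set against the set (set-image comparison, independent of
# the label-invariance filter used by the implementation).
oracle_stabilizer_rows <- function(codons, group, scheme = encoding_scheme()) {
  idx <- sort(as.integer(codon_index(codons, scheme)) + 1L)
  which(vapply(seq_len(group$order), function(i)
    identical(sort(group$action[i, idx]), idx), logical(1)))
}

# Naive per-element color-preserving filter: every color class must map
# onto itself as a set.
oracle_color_rows <- function(coloring, group, scheme = encoding_scheme()) {
  cols <- unclass(coloring)
  class_idx <- lapply(split(names(coloring), cols), function(cods)
    sort(as.integer(codon_index(cods, scheme)) + 1L))
  which(vapply(seq_len(group$order), function(i)
    all(vapply(class_idx, function(idx)
      identical(sort(group$action[i, idx]), idx), logical(1))),
    logical(1)))
}
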