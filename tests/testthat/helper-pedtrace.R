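# Shared builders for small in-memory fixtures.

# Genotype matrix from a plain numeric matrix/vector, with default ids.
make_geno <- function(codes, ids = NULL, loci = NULL) {
  m <- as.matrix(codes)
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(nrow(m)))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, loci)
  storage.mode(m) <- "integer"
  m
}

# A small reproducible population for assignment tests.
tiny_population <- function(seed = 42, n_parents = 12, n_loci = 20,
                            n_crosses = 8) {
  generate_population(n_parents = n_parents, n_loci = n_loci,
                      n_crosses = n_crosses, seed = seed)
}
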