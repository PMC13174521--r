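# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small default genome + tumor, cached across test files
shared_genome <- function() {
  if (is.null(.fixture_env$genome)) {
    .fixture_env$genome <- build_normal_genome(genome_config(seed = 101))
  }
  .fixture_env$genome
}

shared_tumor <- function() {
  if (is.null(.fixture_env$tumor)) {
    .fixture_env$tumor <- derive_tumor_genome(shared_genome(),
                                              somatic_config(seed = 202))
  }
  .fixture_env$tumor
}

# a reduced genome for expensive per-test builds
small_config <- function(seed = 1) {
  genome_config(n_autosome_mimics = 1L, n_acrocentric_mimics = 2L,
                chrom_length = 40000L, array_length = 6000L,
                rdna_copies_per_arm = 3L, dj_unit_length = 1000L,
                seed = seed)
}

random_variants_on <- function(seq, n, seed) {
  set.seed(seed)
  pos <- sort(sample(seq_len(nchar(seq) - 2L), n)) - 1L
  ref <- substring(seq, pos + 1L, pos + 1L)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "", USE.NAMES = FALSE)
  data.frame(pos0 = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}
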