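# Small shared fixtures, built in code.

# A deliberately tiny architecture (2 Tn5 indexes, 3 barcodes per round,
# suffix-distinct) for tests that need a small combinatorial space.
tiny_architecture <- function() {
  barcode_architecture(
    tn5_indexes = c("AAA", "CCC"),
    round_whitelists = list(
      c("AACGTAC", "AATTGCA", "AAGCATG"),
      c("CCCGTAC", "CCTTGCA", "CCGCATG"),
      c("GGCGTAC", "GGTTGCA", "GGGCATG")))
}

# Random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Substitute bases at given 1-based positions with a different base
mutate_at <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

# A simulated read batch shared by several demux tests
make_read_batch <- function(n_cells, fragments_per_cell, seed,
                            error_rate = c(barcode = 0, genomic = 0),
                            dup = dup_model(1, 1), tss_frac = 0,
                            peak_frac = 0.5,
                            frag_len = frag_model("ffpe")) {
  arch <- barcode_architecture()
  genome <- simulate_reference(seed = seed)
  cells <- simulate_cells(n_cells, arch, seed = seed + 1,
                          fragments_per_cell = fragments_per_cell)
  frags <- simulate_fragments(genome, cells, frag_model = frag_len,
                              dup_model = dup, tss_frac = tss_frac,
                              peak_frac = peak_frac, seed = seed + 2)
  reads <- emit_reads(frags, cells, genome, arch, error_rate = error_rate,
                      seed = seed + 3)
  list(arch = arch, genome = genome, cells = cells, frags = frags,
       reads = reads)
}

# Expected cell key (bc1-bc2-bc3-tn5) per read id, from generator truth
truth_keys <- function(batch) {
  idx <- match(batch$reads$truth$cell, batch$cells$cell)
  stats::setNames(
    paste(batch$cells$bc1[idx], batch$cells$bc2[idx], batch$cells$bc3[idx],
          batch$cells$tn5[idx], sep = "-"),
    batch$reads$truth$read_id)
}
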