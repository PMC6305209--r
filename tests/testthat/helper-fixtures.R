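# Shared fixture builders.  All fixtures are generated in code under fixed
# seeds; nothing is read from disk except files the tests write themselves.

random_genome <- function(lengths, seed) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    genome_from_sequences(seqs)
  })
}

# a two-gene fixture with one planted exonic duplication
dup_fixture <- function(seed = 42, segment_length = 100L,
                        hamming_distance = 0L, exon_len = 300L,
                        chrom_len = 10000L, positions = NULL) {
  specs <- list(
    gene_spec("gA", "chr1", 1000, exon_lens = exon_len),
    gene_spec("gB", "chr2", 2000, exon_lens = exon_len))
  dups <- list(duplication_spec("gA", "gB", segment_length,
                                hamming_distance, positions = positions,
                                source_offset = 50, target_offset = 80))
  generate_genome(c(chr1 = chrom_len, chr2 = chrom_len), specs, dups,
                  seed = seed)
}

# sorted canonical form for hit-set comparison
hit_key <- function(hits) {
  sort(paste(hits$chrom, hits$start, hits$strand, hits$mismatches))
}

expect_same_hits <- function(a, b) {
  expect_identical(hit_key(a), hit_key(b))
}

resource_df <- function(resource) resource$records
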