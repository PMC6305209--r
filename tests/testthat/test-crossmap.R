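test_that("a unique random genome yields an empty resource", {
  specs <- list(gene_spec("gA", "chr1", 500, exon_lens = 200L),
                gene_spec("gB", "chr2", 700, exon_lens = 250L))
  fx <- generate_genome(c(chr1 = 6000, chr2 = 6000), specs, seed = 61)
  expect_equal(nrow(fx$truth), 0L)
  res <- compute_crossmap(fx$models, fx$genome)
  expect_equal(nrow(resource_df(res)), 0L)
  expect_false(is_crossmappable(res, "gA", "gB"))
  expect_equal(crossmap_count(res, "gA", "gB"), 0L)
})

test_that("an exact 100 bp copy gives crossmap 26 in both directions at k=75, m=0", {
  fx <- dup_fixture(seed = 42)
  res <- compute_crossmap(fx$models, fx$genome, max_mismatches = 0)
  expect_equal(crossmap_count(res, "gA", "gB"), 26L)  # 100 - 75 + 1
  expect_equal(crossmap_count(res, "gB", "gA"), 26L)
  tr <- truth_resource(fx$truth, 0)
  expect_identical(resource_df(res), resource_df(tr))
})

test_that("a mismatched copy gives the oracle count, strictly below 26", {
  # 3 substitutions spread so that some k-mers exceed m = 2
  fx <- dup_fixture(seed = 43, hamming_distance = 3L,
                    positions = c(20L, 50L, 80L))
  res <- compute_crossmap(fx$models, fx$genome, max_mismatches = 2)
  tr <- truth_resource(fx$truth, 2)
  expect_identical(resource_df(res), resource_df(tr))
  expect_lt(crossmap_count(res, "gA", "gB"), 26L)
  expect_gt(crossmap_count(res, "gA", "gB"), 0L)
})

test_that("cross-mappability can be asymmetric for unequal gene lengths", {
  # gB's exon is exactly the copied segment, so all of gB's k-mers lie
  # inside the copy; but gA's k-mers overhanging the segment by one base
  # still start inside gB's exon and pass at m = 1, so gA -> gB > gB -> gA
  specs <- list(gene_spec("gA", "chr1", 1000, exon_lens = 400L),
                gene_spec("gB", "chr2", 2000, exon_lens = 100L))
  dups <- list(duplication_spec("gA", "gB", 100L, source_offset = 150,
                                target_offset = 0))
  fx <- generate_genome(c(chr1 = 8000, chr2 = 8000), specs, dups, seed = 47)
  res <- compute_crossmap(fx$models, fx$genome, max_mismatches = 1)
  expect_identical(resource_df(res), resource_df(truth_resource(fx$truth, 1)))
  ab <- crossmap_count(res, "gA", "gB")
  ba <- crossmap_count(res, "gB", "gA")
  expect_false(ab == ba)
})

test_that("UTR-only duplications cross-map through the 36-mer path", {
  specs <- list(
    gene_spec("gA", "chr1", 1000, exon_lens = 200L, utr5_len = 80L),
    gene_spec("gB", "chr2", 2000, exon_lens = 200L, utr5_len = 80L))
  dups <- list(duplication_spec("gA", "gB", 60L, region = "utr",
                                source_offset = 10, target_offset = 10))
  fx <- generate_genome(c(chr1 = 8000, chr2 = 8000), specs, dups, seed = 53)
  res <- compute_crossmap(fx$models, fx$genome, max_mismatches = 0)
  expect_identical(resource_df(res), resource_df(truth_resource(fx$truth, 0)))
  expect_equal(crossmap_count(res, "gA", "gB"), 25L)  # 60 - 36 + 1
})

test_that("counts are monotone in the mismatch budget", {
  fx <- dup_fixture(seed = 59, hamming_distance = 4L)
  prev_ab <- 0L
  for (m in 0:3) {
    res <- compute_crossmap(fx$models, fx$genome, max_mismatches = m)
    expect_identical(resource_df(res),
                     resource_df(truth_resource(fx$truth, m)))
    ab <- crossmap_count(res, "gA", "gB")
    expect_gte(ab, prev_ab)
    prev_ab <- ab
  }
  # and bounded by the number of enumerable k-mers from the source
  km <- enumerate_kmers(fx$models$gA, fx$genome)
  expect_lte(prev_ab, nrow(km))
})

test_that("the mappability shortcut never changes the result", {
  for (seed in c(42, 43, 53)) {
    fx <- if (seed == 53) {
      specs <- list(
        gene_spec("gA", "chr1", 1000, exon_lens = 200L, utr5_len = 80L),
        gene_spec("gB", "chr2", 2000, exon_lens = 200L, utr5_len = 80L))
      generate_genome(c(chr1 = 8000, chr2 = 8000), specs,
                      list(duplication_spec("gA", "gB", 60L, region = "utr",
                                            source_offset = 10,
                                            target_offset = 10)), seed = 53)
    } else dup_fixture(seed = seed, hamming_distance = (seed == 43) * 3L)
    full <- compute_crossmap(fx$models, fx$genome, max_mismatches = 2,
                             use_shortcut = FALSE)
    fast <- compute_crossmap(fx$models, fx$genome, max_mismatches = 2,
                             use_shortcut = TRUE)
    expect_identical(resource_df(full), resource_df(fast))
  }
})

test_that("lookups honour direction and absent pairs", {
  res <- crossmap_resource(data.frame(gene_a = "A", gene_b = "B", count = 5L))
  expect_true(is_crossmappable(res, "A", "B", "a_to_b"))
  expect_false(is_crossmappable(res, "B", "A", "a_to_b"))
  expect_true(is_crossmappable(res, "B", "A", "either"))
  expect_false(is_crossmappable(res, "A", "C", "either"))
  expect_equal(crossmap_count(res, "X", "Y"), 0L)
})

test_that("the resource TSV round-trips and validates", {
  res <- crossmap_resource(data.frame(
    gene_a = c("b", "a", "a"), gene_b = c("a", "c", "b"),
    count = c(2L, 7L, 3L)))
  path <- tempfile(fileext = ".tsv")
  write_resource(res, path)
  back <- read_resource(path)
  expect_identical(resource_df(back), resource_df(res))
  expect_identical(resource_df(res)$gene_a, c("a", "a", "b"))  # sorted

  # empty round trip
  p2 <- tempfile(); write_resource(crossmap_resource(), p2)
  expect_equal(nrow(resource_df(read_resource(p2))), 0L)

  # invalid rows
  writeLines(c("gene_a\tgene_b\tcount", "x\ty\t0"), path)
  expect_error(read_resource(path), ">= 1")
  writeLines(c("gene_a\tgene_b\tcount", "x\ty\t1.5"), path)
  expect_error(read_resource(path), "non-integer")
  writeLines(c("bad\theader\there", "x\ty\t1"), path)
  expect_error(read_resource(path), "malformed")
})
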