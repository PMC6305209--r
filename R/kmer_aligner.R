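# Positional k-mer enumeration and approximate (Hamming) genomic placement.
# k-mers drawn from a gene's collapsed regions are the proxy for RNA-seq
# reads; placements tolerate up to a configurable number of mismatches on
# either strand (no indels), mirroring Bowtie v1 -v -a behaviour.

#' Enumerate positional k-mers from a gene's collapsed regions
#'
#' For each collapsed interval of length `L`, yields `max(0, L - k + 1)`
#' k-mers, one per start offset, with `k = k_exon` for the exon class and
#' `k = k_utr` for the UTR class.  k-mers never span two disjoint intervals.
#' k-mers containing N are dropped; the number dropped is recorded in the
#' `n_skipped` attribute.
#'
#' @param model a `gene_model`.
#' @param genome a `genome_seq`.
#' @param k_exon,k_utr k-mer lengths for exonic and UTR regions (defaults 75
#'   and 36; UTRs get a shorter k because they tend to be shorter regions).
#' @return data frame with columns gene_id, region_class, chrom, start, k,
#'   sequence; attribute `n_skipped` counts N-containing k-mers dropped.
#' @export
enumerate_kmers <- function(model, genome, k_exon = 75L, k_utr = 36L) {
  stopifnot(k_exon >= 1L, k_utr >= 1L)
  out <- list()
  for (cls in c("exon", "utr")) {
    k <- if (cls == "exon") as.integer(k_exon) else as.integer(k_utr)
    iv <- if (cls == "exon") model$exon_regions else model$utr_regions
    if (nrow(iv) == 0L) next
    for (i in seq_len(nrow(iv))) {
      L <- iv$end[i] - iv$start[i]
      if (L < k) next
      starts <- iv$start[i] + 0:(L - k)
      seq_iv <- genome_sequence(genome, model$chrom, iv$start[i], iv$end[i])
      seqs <- substring(seq_iv, 1L + starts - iv$start[i],
                        k + starts - iv$start[i])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = model$gene_id, region_class = cls, chrom = model$chrom,
        start = starts, k = k, sequence = seqs, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), region_class = character(0),
               chrom = character(0), start = integer(0), k = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  has_n <- grepl("N", res$sequence, fixed = TRUE)
  res <- res[!has_n, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- sum(has_n)
  res
}

.format_hits <- function(df, genome) {
  hits <- data.frame(
    chrom = chrom_names(genome)[df$chrom_idx],
    start = df$start,
    strand = ifelse(df$fwd == 1L, "+", "-"),
    mismatches = df$mismatches,
    stringsAsFactors = FALSE)
  hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
}

# batch interface used by the genome-wide computations: one index build,
# many queries. Returns hit table with a `query` column (1-based index into
# `sequences`).
.align_batch <- function(sequences, genome, max_mismatches) {
  stopifnot(max_mismatches >= 0L)
  df <- cpp_align_batch(sequences, unname(genome$seq),
                        as.integer(max_mismatches))
  df$chrom <- chrom_names(genome)[df$chrom_idx]
  df$strand <- ifelse(df$fwd == 1L, "+", "-")
  df[, c("query", "chrom", "start", "strand", "mismatches")]
}

#' Find all genomic placements of a k-mer
#'
#' Returns every placement (chromosome, leftmost 0-based coordinate, strand)
#' where the Hamming distance between the k-mer (forward strand) or its
#' reverse complement (minus strand) and the genome substring is at most
#' `max_mismatches`.  No indels.  Genome or query positions containing N
#' never match.  Internally uses a pigeonhole-seeded search: the k-mer is
#' split into `max_mismatches + 1` blocks, each block is anchored exactly via
#' a precomputed genome q-gram index, and candidates are verified by Hamming
#' count.
#'
#' @param kmer_sequence a single k-mer string.
#' @param genome a `genome_seq`.
#' @param max_mismatches maximum Hamming distance (default 2).
#' @return data frame with columns chrom, start, strand, mismatches, sorted
#'   by (chrom, start, strand).
#' @export
align_all <- function(kmer_sequence, genome, max_mismatches = 2L) {
  stopifnot(length(kmer_sequence) == 1L)
  if (nchar(kmer_sequence) == 0L) stop("empty k-mer")
  df <- cpp_align_batch(toupper(kmer_sequence), unname(genome$seq),
                        as.integer(max_mismatches))
  rownames(df) <- NULL
  .format_hits(df, genome)
}

#' Brute-force placement oracle
#'
#' Identical contract to [align_all()], implemented by scanning every offset
#' of every chromosome on both strands and counting mismatches naively.
#' Kept deliberately independent of the seeded search so the two can be
#' checked against each other; guarded to genomes of at most 1 Mb.
#'
#' @inheritParams align_all
#' @export
brute_force_oracle <- function(kmer_sequence, genome, max_mismatches = 2L) {
  stopifnot(length(kmer_sequence) == 1L)
  if (nchar(kmer_sequence) == 0L) stop("empty k-mer")
  if (sum(genome$lengths) > 1e6)
    stop("oracle guard: genome exceeds 1 Mb")
  kmer_sequence <- toupper(kmer_sequence)
  k <- nchar(kmer_sequence)
  code <- function(s) {
    v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    v[is.na(v)] <- 0L
    v
  }
  out <- list()
  for (chrom in chrom_names(genome)) {
    L <- genome_length(genome, chrom)
    if (L < k) next
    g <- code(genome$seq[[chrom]])
    n_off <- L - k + 1L
    for (strand in c("+", "-")) {
      s <- if (strand == "+") kmer_sequence else revcomp(kmer_sequence)
      q <- code(s)
      mm <- integer(n_off)
      for (j in seq_len(k)) {
        gj <- g[j:(n_off + j - 1L)]
        mm <- mm + as.integer(gj == 0L | q[j] == 0L | gj != q[j])
      }
      ok <- which(mm <= max_mismatches)
      if (length(ok))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = ok - 1L, strand = strand,
          mismatches = mm[ok], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Number of genomic placements of a k-mer
#'
#' `C_k`: the number of distinct (chrom, start, strand) placements of the
#' k-mer within the mismatch budget.  Any k-mer extracted from the genome
#' has `C_k >= 1` (it always maps back to its origin).
#'
#' @inheritParams align_all
#' @return integer count.
#' @export
count_placements <- function(kmer_sequence, genome, max_mismatches = 2L) {
  nrow(align_all(kmer_sequence, genome, max_mismatches))
}
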