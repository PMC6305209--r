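# Directed cross-mappability: crossmap(A, B) = number of Gene A's k-mers
# with at least one placement (within the mismatch budget) whose leftmost
# coordinate starts inside Gene B's exonic or UTR intervals.  A k-mer hitting
# B at several positions counts once toward B; a k-mer may count toward
# several target genes.

#' Construct a cross-mappability resource
#'
#' @param records data frame with columns gene_a, gene_b, count (integer
#'   `>= 1`; zero-count pairs are omitted by convention).
#' @return An object of class `crossmap_resource`.
#' @export
crossmap_resource <- function(records = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(gene_a = character(0), gene_b = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  } else {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_a", "gene_b", "count") %in% names(records)))
    if (any(records$count != as.integer(records$count)))
      stop("non-integer cross-mappability count")
    records$count <- as.integer(records$count)
    if (any(records$count <= 0L)) stop("cross-mappability count must be >= 1")
    if (any(records$gene_a == records$gene_b))
      stop("self-pairs are not allowed in a cross-mappability resource")
    records <- records[order(records$gene_a, records$gene_b),
                       c("gene_a", "gene_b", "count"), drop = FALSE]
    if (anyDuplicated(paste0(records$gene_a, "\r", records$gene_b)))
      stop("duplicate directed pair in resource")
    rownames(records) <- NULL
  }
  lookup <- records$count
  names(lookup) <- if (nrow(records)) paste0(records$gene_a, "\r",
                                             records$gene_b) else character(0)
  structure(list(records = records, lookup = lookup),
            class = "crossmap_resource")
}

#' @export
print.crossmap_resource <- function(x, ...) {
  cat("crossmap_resource with", nrow(x$records), "directed pair(s)\n")
  invisible(x)
}

#' Look up a directed cross-mappability count
#'
#' @param resource a `crossmap_resource`.
#' @param gene_a,gene_b gene ids (direction: A to B).
#' @return integer count; 0 for an absent pair.
#' @export
crossmap_count <- function(resource, gene_a, gene_b) {
  v <- unname(resource$lookup[paste0(gene_a, "\r", gene_b)])
  ifelse(is.na(v), 0L, v)
}

#' Is a gene pair cross-mappable?
#'
#' @param resource a `crossmap_resource`.
#' @param gene_a,gene_b gene ids.
#' @param direction `"a_to_b"` (crossmap(A,B) > 0) or `"either"`
#'   (crossmap(A,B) > 0 or crossmap(B,A) > 0).
#' @export
is_crossmappable <- function(resource, gene_a, gene_b,
                             direction = c("either", "a_to_b")) {
  direction <- match.arg(direction)
  ab <- crossmap_count(resource, gene_a, gene_b) > 0L
  if (direction == "a_to_b") return(ab)
  ab | (crossmap_count(resource, gene_b, gene_a) > 0L)
}

#' Compute the genome-wide directed cross-mappability resource
#'
#' Enumerates every k-mer of every gene, finds all genomic placements within
#' the mismatch budget, and counts, for every directed gene pair (A, B), the
#' number of A's k-mers with at least one placement starting inside B's
#' exonic or UTR intervals (leftmost hit coordinate, half-open containment of
#' the start position only).  With `use_shortcut = TRUE` (default) the
#' counting skips genes with mappability 1 and k-mers with mappability 1:
#' such k-mers only ever hit their own locus, so the shortcut is
#' output-equivalent to the full computation (a property the test suite
#' verifies).  Genes whose regions are all shorter than the applicable k
#' yield no k-mers and are excluded both as sources and as targets (their
#' cross-mappability is undetermined).
#'
#' @param models a `gene_model_list`.
#' @param genome a `genome_seq`.
#' @param k_exon,k_utr k-mer lengths (defaults 75 / 36).
#' @param max_mismatches Hamming tolerance (default 2).
#' @param use_shortcut skip mappability-1 genes and k-mers (default `TRUE`).
#' @return A `crossmap_resource`.
#' @export
compute_crossmap <- function(models, genome, k_exon = 75L, k_utr = 36L,
                             max_mismatches = 2L, use_shortcut = TRUE) {
  kh <- .kmer_hit_table(models, genome, k_exon, k_utr, max_mismatches)
  kmers <- kh$kmers
  hits <- kh$hits
  if (nrow(kmers) == 0L) return(crossmap_resource())

  mapp <- .mappability_from_kmers(models, kmers)
  determined <- mapp$gene_id[!is.na(mapp$gene_mappability)]

  keep_kmer <- rep(TRUE, nrow(kmers))
  if (use_shortcut) {
    ambiguous_genes <- mapp$gene_id[!is.na(mapp$gene_mappability) &
                                    mapp$gene_mappability < 1]
    keep_kmer <- kmers$C_k > 1L & kmers$gene_id %in% ambiguous_genes
  }
  hits <- hits[keep_kmer[hits$query], , drop = FALSE]
  if (nrow(hits) == 0L) return(crossmap_resource())

  # target membership: hit start position inside exon union UTR intervals of
  # a determined gene
  reg <- list()
  for (gid in determined) {
    m <- models[[gid]]
    iv <- rbind(m$exon_regions, m$utr_regions)
    if (nrow(iv) == 0L) next
    reg[[length(reg) + 1L]] <- data.frame(
      gene_id = gid, chrom = m$chrom, start = iv$start, end = iv$end,
      stringsAsFactors = FALSE)
  }
  if (length(reg) == 0L) return(crossmap_resource())
  reg <- do.call(rbind, reg)

  reg_gr <- GenomicRanges::GRanges(
    reg$chrom, IRanges::IRanges(start = reg$start + 1L, end = reg$end))
  hit_gr <- GenomicRanges::GRanges(
    hits$chrom, IRanges::IRanges(start = hits$start + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(hit_gr, reg_gr)

  src <- kmers$gene_id[hits$query[S4Vectors::queryHits(ov)]]
  tgt <- reg$gene_id[S4Vectors::subjectHits(ov)]
  qid <- hits$query[S4Vectors::queryHits(ov)]
  keep <- src != tgt
  if (!any(keep)) return(crossmap_resource())
  pairs <- unique(data.frame(query = qid[keep], gene_a = src[keep],
                             gene_b = tgt[keep], stringsAsFactors = FALSE))
  counts <- stats::aggregate(query ~ gene_a + gene_b, data = pairs,
                             FUN = length)
  names(counts)[names(counts) == "query"] <- "count"
  crossmap_resource(counts)
}

#' Write a cross-mappability resource as TSV
#'
#' Three tab-separated columns (gene_a, gene_b, count), one row per directed
#' pair with a positive count, sorted by (gene_a, gene_b).
#'
#' @param resource a `crossmap_resource`.
#' @param path output path.
#' @export
write_resource <- function(resource, path) {
  write.table(resource$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a cross-mappability resource from TSV
#'
#' @param path a file written by [write_resource()].
#' @return A `crossmap_resource`; rows with non-integer or non-positive
#'   counts are an error.
#' @export
read_resource <- function(path) {
  if (!file.exists(path)) stop("resource file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  if (!identical(names(df), c("gene_a", "gene_b", "count")))
    stop("malformed resource header: expected gene_a, gene_b, count")
  crossmap_resource(df)
}
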