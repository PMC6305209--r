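# Collapsed gene models: per gene, the union of exon intervals and the union
# of UTR intervals across all transcripts, with UTR bases subtracted from the
# exon class by default so every base belongs to exactly one region class.
# Intervals are 0-based half-open throughout.

.empty_intervals <- function() data.frame(start = integer(0), end = integer(0))

.as_intervals <- function(x) {
  if (is.null(x) || NROW(x) == 0L) return(.empty_intervals())
  x <- as.data.frame(x)
  if (!all(c("start", "end") %in% names(x)))
    stop("intervals need 'start' and 'end' columns")
  if (any(x$end <= x$start)) stop("empty or inverted interval")
  x[order(x$start), c("start", "end"), drop = FALSE]
}

.to_iranges <- function(iv) IRanges::IRanges(start = iv$start + 1L, end = iv$end)

.from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# union of possibly-overlapping intervals; abutting intervals are merged
merge_intervals <- function(iv) {
  iv <- .as_intervals(iv)
  if (nrow(iv) == 0L) return(iv)
  .from_iranges(IRanges::reduce(.to_iranges(iv)))
}

subtract_intervals <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  .from_iranges(IRanges::setdiff(.to_iranges(a), .to_iranges(b)))
}

interval_total_length <- function(iv) {
  iv <- .as_intervals(iv)
  sum(iv$end - iv$start)
}

#' Construct a collapsed gene model
#'
#' Collapses (merges) exon and UTR intervals, optionally subtracts UTR bases
#' from the exon class so the two classes are disjoint, and derives the gene
#' span and TSS (span start on `+`, span end - 1 on `-`).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,utrs data frames with 0-based half-open `start`/`end` columns
#'   (one row per interval, possibly overlapping across transcripts).
#' @param gene_type annotation class, e.g. `"protein_coding"` or
#'   `"pseudogene"`.
#' @param genome optional `genome_seq`; if given, intervals are checked
#'   against chromosome bounds.
#' @param utr_subtraction if `TRUE` (default), UTR intervals are removed from
#'   the exon class so each base belongs to exactly one class.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, utrs = NULL,
                       gene_type = "protein_coding", genome = NULL,
                       utr_subtraction = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exon_iv <- merge_intervals(exons)
  utr_iv <- merge_intervals(utrs)
  if (nrow(exon_iv) == 0L && nrow(utr_iv) == 0L)
    stop("gene ", gene_id, " has no exon or UTR intervals")
  if (utr_subtraction) exon_iv <- subtract_intervals(exon_iv, utr_iv)
  all_iv <- rbind(exon_iv, utr_iv)
  span <- c(min(all_iv$start), max(all_iv$end))
  if (!is.null(genome)) {
    L <- genome_length(genome, chrom)
    if (span[1] < 0L || span[2] > L)
      stop("gene ", gene_id, " extends outside chromosome ", chrom)
  }
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tss = if (strand == "+") span[1] else span[2] - 1L,
    exon_regions = exon_iv, utr_regions = utr_iv,
    gene_type = gene_type, span = span
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d (%s), %d exon / %d UTR interval(s)\n",
              x$gene_id, x$gene_type, x$chrom, x$span[1], x$span[2],
              x$strand, nrow(x$exon_regions), nrow(x$utr_regions)))
  invisible(x)
}

#' Build collapsed gene models from a GTF file
#'
#' Reads a Gencode-dialect GTF (feature types `gene`, `exon`, `UTR`;
#' attributes `gene_id` and `gene_type`), merges exon and UTR intervals
#' across all transcripts of each gene, and returns one collapsed
#' [gene_model()] per gene.  GTF coordinates (1-based inclusive) are
#' converted to the package's 0-based half-open convention on ingest.
#' Genes with no exon and no UTR feature are skipped with a warning.
#'
#' @param gtf_path path to a GTF file.
#' @param genome optional `genome_seq` used to bounds-check intervals.
#' @param utr_subtraction passed to [gene_model()].
#' @return A named list of `gene_model` objects (class `gene_model_list`),
#'   ordered by gene_id.
#' @export
build_gene_models <- function(gtf_path, genome = NULL, utr_subtraction = TRUE) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("exon", "UTR")
  if (!all(c("gene_id") %in% names(meta))) stop("GTF has no gene_id attribute")
  feat <- data.frame(
    type = as.character(meta$type[keep]),
    gene_id = as.character(meta$gene_id[keep]),
    gene_type = if ("gene_type" %in% names(meta))
      as.character(meta$gene_type[keep]) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)[keep]),
    start = GenomicRanges::start(gr)[keep] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr)[keep]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(feat$gene_id) | !nzchar(feat$gene_id)))
    stop("GTF feature without gene_id attribute")

  gene_rows <- which(meta$type == "gene")
  gene_types <- stats::setNames(
    if ("gene_type" %in% names(meta))
      as.character(meta$gene_type[gene_rows]) else
        rep(NA_character_, length(gene_rows)),
    as.character(meta$gene_id[gene_rows]))

  all_ids <- unique(c(as.character(meta$gene_id[gene_rows]), feat$gene_id))
  all_ids <- sort(all_ids[!is.na(all_ids)])
  models <- list()
  for (gid in all_ids) {
    rows <- feat[feat$gene_id == gid, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("gene ", gid, " has no exon or UTR features; skipped")
      next
    }
    if (length(unique(rows$chrom)) > 1L)
      stop("gene ", gid, " has features on multiple chromosomes")
    gtype <- unname(gene_types[gid])
    if (length(gtype) == 0L) gtype <- NA_character_
    if (is.na(gtype)) gtype <- rows$gene_type[1]
    if (is.na(gtype)) gtype <- "unknown"
    models[[gid]] <- gene_model(
      gene_id = gid, chrom = rows$chrom[1], strand = rows$strand[1],
      exons = rows[rows$type == "exon", c("start", "end")],
      utrs = rows[rows$type == "UTR", c("start", "end")],
      gene_type = gtype, genome = genome,
      utr_subtraction = utr_subtraction)
  }
  structure(models, class = "gene_model_list")
}

#' @export
print.gene_model_list <- function(x, ...) {
  cat("gene_model_list with", length(x), "gene(s)\n")
  invisible(x)
}

#' Genes with TSS near a genomic position
#'
#' Returns the ids of genes whose transcription start site lies within
#' `window_bp` of `pos` (inclusive, `|TSS - pos| <= window_bp`) on `chrom`.
#' This is the window used both for the cis-eQTL definition and for
#' identifying candidate cross-mapping genes around a trans-eQTL variant.
#'
#' @param models a `gene_model_list`.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @param window_bp non-negative window half-width in bp.
#' @return character vector of gene ids.
#' @export
genes_near_position <- function(models, chrom, pos, window_bp = 1e6) {
  stopifnot(window_bp >= 0)
  hits <- vapply(models, function(m) {
    m$chrom == chrom && abs(m$tss - pos) <= window_bp
  }, logical(1))
  names(models)[hits]
}

#' Do two gene spans overlap?
#'
#' `TRUE` iff both genes are on the same chromosome and their genomic spans
#' (half-open) intersect.  Used to exclude physically overlapping gene pairs
#' from co-expression rankings.
#'
#' @param model_a,model_b `gene_model` objects.
#' @export
spans_overlap <- function(model_a, model_b) {
  model_a$chrom == model_b$chrom &&
    model_a$span[1] < model_b$span[2] &&
    model_b$span[1] < model_a$span[2]
}
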