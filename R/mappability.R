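# Mappability scores: per k-mer (1 / C_k), per region class (mean over the
# class's k-mers), and per gene (length-weighted average of the exon and UTR
# components).  "Undetermined" components are represented as NA.

#' Mappability of a single k-mer
#'
#' Defined as `1 / C_k`, where `C_k` is the number of genomic placements of
#' the k-mer within the mismatch budget.  A value of 1 means the k-mer is
#' genome-unique.
#'
#' @param C_k integer placement count, `>= 1`.
#' @return real in (0, 1].
#' @export
kmer_mappability <- function(C_k) {
  if (any(C_k <= 0)) stop("C_k must be >= 1 (a genomic k-mer always self-maps)")
  1 / C_k
}

#' Mean mappability of a region class
#'
#' Arithmetic mean of the k-mer mappabilities drawn from one region class of
#' a gene.  When the gene yields no k-mer of that class (all its intervals
#' shorter than k), the component is undetermined and `NA` is returned.
#'
#' @param kmer_mappabilities numeric vector of per-k-mer mappabilities.
#' @return real in (0, 1], or `NA` when undetermined.
#' @export
region_mappability <- function(kmer_mappabilities) {
  if (length(kmer_mappabilities) == 0L) return(NA_real_)
  mean(kmer_mappabilities)
}

#' Gene mappability
#'
#' Length-weighted average of the exon and UTR component mappabilities,
#' weights proportional to the total collapsed length of each region class.
#' An undetermined component is excluded together with its weight; if both
#' components are undetermined the gene mappability is undetermined (`NA`).
#'
#' @param exon_map,utr_map component mappabilities (`NA` = undetermined).
#' @param exon_len,utr_len total collapsed region lengths in bp.
#' @return real in (0, 1], or `NA`.
#' @export
gene_mappability <- function(exon_map, utr_map, exon_len, utr_len) {
  stopifnot(exon_len >= 0, utr_len >= 0)
  if (is.na(exon_map) && is.na(utr_map)) return(NA_real_)
  if (exon_len == 0 && utr_len == 0)
    stop("defined mappability components with zero total region length")
  if (is.na(exon_map)) return(utr_map)
  if (is.na(utr_map)) return(exon_map)
  (exon_map * exon_len + utr_map * utr_len) / (exon_len + utr_len)
}

# Internal workhorse shared with the cross-mappability computation: enumerate
# every k-mer of every gene, align them all in one batch, and return the
# k-mer table (with C_k) plus all hits.
.kmer_hit_table <- function(models, genome, k_exon = 75L, k_utr = 36L,
                            max_mismatches = 2L) {
  kmers <- lapply(models, enumerate_kmers, genome = genome,
                  k_exon = k_exon, k_utr = k_utr)
  kmers <- do.call(rbind, c(kmers, list(make.row.names = FALSE)))
  if (is.null(kmers) || nrow(kmers) == 0L) {
    return(list(kmers = data.frame(), hits = data.frame()))
  }
  hits <- .align_batch(kmers$sequence, genome, max_mismatches)
  Ck <- tabulate(hits$query, nbins = nrow(kmers))
  kmers$C_k <- Ck
  kmers$mappability <- 1 / Ck
  list(kmers = kmers, hits = hits)
}

#' Per-gene mappability table
#'
#' Computes exon, UTR and gene mappability for every gene in `models` by
#' enumerating all k-mers and counting their genomic placements.
#'
#' @param models a `gene_model_list`.
#' @param genome a `genome_seq`.
#' @param k_exon,k_utr k-mer lengths (defaults 75 / 36).
#' @param max_mismatches Hamming tolerance for placements (default 2).
#' @return data frame with one row per gene (ordered by gene_id): gene_id,
#'   exon_mappability, utr_mappability, gene_mappability (`NA` =
#'   undetermined), exon_len, utr_len.
#' @export
compute_gene_mappability <- function(models, genome, k_exon = 75L,
                                     k_utr = 36L, max_mismatches = 2L) {
  kh <- .kmer_hit_table(models, genome, k_exon, k_utr, max_mismatches)
  .mappability_from_kmers(models, kh$kmers)
}

.mappability_from_kmers <- function(models, kmers) {
  ids <- sort(names(models))
  res <- data.frame(gene_id = ids,
                    exon_mappability = NA_real_, utr_mappability = NA_real_,
                    gene_mappability = NA_real_,
                    exon_len = NA_integer_, utr_len = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    m <- models[[ids[i]]]
    ke <- if (nrow(kmers)) kmers$mappability[kmers$gene_id == ids[i] &
                                             kmers$region_class == "exon"]
          else numeric(0)
    ku <- if (nrow(kmers)) kmers$mappability[kmers$gene_id == ids[i] &
                                             kmers$region_class == "utr"]
          else numeric(0)
    em <- region_mappability(ke)
    um <- region_mappability(ku)
    el <- interval_total_length(m$exon_regions)
    ul <- interval_total_length(m$utr_regions)
    res$exon_mappability[i] <- em
    res$utr_mappability[i] <- um
    res$gene_mappability[i] <- if (is.na(em) && is.na(um)) NA_real_ else
      gene_mappability(em, um, el, ul)
    res$exon_len[i] <- el
    res$utr_len[i] <- ul
  }
  res
}

#' Write a mappability table as TSV
#'
#' @param mappability data frame from [compute_gene_mappability()].
#' @param path output path; undetermined values are written as `NA`.
#' @export
write_mappability <- function(mappability, path) {
  write.table(mappability[order(mappability$gene_id), ], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
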