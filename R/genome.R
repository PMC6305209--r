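#' Genome sequence container
#'
#' A thin container around a named set of chromosome sequences, uppercased
#' and restricted to the alphabet `{A,C,G,T,N}`.  Coordinates throughout the
#' package are 0-based, half-open.
#'
#' @param sequences named character vector of chromosome sequences.
#' @return An object of class `genome_seq`.
#' @export
genome_from_sequences <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  if (any(nchar(sequences) < 1L)) stop("empty sequence record")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    n_amb <- sum(vapply(sequences[bad],
                        function(s) sum(strsplit(gsub("[ACGTN]", "", s),
                                                 "")[[1]] != ""),
                        integer(1)))
    message("mapped ", n_amb, " ambiguity-code base(s) to N")
    sequences <- vapply(sequences,
                        function(s) gsub("[^ACGTN]", "N", s),
                        character(1))
  }
  structure(list(seq = sequences, lengths = nchar(sequences)),
            class = "genome_seq")
}

#' Load a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a [genome_from_sequences()]
#' container.  Sequences are uppercased; IUPAC ambiguity codes other than N
#' are mapped to N with a message.  Record names are taken from the first
#' whitespace-delimited token of each header.
#'
#' @param fasta_path path to a FASTA file.
#' @return An object of class `genome_seq`.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  ss <- Biostrings::readBStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(ss) == 0L)) stop("empty FASTA record")
  seqs <- as.character(ss)
  names(seqs) <- nm
  genome_from_sequences(seqs)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x$seq), "chromosome(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Chromosome names of a genome
#' @param genome a `genome_seq` object.
#' @export
chrom_names <- function(genome) names(genome$seq)

#' Chromosome length
#' @param genome a `genome_seq` object.
#' @param chrom chromosome name.
#' @return length in bp.
#' @export
genome_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  unname(genome$lengths[chrom])
}

#' Extract genomic sequence
#'
#' @param genome a `genome_seq` object.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates; defaults to the whole
#'   chromosome.
#' @return character string.
#' @export
genome_sequence <- function(genome, chrom, start = 0L, end = NULL) {
  L <- genome_length(genome, chrom)
  if (is.null(end)) end <- L
  if (start < 0L || end > L || start >= end)
    stop("coordinates [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", L, ")")
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' Reverse complement
#'
#' @param s character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
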