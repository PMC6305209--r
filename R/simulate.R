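# Synthetic fixtures with planted ground truth.  Genomes are i.i.d. uniform
# ACGT sequence; genes are planted at fixed coordinates; sequence
# duplications between genes are planted at controlled Hamming distances and
# their expected cross-mappability counts are derived with the brute-force
# placement oracle, so every downstream computation can be checked exactly.
# Expression fixtures emulate the false-positive mechanism: a fraction of a
# source gene's signal (alpha) leaks into a sequence-similar target gene, and
# a cis-acting variant on the source then shows up as a spurious trans
# association with the target.

#' Describe a simple planted gene
#'
#' A single-transcript gene laid out as consecutive exons separated by
#' introns, with optional UTRs covering the first and last bases of the
#' gene (UTR features are inside exon features, as in a real GTF).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param start 0-based genomic start.
#' @param exon_lens vector of exon lengths (bp).
#' @param intron_len intron length between consecutive exons.
#' @param utr5_len,utr3_len UTR lengths at the gene ends (0 = none).
#' @param strand `"+"` or `"-"`.
#' @param gene_type annotation class.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(gene_id, chrom, start, exon_lens = 300L,
                      intron_len = 100L, utr5_len = 0L, utr3_len = 0L,
                      strand = "+", gene_type = "protein_coding") {
  stopifnot(utr5_len < exon_lens[1],
            utr3_len < exon_lens[length(exon_lens)])
  structure(list(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 exon_lens = as.integer(exon_lens),
                 intron_len = as.integer(intron_len),
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 strand = strand, gene_type = gene_type),
            class = "gene_spec")
}

#' Describe a planted duplication between two genes
#'
#' A `segment_length` bp stretch of the source gene's region (exon or UTR
#' class) is copied into the target gene's region of the same class, with
#' `hamming_distance` substitutions planted at `positions` (0-based offsets
#' within the segment; sampled uniformly if `NULL`).
#'
#' @param source_gene,target_gene gene ids.
#' @param segment_length copied length in bp.
#' @param hamming_distance number of substitutions planted in the copy.
#' @param positions optional distinct 0-based substitution offsets.
#' @param region `"exon"` or `"utr"`: which region class hosts the segment
#'   on both genes.
#' @param source_offset,target_offset 0-based offsets of the segment within
#'   the hosting collapsed interval.
#' @return a `duplication_spec` list.
#' @export
duplication_spec <- function(source_gene, target_gene, segment_length,
                             hamming_distance = 0L, positions = NULL,
                             region = c("exon", "utr"),
                             source_offset = 0L, target_offset = 0L) {
  region <- match.arg(region)
  if (!is.null(positions)) {
    stopifnot(length(positions) == hamming_distance,
              !anyDuplicated(positions),
              all(positions >= 0 & positions < segment_length))
  }
  structure(list(source_gene = source_gene, target_gene = target_gene,
                 segment_length = as.integer(segment_length),
                 hamming_distance = as.integer(hamming_distance),
                 positions = positions, region = region,
                 source_offset = as.integer(source_offset),
                 target_offset = as.integer(target_offset)),
            class = "duplication_spec")
}

.spec_intervals <- function(spec) {
  exons <- list(); pos <- spec$start
  for (len in spec$exon_lens) {
    exons[[length(exons) + 1L]] <- c(pos, pos + len)
    pos <- pos + len + spec$intron_len
  }
  exons <- do.call(rbind, exons)
  utrs <- NULL
  if (spec$utr5_len > 0L)
    utrs <- rbind(utrs, c(exons[1, 1], exons[1, 1] + spec$utr5_len))
  if (spec$utr3_len > 0L) {
    last <- exons[nrow(exons), ]
    utrs <- rbind(utrs, c(last[2] - spec$utr3_len, last[2]))
  }
  list(exons = data.frame(start = exons[, 1], end = exons[, 2]),
       utrs = if (is.null(utrs)) NULL else
         data.frame(start = utrs[, 1], end = utrs[, 2]))
}

.models_from_specs <- function(gene_specs, genome = NULL,
                               utr_subtraction = TRUE) {
  models <- list()
  for (spec in gene_specs) {
    iv <- .spec_intervals(spec)
    models[[spec$gene_id]] <- gene_model(
      spec$gene_id, spec$chrom, spec$strand, iv$exons, iv$utrs,
      gene_type = spec$gene_type, genome = genome,
      utr_subtraction = utr_subtraction)
  }
  structure(models, class = "gene_model_list")
}

# locate the genomic interval hosting a duplication segment on one gene
.segment_coords <- function(model, region, offset, seg_len) {
  iv <- if (region == "exon") model$exon_regions else model$utr_regions
  ok <- which(iv$end - iv$start >= offset + seg_len)
  if (!length(ok))
    stop("no ", region, " interval of gene ", model$gene_id,
         " can host a ", seg_len, " bp segment at offset ", offset)
  c(iv$start[ok[1]] + offset, iv$start[ok[1]] + offset + seg_len)
}

.substitute_bases <- function(seg, positions) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seg, "")[[1]]
  for (p in positions) {
    cur <- match(chars[p + 1L], bases)
    chars[p + 1L] <- bases[(cur %% 4L) + 1L]  # deterministic: next base
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted duplications and oracle truth
#'
#' Draws i.i.d. uniform ACGT chromosomes, plants the specified genes and
#' inter-gene duplications, and derives a ground-truth table of expected
#' directed cross-mappability counts for every mismatch budget up to
#' `truth_max_mismatches` using the brute-force placement oracle.  At the
#' default k (75/36) an accidental, non-planted duplication in i.i.d.
#' sequence is vanishingly improbable, so truth counting is restricted to
#' k-mers overlapping planted segments.  Deterministic under `seed`.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param gene_specs list of [gene_spec()] objects.
#' @param duplication_specs list of [duplication_spec()] objects.
#' @param seed integer seed.
#' @param outdir optional directory; when given, `genome.fa` and
#'   `annotation.gtf` are written there (byte-deterministic under the seed).
#' @param k_exon,k_utr k-mer lengths used for the truth table.
#' @param truth_max_mismatches largest mismatch budget tabulated (default 3).
#' @return list with `genome` (`genome_seq`), `models` (`gene_model_list`),
#'   `truth` (data frame gene_a, gene_b, max_mismatches, count),
#'   `duplications` (specs with resolved coordinates and substitution
#'   positions), and file paths when `outdir` was given.
#' @export
generate_genome <- function(chrom_lengths, gene_specs,
                            duplication_specs = list(), seed,
                            outdir = NULL, k_exon = 75L, k_utr = 36L,
                            truth_max_mismatches = 3L) {
  stopifnot(!is.null(names(chrom_lengths)))
  withr::with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    genome <- genome_from_sequences(seqs)
    models <- .models_from_specs(gene_specs, genome = genome)

    # resolve and plant duplications
    planted <- list()  # genomic windows already written to, per chrom
    resolved <- list()
    for (dup in duplication_specs) {
      src <- models[[dup$source_gene]]; tgt <- models[[dup$target_gene]]
      if (is.null(src) || is.null(tgt)) stop("duplication names unknown gene")
      sc <- .segment_coords(src, dup$region, dup$source_offset,
                            dup$segment_length)
      tc <- .segment_coords(tgt, dup$region, dup$target_offset,
                            dup$segment_length)
      for (w in list(c(src$chrom, sc), c(tgt$chrom, tc))) {
        key <- w[1]
        win <- as.integer(w[2:3])
        for (p in planted[[key]] %||% list())
          if (win[1] < p[2] && p[1] < win[2])
            stop("overlapping planted segments on ", key)
        planted[[key]] <- c(planted[[key]] %||% list(), list(win))
      }
      seg <- genome_sequence(genome, src$chrom, sc[1], sc[2])
      positions <- dup$positions
      if (is.null(positions) && dup$hamming_distance > 0L)
        positions <- sort(sample.int(dup$segment_length,
                                     dup$hamming_distance) - 1L)
      if (dup$hamming_distance > 0L)
        seg <- .substitute_bases(seg, positions)
      s <- genome$seq[[tgt$chrom]]
      substr(s, tc[1] + 1L, tc[2]) <- seg
      genome$seq[[tgt$chrom]] <- s
      # force the bases flanking the copy to differ from the corresponding
      # source flanks, so that k-mers overhanging the segment by even one
      # base can never extend a chance match: planted counts then follow
      # the within-segment closed form exactly
      genome <- .force_flank_mismatch(genome, src$chrom, sc, tgt$chrom, tc)
      dup$positions <- positions
      dup$source_coords <- sc
      dup$target_coords <- tc
      resolved[[length(resolved) + 1L]] <- dup
    }
    genome <- genome_from_sequences(genome$seq)  # refresh lengths

    truth <- .oracle_truth(models, genome, resolved, k_exon, k_utr,
                           truth_max_mismatches)

    out <- list(genome = genome, models = models, truth = truth,
                duplications = resolved)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      out$fasta_path <- file.path(outdir, "genome.fa")
      out$gtf_path <- file.path(outdir, "annotation.gtf")
      write_genome_fasta(genome, out$fasta_path)
      write_models_gtf(gene_specs, out$gtf_path)
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.force_flank_mismatch <- function(genome, src_chrom, sc, tgt_chrom, tc) {
  bases <- c("A", "C", "G", "T")
  fix_one <- function(spos, tpos) {
    if (spos < 0L || tpos < 0L) return()
    if (spos >= genome$lengths[[src_chrom]] ||
        tpos >= genome$lengths[[tgt_chrom]]) return()
    sb <- substr(genome$seq[[src_chrom]], spos + 1L, spos + 1L)
    tb <- substr(genome$seq[[tgt_chrom]], tpos + 1L, tpos + 1L)
    if (sb == tb) {
      t <- genome$seq[[tgt_chrom]]
      substr(t, tpos + 1L, tpos + 1L) <- bases[(match(sb, bases) %% 4L) + 1L]
      genome$seq[[tgt_chrom]] <<- t
    }
  }
  fix_one(sc[1] - 1L, tc[1] - 1L)
  fix_one(sc[2], tc[2])
  genome
}

# oracle-derived truth: for every k-mer overlapping a planted segment, find
# all placements with the naive scanner and count, per (source, target,
# mismatch budget), the distinct k-mers with >= 1 hit starting in the
# target's regions.
.oracle_truth <- function(models, genome, duplications, k_exon, k_utr,
                          max_mm) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      max_mismatches = integer(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(duplications)) return(empty)
  windows <- lapply(duplications, function(d) {
    src <- models[[d$source_gene]]; tgt <- models[[d$target_gene]]
    list(c(src$chrom, d$source_coords), c(tgt$chrom, d$target_coords))
  })
  windows <- do.call(c, windows)

  # determined genes and their region tables, for hit membership
  kmer_tabs <- lapply(models, enumerate_kmers, genome = genome,
                      k_exon = k_exon, k_utr = k_utr)
  determined <- names(models)[vapply(kmer_tabs, nrow, integer(1)) > 0L]
  regions <- lapply(models[determined], function(m)
    rbind(m$exon_regions, m$utr_regions))

  rows <- list()
  for (gid in names(models)) {
    km <- kmer_tabs[[gid]]
    if (nrow(km) == 0L) next
    ov <- rep(FALSE, nrow(km))
    for (w in windows) {
      if (w[1] != km$chrom[1]) next
      ws <- as.integer(w[2]); we <- as.integer(w[3])
      ov <- ov | (km$start < we & ws < km$start + km$k)
    }
    km <- km[ov, , drop = FALSE]
    if (nrow(km) == 0L) next
    for (i in seq_len(nrow(km))) {
      hits <- brute_force_oracle(km$sequence[i], genome, max_mm)
      if (nrow(hits) == 0L) next
      for (tid in determined) {
        if (tid == gid) next
        m <- models[[tid]]
        sel <- hits$chrom == m$chrom
        if (!any(sel)) next
        h <- hits[sel, , drop = FALSE]
        iv <- regions[[tid]]
        inside <- vapply(h$start, function(p)
          any(iv$start <= p & p < iv$end), logical(1))
        if (!any(inside)) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = gid, gene_b = tid,
          best_mm = min(h$mismatches[inside]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  best <- do.call(rbind, rows)
  out <- list()
  for (m in 0:max_mm) {
    sub <- best[best$best_mm <= m, , drop = FALSE]
    if (nrow(sub) == 0L) next
    cnt <- stats::aggregate(best_mm ~ gene_a + gene_b, data = sub,
                            FUN = length)
    names(cnt)[3] <- "count"
    cnt$max_mismatches <- m
    out[[length(out) + 1L]] <- cnt[, c("gene_a", "gene_b",
                                       "max_mismatches", "count")]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$max_mismatches, res$gene_a, res$gene_b), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-mappability resource implied by a truth table
#'
#' @param truth truth data frame from [generate_genome()].
#' @param max_mismatches mismatch budget to extract.
#' @return a `crossmap_resource` with the oracle-expected counts.
#' @export
truth_resource <- function(truth, max_mismatches = 2L) {
  sub <- truth[truth$max_mismatches == max_mismatches, , drop = FALSE]
  crossmap_resource(sub[, c("gene_a", "gene_b", "count")])
}

#' Write a genome as FASTA
#'
#' @param genome a `genome_seq`.
#' @param path output path (records wrapped at 60 columns).
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write gene specs as a Gencode-dialect GTF
#'
#' Emits gene, exon and UTR features with `gene_id` and `gene_type`
#' attributes, 1-based inclusive coordinates.
#'
#' @param gene_specs list of [gene_spec()] objects.
#' @param path output path.
#' @export
write_models_gtf <- function(gene_specs, path) {
  lines <- character(0)
  fmt <- function(chrom, feature, start0, end0, strand, gid, gtype) {
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_type \"%s\";",
            chrom, feature, start0 + 1L, end0, strand, gid, gtype)
  }
  for (spec in gene_specs) {
    iv <- .spec_intervals(spec)
    span <- c(min(iv$exons$start), max(iv$exons$end))
    lines <- c(lines, fmt(spec$chrom, "gene", span[1], span[2],
                          spec$strand, spec$gene_id, spec$gene_type))
    for (i in seq_len(nrow(iv$exons)))
      lines <- c(lines, fmt(spec$chrom, "exon", iv$exons$start[i],
                            iv$exons$end[i], spec$strand, spec$gene_id,
                            spec$gene_type))
    if (!is.null(iv$utrs))
      for (i in seq_len(nrow(iv$utrs)))
        lines <- c(lines, fmt(spec$chrom, "UTR", iv$utrs$start[i],
                              iv$utrs$end[i], spec$strand, spec$gene_id,
                              spec$gene_type))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate expression with planted contamination
#'
#' Every gene receives independent standard-normal expression across
#' samples; each contamination target is then replaced by
#' `alpha * source + Normal(0, noise_sd)`, emulating reads from the source
#' gene misaligned to the sequence-similar target.  Under this generative
#' model the population correlation between source and target is
#' `alpha / sqrt(alpha^2 + noise_sd^2)`.
#'
#' @param gene_ids character vector of genes to simulate.
#' @param contamination data frame with columns source, target, alpha
#'   (`alpha` in `[0, 1)`); a gene may not be both a source and a target.
#' @param n_samples number of samples.
#' @param noise_sd standard deviation of the target's own noise (default 1).
#' @param seed integer seed.
#' @return genes-by-samples matrix with rownames `gene_ids`.
#' @export
simulate_expression <- function(gene_ids, contamination = NULL, n_samples,
                                noise_sd = 1, seed) {
  if (!is.null(contamination) && nrow(contamination)) {
    stopifnot(all(contamination$alpha >= 0), all(contamination$alpha < 1),
              all(contamination$source %in% gene_ids),
              all(contamination$target %in% gene_ids))
    if (any(contamination$target %in% contamination$source))
      stop("a gene may not be both a contamination source and target")
    if (anyDuplicated(contamination$target))
      stop("a target may receive contamination from only one source")
  }
  withr::with_seed(seed, {
    E <- matrix(rnorm(length(gene_ids) * n_samples),
                nrow = length(gene_ids),
                dimnames = list(gene_ids, paste0("s", seq_len(n_samples))))
    if (!is.null(contamination) && nrow(contamination)) {
      for (i in seq_len(nrow(contamination))) {
        src <- contamination$source[i]; tgt <- contamination$target[i]
        E[tgt, ] <- contamination$alpha[i] * E[src, ] +
          rnorm(n_samples, sd = noise_sd)
      }
    }
    E
  })
}

#' Add cis-acting variants on contamination source genes
#'
#' For every contamination source gene, places a biallelic variant within
#' the cis window of the gene's TSS, draws Binomial(2, maf) dosages, and
#' adds `beta_cis * dosage` to the source gene's expression.  Each
#' contaminated target inherits the genetic signal only through its
#' contamination fraction (`alpha * beta_cis * dosage`), which is what makes
#' the variant a spurious trans-eQTL of the target.  Optionally adds
#' effect-free null variants for calibration experiments.
#'
#' @param expression genes-by-samples matrix from [simulate_expression()].
#' @param gene_info a `gene_model_list` or data frame (gene_id, chrom, tss).
#' @param contamination contamination table (source, target, alpha).
#' @param maf minor allele frequency in (0, 0.5].
#' @param beta_cis cis effect size per dosage unit.
#' @param seed integer seed.
#' @param cis_offset_bp variant placement offset from the source TSS.
#' @param n_null_variants number of additional variants with no effect.
#' @param null_chrom chromosome hosting the null variants (defaults to the
#'   first source gene's chromosome).
#' @return list with `variants` (variant_id, chrom, pos, maf), `genotypes`
#'   (variants-by-samples dosage matrix) and the updated `expression`.
#' @export
simulate_genotypes_and_cis <- function(expression, gene_info, contamination,
                                       maf = 0.3, beta_cis = 1, seed,
                                       cis_offset_bp = 1e4,
                                       n_null_variants = 0L,
                                       null_chrom = NULL) {
  stopifnot(maf > 0, maf <= 0.5)
  info <- .gene_info(gene_info)
  n <- ncol(expression)
  sources <- unique(contamination$source)
  withr::with_seed(seed, {
    draw_geno <- function() {
      repeat {
        g <- rbinom(n, 2, maf)
        if (stats::var(g) > 0) return(g)
      }
    }
    vids <- character(0); vchrom <- character(0); vpos <- integer(0)
    G <- NULL
    for (src in sources) {
      row <- info[info$gene_id == src, ]
      if (nrow(row) == 0L) stop("source gene ", src, " absent from gene_info")
      g <- draw_geno()
      expression[src, ] <- expression[src, ] + beta_cis * g
      for (i in which(contamination$source == src)) {
        tgt <- contamination$target[i]
        expression[tgt, ] <- expression[tgt, ] +
          contamination$alpha[i] * beta_cis * g
      }
      vids <- c(vids, paste0("v_", src))
      vchrom <- c(vchrom, row$chrom)
      vpos <- c(vpos, as.integer(row$tss + cis_offset_bp))
      G <- rbind(G, g)
    }
    if (n_null_variants > 0L) {
      nc <- null_chrom %||% info$chrom[info$gene_id == sources[1]]
      for (j in seq_len(n_null_variants)) {
        g <- draw_geno()
        vids <- c(vids, sprintf("null_%03d", j))
        vchrom <- c(vchrom, nc)
        vpos <- c(vpos, as.integer(j * 1000L))
        G <- rbind(G, g)
      }
    }
    rownames(G) <- vids
    colnames(G) <- colnames(expression)
    list(variants = data.frame(variant_id = vids, chrom = vchrom,
                               pos = vpos, maf = maf,
                               stringsAsFactors = FALSE),
         genotypes = G, expression = expression)
  })
}
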