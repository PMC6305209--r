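# Variant-gene association screening: MAF / repeat filtering, cis/trans
# classification, OLS association tests, BH FDR, cross-mappability flagging
# and FDR reassessment after filtering flagged tests.

.gene_info <- function(models) {
  if (is.data.frame(models)) {
    stopifnot(all(c("gene_id", "chrom", "tss") %in% names(models)))
    return(models)
  }
  data.frame(
    gene_id = names(models),
    chrom = vapply(models, function(m) m$chrom, character(1)),
    tss = vapply(models, function(m) m$tss, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter variants by MAF and repeat regions
#'
#' Keeps variants with `maf >= maf_min` (inclusive) whose position does not
#' fall inside any repeat interval.
#'
#' @param variants data frame with columns variant_id, chrom, pos (0-based),
#'   maf.
#' @param repeat_intervals optional data frame of 0-based half-open repeat
#'   intervals (columns chrom, start, end), e.g. read from a BED file.
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @return the filtered variant data frame.
#' @export
filter_variants <- function(variants, repeat_intervals = NULL,
                            maf_min = 0.05) {
  keep <- variants$maf >= maf_min
  if (!is.null(repeat_intervals) && nrow(repeat_intervals) > 0L) {
    in_repeat <- vapply(seq_len(nrow(variants)), function(i) {
      ri <- repeat_intervals[repeat_intervals$chrom == variants$chrom[i], ,
                             drop = FALSE]
      any(ri$start <= variants$pos[i] & variants$pos[i] < ri$end)
    }, logical(1))
    keep <- keep & !in_repeat
  }
  variants[keep, , drop = FALSE]
}

#' Read repeat regions from a BED file
#'
#' @param path BED file (0-based half-open, as standard).
#' @return data frame with columns chrom, start, end.
#' @export
read_repeat_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Classify a variant-gene pair as cis, trans or other
#'
#' cis: same chromosome and `|pos - TSS| <= cis_window` (inclusive);
#' trans: different chromosomes; other: same chromosome beyond the window.
#'
#' @param variant list or one-row data frame with `chrom` and `pos`.
#' @param gene_model a `gene_model` (or anything with `chrom` and `tss`).
#' @param cis_window window half-width in bp (default 1e6).
#' @return one of `"cis"`, `"trans"`, `"other"`.
#' @export
classify_pair <- function(variant, gene_model, cis_window = 1e6) {
  if (variant$chrom != gene_model$chrom) return("trans")
  if (abs(variant$pos - gene_model$tss) <= cis_window) return("cis")
  "other"
}

# residualize rows of M (features x samples) against covariates
# (covariates x samples) plus an intercept
.resid_rows <- function(M, covariates = NULL) {
  n <- ncol(M)
  X <- cbind(rep(1, n), if (is.null(covariates)) NULL else t(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate matrix")
  Q <- qr.Q(qx)
  M - (M %*% Q) %*% t(Q)
}

#' Linear association test between a genotype and an expression vector
#'
#' Ordinary least squares of expression on genotype dosage plus covariates
#' and an intercept, with a two-sided t-test on the genotype coefficient.
#' Computed through the Frisch-Waugh-Lovell closed form: both vectors are
#' residualized against the covariates (plus intercept) and the genotype
#' effect is estimated from the residual regression with
#' `df = n - n_covariates - 2`.
#'
#' @param genotype numeric dosage vector (one value per sample).
#' @param expression_row numeric expression vector.
#' @param covariates optional covariates-by-samples matrix.
#' @return list with `beta`, `statistic` (t-value) and `p`.
#' @export
linear_association <- function(genotype, expression_row, covariates = NULL) {
  n <- length(genotype)
  stopifnot(length(expression_row) == n)
  q <- 1L + if (is.null(covariates)) 0L else nrow(covariates)
  if (n < q + 2L) stop("too few samples for the model")
  if (stats::var(genotype) == 0) stop("zero-variance genotype")
  rg <- .resid_rows(matrix(genotype, nrow = 1), covariates)[1, ]
  ry <- .resid_rows(matrix(expression_row, nrow = 1), covariates)[1, ]
  df <- n - q - 1L
  beta <- sum(rg * ry) / sum(rg^2)
  rss <- sum((ry - beta * rg)^2)
  se <- sqrt(rss / df / sum(rg^2))
  t <- beta / se
  list(beta = beta, statistic = t, p = 2 * stats::pt(-abs(t), df = df))
}

#' Genome-wide trans-eQTL scan
#'
#' Tests every inter-chromosomal variant-gene pair with the OLS model of
#' [linear_association()], vectorized across pairs: genotypes and expression
#' are residualized against the covariates once, pairwise correlations of
#' the residuals give the t statistics.  Zero-variance genotypes are skipped
#' with a message.
#'
#' @param genotypes variants-by-samples dosage matrix (rownames variant ids).
#' @param variant_meta data frame with variant_id, chrom, pos.
#' @param expression genes-by-samples matrix (rownames gene ids).
#' @param models a `gene_model_list` or data frame with gene_id, chrom, tss.
#' @param covariates optional covariates-by-samples matrix.
#' @param cis_window cis window half-width (default 1e6).
#' @param classes which pair classes to report (default `"trans"` only).
#' @return data frame of association records: variant_id, gene_id, chrom,
#'   pos, beta, statistic, p, fdr (BH within the returned set), eqtl_class,
#'   crossmappable (`NA` until flagged).
#' @export
trans_eqtl_scan <- function(genotypes, variant_meta, expression, models,
                            covariates = NULL, cis_window = 1e6,
                            classes = "trans") {
  info <- .gene_info(models)
  stopifnot(identical(rownames(genotypes), variant_meta$variant_id))
  genes <- rownames(expression)
  info <- info[match(genes, info$gene_id), , drop = FALSE]
  if (any(is.na(info$gene_id))) stop("expression gene absent from models")

  gvar <- apply(genotypes, 1, stats::var)
  if (any(gvar == 0)) {
    message("skipping ", sum(gvar == 0), " zero-variance genotype(s)")
    genotypes <- genotypes[gvar > 0, , drop = FALSE]
    variant_meta <- variant_meta[gvar > 0, , drop = FALSE]
  }
  n <- ncol(expression)
  q <- 1L + if (is.null(covariates)) 0L else nrow(covariates)
  df <- n - q - 1L
  rg <- .resid_rows(genotypes, covariates)
  re <- .resid_rows(expression, covariates)
  sg <- sqrt(rowSums(rg^2))
  se <- sqrt(rowSums(re^2))
  r <- (rg %*% t(re)) / (sg %*% t(se))  # variants x genes
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  beta <- r * (matrix(1 / sg, nrow(r), ncol(r)) *
               matrix(se, nrow(r), ncol(r), byrow = TRUE))
  p <- 2 * stats::pt(-abs(tstat), df = df)

  # classify all pairs
  vchrom <- variant_meta$chrom
  vpos <- variant_meta$pos
  cls <- matrix("other", nrow(r), ncol(r))
  diffc <- outer(vchrom, info$chrom, "!=")
  cls[diffc] <- "trans"
  near <- abs(outer(vpos, info$tss, "-")) <= cis_window & !diffc
  cls[near] <- "cis"

  keep <- which(matrix(cls %in% classes, nrow(r)), arr.ind = TRUE)
  out <- data.frame(
    variant_id = variant_meta$variant_id[keep[, 1]],
    gene_id = genes[keep[, 2]],
    chrom = vchrom[keep[, 1]],
    pos = vpos[keep[, 1]],
    beta = beta[keep], statistic = tstat[keep], p = p[keep],
    eqtl_class = cls[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$variant_id, out$gene_id), , drop = FALSE]
  out$fdr <- bh_fdr(out$p)
  out$crossmappable <- NA
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard BH step-up adjustment, `min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) &&
      (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Flag cross-mappable trans-eQTLs
#'
#' A trans association is flagged as cross-mappable when some gene with TSS
#' within `window_bp` of the variant cross-maps to the trans target gene
#' (in the requested direction).
#'
#' @param associations association records (see [trans_eqtl_scan()]) carrying
#'   variant chrom/pos columns.
#' @param models a `gene_model_list`.
#' @param resource a `crossmap_resource`.
#' @param window_bp window around the variant (default 1e6).
#' @param direction `"either"` (default, conservative) or `"a_to_b"`
#'   (candidate gene to target only).
#' @return `associations` with the `crossmappable` column set.
#' @export
flag_trans_eqtls <- function(associations, models, resource,
                             window_bp = 1e6,
                             direction = c("either", "a_to_b")) {
  direction <- match.arg(direction)
  if (!all(associations$gene_id %in% names(models)))
    stop("target gene absent from models")
  key <- paste0(associations$chrom, ":", associations$pos)
  flags <- logical(nrow(associations))
  for (k in unique(key)) {
    idx <- which(key == k)
    nearby <- genes_near_position(models, associations$chrom[idx[1]],
                                  associations$pos[idx[1]], window_bp)
    for (i in idx) {
      tgt <- associations$gene_id[i]
      cand <- setdiff(nearby, tgt)
      flags[i] <- length(cand) > 0L &&
        any(vapply(cand, function(g)
          is_crossmappable(resource, g, tgt, direction), logical(1)))
    }
  }
  associations$crossmappable <- flags
  associations
}

#' Reassess the significant set after filtering flagged tests
#'
#' Computes the BH-significant set over all tests and, separately, the
#' BH-significant set over the unflagged tests only (FDR recomputed on the
#' reduced test set, as required after removing suspect hits).
#'
#' @param associations association records with raw `p` and `crossmappable`.
#' @param alpha FDR threshold (default 0.05).
#' @return list with `original_significant` and `filtered_significant`
#'   (data frames), plus unique target-gene counts `n_genes_original` and
#'   `n_genes_filtered`.
#' @export
refilter_and_reassess <- function(associations, alpha = 0.05) {
  a <- associations
  a$fdr <- bh_fdr(a$p)
  orig <- a[a$fdr <= alpha, , drop = FALSE]
  unflagged <- associations[!associations$crossmappable, , drop = FALSE]
  unflagged$fdr <- bh_fdr(unflagged$p)
  filt <- unflagged[unflagged$fdr <= alpha, , drop = FALSE]
  list(original_significant = orig,
       filtered_significant = filt,
       n_genes_original = length(unique(orig$gene_id)),
       n_genes_filtered = length(unique(filt$gene_id)))
}

#' Fraction of cross-mappable hits among the top-ranked associations
#'
#' Orders tests by increasing p (ties broken by variant then gene id) and
#' reports, for every rank r, the fraction of the top r that are flagged
#' cross-mappable, together with the background flagged fraction over all
#' tested pairs.
#'
#' @param associations association records with `p` and `crossmappable`.
#' @return list with `curve` (data frame rank, fraction) and `background`.
#' @export
top_hit_crossmap_fraction <- function(associations) {
  o <- order(associations$p, associations$variant_id, associations$gene_id)
  fl <- associations$crossmappable[o]
  list(curve = data.frame(rank = seq_along(fl),
                          fraction = cumsum(fl) / seq_along(fl)),
       background = mean(associations$crossmappable))
}

#' Replication fraction by cross-mappability class
#'
#' For the best variant per discovery target gene (lowest discovery p, ties
#' broken by lexicographic variant id), computes the share of pairs whose
#' replication BH-FDR is `<= alpha`, separately for flagged and unflagged
#' pairs.  Pairs without a replication value are excluded with a message.
#'
#' @param discovery data frame with variant_id, gene_id, p, crossmappable.
#' @param replication_pvalues data frame with variant_id, gene_id, p.
#' @param alpha replication FDR threshold (default 0.05).
#' @return data frame with one row per class: crossmappable, n,
#'   n_replicated, fraction (`NA` for an empty class).
#' @export
replication_fraction <- function(discovery, replication_pvalues,
                                 alpha = 0.05) {
  d <- discovery[order(discovery$p, discovery$variant_id), , drop = FALSE]
  best <- d[!duplicated(d$gene_id), , drop = FALSE]
  key_b <- paste0(best$variant_id, "\r", best$gene_id)
  key_r <- paste0(replication_pvalues$variant_id, "\r",
                  replication_pvalues$gene_id)
  idx <- match(key_b, key_r)
  if (any(is.na(idx))) {
    message("excluding ", sum(is.na(idx)),
            " pair(s) without a replication value")
    best <- best[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  rep_p <- replication_pvalues$p[idx]
  rep_fdr <- bh_fdr(rep_p)
  out <- lapply(c(FALSE, TRUE), function(fl) {
    sel <- best$crossmappable == fl
    n <- sum(sel)
    nr <- sum(rep_fdr[sel] <= alpha)
    data.frame(crossmappable = fl, n = n, n_replicated = nr,
               fraction = if (n > 0) nr / n else NA_real_)
  })
  do.call(rbind, out)
}
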