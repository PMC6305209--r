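# Co-expression screening: covariate residualization, absolute Pearson
# correlation of gene pairs, cross-mappability-weighted pair sampling, and
# the one-sided rank-sum comparison between cross-mappable and
# non-cross-mappable pairs.

#' Residualize expression against covariates
#'
#' Per gene, residuals of the OLS regression of expression on the covariates
#' plus an intercept.  With no covariates this centers each gene.  Residuals
#' are orthogonal to the covariates up to numerical precision.
#'
#' @param expression genes-by-samples matrix.
#' @param covariates optional covariates-by-samples matrix (full row rank).
#' @return residualized genes-by-samples matrix.
#' @export
residualize <- function(expression, covariates = NULL) {
  .resid_rows(as.matrix(expression), covariates)
}

#' Absolute Pearson correlation
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return `|r|` in `[0, 1]`.
#' @export
abs_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input")
  abs(stats::cor(x, y))
}

#' Absolute Pearson correlation for a table of gene pairs
#'
#' @param expression (residualized) genes-by-samples matrix.
#' @param pairs data frame with gene_a, gene_b columns.
#' @return `pairs` with an `abs_r` column appended.
#' @export
pair_abs_correlation <- function(expression, pairs) {
  a <- expression[pairs$gene_a, , drop = FALSE]
  b <- expression[pairs$gene_b, , drop = FALSE]
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  r <- rowSums(ca * cb) / sqrt(rowSums(ca^2) * rowSums(cb^2))
  pairs$abs_r <- abs(unname(r))
  pairs
}

#' Sample gene pairs, optionally proportionally to cross-mappability
#'
#' Draws `n` distinct pairs without replacement.  In weighted mode each
#' successive draw is made with probability proportional to the remaining
#' pairs' weights (so the sample covers the whole cross-mappability range
#' rather than just the mass of low-weight pairs).  Reproducible under a
#' fixed seed.
#'
#' @param pairs data frame of candidate pairs.
#' @param weights non-negative sampling weights (one per pair); ignored in
#'   uniform mode.
#' @param n number of pairs to draw (`<= nrow(pairs)`).
#' @param seed integer seed.
#' @param mode `"weight_proportional"` or `"uniform"`.
#' @return the sampled rows of `pairs`.
#' @export
sample_pairs <- function(pairs, weights = NULL, n, seed,
                         mode = c("weight_proportional", "uniform")) {
  mode <- match.arg(mode)
  if (n > nrow(pairs)) stop("n exceeds the number of available pairs")
  if (mode == "weight_proportional") {
    stopifnot(!is.null(weights), length(weights) == nrow(pairs),
              all(weights >= 0), any(weights > 0))
  }
  idx <- withr::with_seed(seed, {
    if (mode == "uniform") sample.int(nrow(pairs), n)
    else sample.int(nrow(pairs), n, prob = weights)
  })
  pairs[idx, , drop = FALSE]
}

#' One-sided Wilcoxon rank-sum test (greater)
#'
#' p-value for the alternative that values in `sample_a` are stochastically
#' greater than values in `sample_b`.  Exact enumeration when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return p-value.
#' @export
rank_sum_greater <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0L, length(sample_b) > 0L)
  combined <- c(sample_a, sample_b)
  exact <- length(combined) <= 20L && !anyDuplicated(combined)
  suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "greater",
                       exact = exact, correct = !exact)$p.value)
}

#' Group gene pairs by cross-mappability quantile
#'
#' Partitions pairs into a zero group (cross-mappability 0), a set of
#' fixed-size upper groups taken from the top of the cross-mappability
#' distribution (sizes given from the top downward), and equally-sized
#' quantile groups for the remaining positive-weight pairs.  With the
#' default spec this reproduces a 22-group layout: group "0", 12 quantile
#' groups, and 9 upper groups of sizes 50,000 / 25,000 / 10,000 / 5,000 /
#' 2,000 x 5 (top).
#'
#' @param weights non-negative cross-mappability per pair.
#' @param upper_counts target sizes of the upper groups, largest
#'   cross-mappability first (default `c(2000, 2000, 2000, 2000, 2000,
#'   5000, 10000, 25000, 50000)`).
#' @param n_quantile_groups number of equal quantile groups for the
#'   remaining positive-weight pairs (default 12).
#' @return data frame with pair index, group label (ordered factor, "0"
#'   lowest), and weight; attribute `groups` summarizes sizes and weight
#'   bounds.  If there are fewer positive pairs than the upper spec
#'   requires, groups are truncated with a warning.
#' @export
quantile_group_pairs <- function(weights,
                                 upper_counts = c(2000, 2000, 2000, 2000,
                                                  2000, 5000, 10000, 25000,
                                                  50000),
                                 n_quantile_groups = 12L) {
  stopifnot(all(weights >= 0))
  pos <- which(weights > 0)
  # order positive pairs by weight, largest first (stable in pair index)
  o <- pos[order(-weights[pos], pos)]
  labels <- rep(NA_character_, length(weights))
  labels[weights == 0] <- "0"
  group_names <- character(0)

  take <- 0L
  for (i in seq_along(upper_counts)) {
    want <- upper_counts[i]
    avail <- length(o) - take
    if (avail <= 0L) {
      warning("fewer positive-weight pairs than the group spec requires; ",
              "groups truncated")
      break
    }
    got <- min(want, avail)
    if (got < want)
      warning("fewer positive-weight pairs than the group spec requires; ",
              "groups truncated")
    nm <- paste0("top", i)
    labels[o[(take + 1L):(take + got)]] <- nm
    group_names <- c(group_names, nm)
    take <- take + got
  }
  rest <- if (take < length(o)) o[(take + 1L):length(o)] else integer(0)
  if (length(rest)) {
    # rest is ordered largest-first; quantile group 1 = lowest weights
    qg <- ceiling(seq_along(rest) / (length(rest) / n_quantile_groups))
    qg <- n_quantile_groups + 1L - pmin(qg, n_quantile_groups)
    labels[rest] <- paste0("q", qg)
    group_names <- c(group_names, paste0("q", sort(unique(qg),
                                                   decreasing = TRUE)))
  }
  lev <- c("0", rev(group_names))
  out <- data.frame(pair = seq_along(weights),
                    group = factor(labels, levels = lev, ordered = TRUE),
                    weight = weights)
  summ <- do.call(rbind, lapply(lev, function(g) {
    w <- weights[out$group == g]
    data.frame(group = g, n = length(w),
               min_weight = if (length(w)) min(w) else NA_real_,
               max_weight = if (length(w)) max(w) else NA_real_)
  }))
  attr(out, "groups") <- summ
  out
}

#' Fraction of cross-mappable pairs among the top co-expressed pairs
#'
#' Orders pairs by decreasing absolute correlation (after excluding
#' span-overlapping pairs upstream) and reports the cumulative flagged
#' fraction, plus the background rate.
#'
#' @param pair_table data frame with `abs_r` and `crossmappable` columns.
#' @return list with `curve` (rank, fraction) and `background`.
#' @export
top_coexpression_crossmap_fraction <- function(pair_table) {
  o <- order(-pair_table$abs_r)
  fl <- pair_table$crossmappable[o]
  list(curve = data.frame(rank = seq_along(fl),
                          fraction = cumsum(fl) / seq_along(fl)),
       background = mean(pair_table$crossmappable))
}
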