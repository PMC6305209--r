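test_that("variant filtering applies inclusive MAF and repeat masking", {
  v <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                  chrom = "c1", pos = c(10L, 20L, 150L, 300L),
                  maf = c(0.04, 0.05, 0.3, 0.3))
  rep_iv <- data.frame(chrom = "c1", start = 100L, end = 200L)
  out <- filter_variants(v, rep_iv, maf_min = 0.05)
  expect_identical(out$variant_id, c("v2", "v4"))  # v1 low MAF, v3 in repeat
  expect_identical(filter_variants(v)$variant_id, c("v2", "v3", "v4"))
})

test_that("cis/trans classification uses the inclusive 1 Mb TSS window", {
  gm <- gene_model("g", "c1", "+", data.frame(start = 5e6, end = 5.001e6))
  expect_identical(classify_pair(list(chrom = "c1", pos = 5e6 - 999999), gm),
                   "cis")
  expect_identical(classify_pair(list(chrom = "c1", pos = 5e6 + 1e6), gm),
                   "cis")
  expect_identical(classify_pair(list(chrom = "c2", pos = 5e6), gm), "trans")
  expect_identical(classify_pair(list(chrom = "c1", pos = 1e7), gm), "other")
})

test_that("the OLS association test matches lm and recovers a perfect fit", {
  withr::with_seed(71, {
    g <- rbinom(10, 2, 0.4)
    fit <- linear_association(g, 2 * g)
    expect_equal(fit$beta, 2)
    expect_lt(fit$p, 1e-12)

    # against lm with covariates
    n <- 80
    geno <- rbinom(n, 2, 0.3)
    cov <- rbind(age = rnorm(n), pc1 = rnorm(n))
    y <- 0.4 * geno + 0.2 * cov[1, ] + rnorm(n)
    mine <- linear_association(geno, y, cov)
    ref <- summary(lm(y ~ geno + t(cov)))$coefficients["geno", ]
    expect_equal(mine$beta, unname(ref["Estimate"]))
    expect_equal(mine$statistic, unname(ref["t value"]))
    expect_equal(mine$p, unname(ref["Pr(>|t|)"]))

    expect_error(linear_association(rep(1, 10), rnorm(10)), "zero-variance")
  })
})

test_that("the OLS test recovers a simulated effect within 3 standard errors", {
  withr::with_seed(73, {
    n <- 200; b <- 0.5
    betas <- se_ok <- numeric(50)
    for (i in 1:50) {
      g <- rbinom(n, 2, 0.3)
      y <- b * g + rnorm(n)
      fit <- linear_association(g, y)
      se <- fit$beta / fit$statistic
      se_ok[i] <- abs(fit$beta - b) <= 3 * se
      betas[i] <- fit$beta
    }
    expect_gte(mean(se_ok), 0.95)
    # mean of 50 estimates: SE ~ 0.109 / sqrt(50), allow 3 sigma
    expect_lt(abs(mean(betas) - b), 0.05)
  })
})

test_that("BH adjustment matches the closed-form step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.5, 7)), rep(0.5, 7))
  # hand-computed min-step example with distinct values
  expect_equal(bh_fdr(c(0.001, 0.012, 0.04, 0.3)),
               c(0.001 * 4 / 1, 0.012 * 4 / 2, 0.04 * 4 / 3, 0.3),
               tolerance = 1e-12)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("flagging requires a cross-mapping gene within the window", {
  models <- structure(list(
    cisg = gene_model("cisg", "c1", "+", data.frame(start = 200000, end = 200400)),
    farg = gene_model("farg", "c1", "+", data.frame(start = 1500000, end = 1500400)),
    tgt = gene_model("tgt", "c2", "+", data.frame(start = 1000, end = 1400)),
    tgt2 = gene_model("tgt2", "c2", "+", data.frame(start = 9000, end = 9400))
  ), class = "gene_model_list")
  res <- crossmap_resource(data.frame(
    gene_a = c("cisg", "farg"), gene_b = c("tgt", "tgt2"),
    count = c(7L, 4L)))
  assoc <- data.frame(
    variant_id = "v1", gene_id = c("tgt", "tgt2"),
    chrom = "c1", pos = 0L, p = c(1e-8, 1e-6),
    eqtl_class = "trans", stringsAsFactors = FALSE)
  out <- flag_trans_eqtls(assoc, models, res, window_bp = 1e6)
  expect_true(out$crossmappable[out$gene_id == "tgt"])    # cisg at 200 kb
  expect_false(out$crossmappable[out$gene_id == "tgt2"])  # farg at 1.5 Mb
  expect_error(flag_trans_eqtls(
    data.frame(variant_id = "v", gene_id = "nope", chrom = "c1", pos = 0L),
    models, res), "absent")
})

test_that("FDR reassessment after filtering matches the hand-worked example", {
  # 4 tests; the two flagged ones carry the smallest p-values.
  # original BH: sorted p (0.0001, 0.0002, 0.03, 0.2) -> adjusted
  # (0.0004, 0.0004, 0.04, 0.2): three significant at alpha = 0.05,
  # including the unflagged p = 0.03.
  # after dropping flagged tests: BH on (0.03, 0.2) -> (0.06, 0.2):
  # nothing significant.
  assoc <- data.frame(
    variant_id = paste0("v", 1:4), gene_id = paste0("g", 1:4),
    p = c(0.0001, 0.0002, 0.03, 0.2),
    crossmappable = c(TRUE, TRUE, FALSE, FALSE))
  out <- refilter_and_reassess(assoc, alpha = 0.05)
  expect_equal(sort(out$original_significant$gene_id), c("g1", "g2", "g3"))
  expect_equal(nrow(out$filtered_significant), 0L)
  expect_equal(out$n_genes_original, 3L)
  expect_equal(out$n_genes_filtered, 0L)

  # all unflagged: identical sets
  assoc$crossmappable <- FALSE
  out2 <- refilter_and_reassess(assoc, alpha = 0.05)
  expect_identical(out2$original_significant$gene_id,
                   out2$filtered_significant$gene_id)

  # alpha = 0: both empty
  out3 <- refilter_and_reassess(assoc, alpha = 0)
  expect_equal(nrow(out3$original_significant), 0L)
  expect_equal(nrow(out3$filtered_significant), 0L)
})

test_that("top-hit curve reports cumulative flagged fractions and background", {
  assoc <- data.frame(
    variant_id = paste0("v", 1:8), gene_id = paste0("g", 1:8),
    p = (1:8) / 100,
    crossmappable = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  out <- top_hit_crossmap_fraction(assoc)
  expect_equal(out$curve$fraction[4], 0.75)
  expect_equal(out$background, 3 / 8)

  assoc$crossmappable <- FALSE
  expect_true(all(top_hit_crossmap_fraction(assoc)$curve$fraction == 0))
})

test_that("replication fractions per flag class match direct arithmetic", {
  withr::with_seed(79, {
    # 28 non-cross-mappable genes of which 3 replicate; 16 cross-mappable
    # of which 5 replicate
    n_nc <- 28; n_cm <- 16
    disc <- data.frame(
      variant_id = paste0("v", 1:(n_nc + n_cm)),
      gene_id = paste0("g", 1:(n_nc + n_cm)),
      p = runif(n_nc + n_cm, 0, 1e-4),
      crossmappable = rep(c(FALSE, TRUE), c(n_nc, n_cm)))
    # replication p-values: tiny for the designated replicators, ~1 otherwise
    repl_p <- rep(0.99, n_nc + n_cm)
    repl_p[c(1:3, n_nc + 1:5)] <- 1e-8
    repl <- data.frame(variant_id = disc$variant_id,
                       gene_id = disc$gene_id, p = repl_p)
    out <- replication_fraction(disc, repl, alpha = 0.05)
    expect_equal(out$fraction[!out$crossmappable], 3 / 28, tolerance = 1e-12)
    expect_equal(out$fraction[out$crossmappable], 5 / 16, tolerance = 1e-12)
    expect_equal(round(out$fraction[!out$crossmappable] * 100, 2), 10.71)
    expect_equal(round(out$fraction[out$crossmappable] * 100, 2), 31.25)

    # best-variant-per-gene selection keeps the lowest p
    disc2 <- rbind(disc,
                   data.frame(variant_id = "vdup", gene_id = "g1",
                              p = 1, crossmappable = FALSE))
    repl2 <- rbind(repl, data.frame(variant_id = "vdup", gene_id = "g1",
                                    p = 0.5))
    out2 <- replication_fraction(disc2, repl2, alpha = 0.05)
    expect_equal(out2$n[!out2$crossmappable], 28)

    # missing replication values are excluded with a message
    expect_message(
      out3 <- replication_fraction(disc, repl[-1, ], alpha = 0.05),
      "excluding 1")
    expect_equal(out3$n[!out3$crossmappable], 27)

    # empty class reported NA
    out4 <- replication_fraction(disc[disc$crossmappable, ], repl)
    expect_true(is.na(out4$fraction[!out4$crossmappable]))
  })
})

test_that("the vectorized trans scan agrees with the single-pair test", {
  withr::with_seed(83, {
    n <- 60
    E <- matrix(rnorm(3 * n), 3, dimnames = list(c("gX", "gY", "gZ"), NULL))
    G <- matrix(rbinom(2 * n, 2, 0.3), 2, dimnames = list(c("v1", "v2"), NULL))
    vm <- data.frame(variant_id = c("v1", "v2"), chrom = c("c1", "c2"),
                     pos = c(100L, 200L))
    gi <- data.frame(gene_id = c("gX", "gY", "gZ"),
                     chrom = c("c1", "c2", "c3"), tss = c(1e6, 2e6, 3e6))
    cov <- rbind(pc1 = rnorm(n))
    sc <- trans_eqtl_scan(G, vm, E, gi, covariates = cov)
    # v1 x gX is same-chrom beyond 1 Mb -> "other", excluded
    expect_equal(nrow(sc), 4L)
    for (i in seq_len(nrow(sc))) {
      single <- linear_association(G[sc$variant_id[i], ],
                                   E[sc$gene_id[i], ], cov)
      expect_equal(sc$p[i], single$p)
      expect_equal(sc$beta[i], single$beta)
    }
  })
})
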