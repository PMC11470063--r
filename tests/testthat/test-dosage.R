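test_that("cell QC uses strict less-than thresholds", {
  ng <- 600L
  m <- matrix(0L, ng, 3,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              c("m1_c1", "m1_c2", "m1_c3")))
  m[1:499, 1] <- 1L          # 499 UMI, 499 genes -> removed
  m[1:500, 2] <- 1L          # 500 UMI, 500 genes -> retained (boundary)
  m[1:499, 3] <- 2L          # 998 UMI but 499 genes -> removed
  cm <- make_tiny_cm(m)
  out <- filter_cells(cm, min_umi = 500L, min_genes = 500L)
  expect_equal(colnames(out$counts), "m1_c2")
  # empty matrix passes through
  cm0 <- make_tiny_cm(m[, 0, drop = FALSE])
  expect_warning(out0 <- filter_cells(cm0), "all cells")
  expect_equal(ncol(out0$counts), 0L)
})

test_that("UMI outlier flagging supports both rule readings", {
  expect_equal(flag_umi_outliers(rep(100, 50)), rep(FALSE, 50))
  set.seed(3)
  # bounded noise: no non-outlier can exceed mean + 3 sd
  tot <- round(runif(1000, 900, 1100))
  tot[1] <- round(mean(tot) + 4 * sd(tot))
  fl <- flag_umi_outliers(tot)
  expect_true(fl[1])
  expect_equal(sum(fl[-1]), 0L)
  # the literal product rule mu * 3 * sigma flags nothing here
  # (threshold far above every total) but flags everything when the
  # dispersion is tiny relative to the mean
  expect_equal(sum(flag_umi_outliers(tot, rule = "mu_times_3sigma")), 0L)
  tight <- c(rep(1000, 20), 1001)
  expect_true(all(flag_umi_outliers(tight, rule = "mu_times_3sigma")))
  expect_error(flag_umi_outliers(5), "2 cells")
})

test_that("pseudobulk sums raw counts per mouse and conserves totals", {
  g <- fx_genome()
  cm <- simulate_sc_counts(g, make_dosage_designs(TRUE), seed = 41L)
  pb <- pseudobulk(cm)
  expect_equal(sum(pb$counts), sum(cm$counts))
  # independent summation oracle per (gene, mouse)
  for (s in sample(colnames(pb$counts), 2)) {
    cols <- cm$cells$sample_id == s
    expect_equal(pb$counts[, s], rowSums(cm$counts[, cols]))
  }
  # one cell per mouse: table equals the input columns
  one <- cm
  keep <- !duplicated(cm$cells$sample_id)
  one$counts <- cm$counts[, keep]; one$cells <- cm$cells[keep]
  pb1 <- pseudobulk(one)
  expect_equal(unname(pb1$counts), unname(one$counts))
  # two cells with counts 3 and 4 sum to 7
  m <- matrix(c(3L, 4L), 1, 2, dimnames = list("g1", c("m1_c1", "m1_c2")))
  expect_equal(unname(pseudobulk(make_tiny_cm(m))$counts[1, 1]), 7L)
})

test_that("gene filtering reads 'fewer than 10 per sample' per sample", {
  m <- matrix(c(12L, 9L,
                10L, 10L,
                50L, 0L), 3, 2, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  pb <- structure(list(counts = m,
                       samples = data.table::data.table(
                         sample_id = c("s1", "s2"), genotype = "XXT",
                         carrier = FALSE, sex_chr = "XX", gonad = "T"),
                       genes = data.table::data.table(
                         gene = rownames(m), contig = "chrA",
                         start = 1:3, end = 2:4)),
                  class = "pseudobulk")
  expect_equal(rownames(filter_genes(pb, 10L)$counts), "gB")
  expect_equal(rownames(filter_genes(pb, 0L)$counts), rownames(m))
  expect_equal(rownames(filter_genes(pb, 10L, mode = "total")$counts),
               c("gA", "gB", "gC"))
})

test_that("size factors are median-of-ratios, matching hand computation and DESeq2", {
  m <- matrix(rpois(40, 100) + 1L, 10, 4)
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))

  # sample2 = 2 x sample1: hand computation gives (1/sqrt(2), sqrt(2))
  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  # permutation symmetry
  sf <- size_factors(m)
  sf_perm <- size_factors(m[, c(3, 1, 4, 2)])
  expect_equal(unname(sf_perm), unname(sf[c(3, 1, 4, 2)]))
  # independent cross-check against DESeq2's estimator
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
  # all-zero gene rows break no qualifying-gene case
  expect_error(size_factors(matrix(c(0L, 5L, 3L, 0L), 2, 2)), "nonzero")
})

test_that("method-of-moments dispersion recovers alpha and floors Poisson data", {
  set.seed(6)
  n <- 50L
  groups <- rep(c("a", "b"), each = n / 2)
  sf <- rep(1, n)
  # NB alpha = 0.5: median estimate within [0.35, 0.65]
  mnb <- t(vapply(1:200, function(i)
    rnbinom(n, mu = 100, size = 1 / 0.5), numeric(n)))
  rownames(mnb) <- sprintf("g%03d", 1:200)
  a_nb <- estimate_dispersion(mnb, sf, groups)
  expect_gt(median(a_nb), 0.35); expect_lt(median(a_nb), 0.65)
  # Poisson data: most estimates at or near the floor
  mpo <- t(vapply(1:200, function(i) rpois(n, 100), numeric(n)))
  rownames(mpo) <- sprintf("g%03d", 1:200)
  a_po <- estimate_dispersion(mpo, sf, groups)
  expect_gt(mean(a_po < 0.01), 0.8)
  # variance < mean is floored exactly
  mlow <- matrix(rep(c(10L, 10L, 10L, 11L), 3), 3, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  a_fl <- estimate_dispersion(mlow, rep(1, 4), rep(c("a", "b"), each = 2))
  expect_true(all(a_fl == 1e-8))
  # moderation floors every gene at the across-gene median
  a_mod <- estimate_dispersion(mnb, sf, groups, moderate = TRUE)
  expect_true(all(a_mod >= median(a_nb)))
})

test_that("the NB Wald test is calibrated under the null and recovers the dosage effect", {
  g <- fx_genome()
  # null: multiplier 1
  cm0 <- simulate_sc_counts(g, make_dosage_designs(FALSE),
                            params = list(multiplier = 1), seed = 51L)
  out0 <- run_dosage(cm0, g, gonad = "T")
  res0 <- out0$results[tested == TRUE]
  expect_lt(abs(median(res0$log2fc)), 0.1)
  expect_gt(mean(res0$pvalue), 0.25)   # roughly uniform p-values
  expect_lt(mean(res0$pvalue), 0.75)

  # dosage: multiplier 2 genes recover log2FC ~ 1
  cm2 <- simulate_sc_counts(g, make_dosage_designs(TRUE), seed = 52L)
  out2 <- run_dosage(cm2, g, gonad = "T")
  dupg <- cm2$truth[in_duplication == TRUE, gene]
  l2 <- out2$results[gene %in% dupg, log2fc]
  expect_gt(mean(l2), 0.8); expect_lt(mean(l2), 1.2)
  # only chrX genes are tested
  expect_true(all(out2$results[tested == TRUE, contig] == "chrX"))
})

test_that("the alpha->0 limit of the NB fit agrees with a Poisson GLM oracle", {
  set.seed(7)
  n <- 6L
  x <- rep(c(0L, 1L), each = 3)
  sf <- rlnorm(n, 0, 0.2)
  samples <- data.table::data.table(
    sample_id = paste0("s", 1:n), genotype = ifelse(x == 1, "XYT", "XXT"),
    carrier = FALSE, sex_chr = ifelse(x == 1, "XY", "XX"), gonad = "T")
  m <- t(vapply(1:20, function(i)
    rpois(n, lambda = sf * exp(runif(1, 3, 6) + 0.5 * x)), numeric(n)))
  rownames(m) <- sprintf("g%02d", 1:20)
  pb <- structure(list(counts = m, samples = samples,
                       genes = data.table::data.table(
                         gene = rownames(m), contig = "chrX",
                         start = seq_len(20), end = seq_len(20) + 1L)),
                  class = "pseudobulk")
  disp <- setNames(rep(1e-10, 20), rownames(m))
  res <- nb_wald_test(pb, sf, disp)
  for (gi in rownames(m)) {
    fit <- stats::glm(m[gi, ] ~ x + offset(log(sf)), family = stats::poisson())
    z_oracle <- summary(fit)$coefficients["x", "z value"]
    expect_lt(abs(res[gene == gi, stat] - z_oracle), 0.05)
  }
})

test_that("BH adjustment matches the hand-computed step-up values", {
  res <- data.table::data.table(
    gene = paste0("g", 1:4), contig = "chrX", basemean = 100,
    log2fc = c(1, 1, -1, 1), se = 0.1, stat = 5,
    pvalue = c(0.01, 0.02, 0.03, 0.04), padj = NA_real_, tested = TRUE)
  adj <- bh_adjust(res, q = 0.10)
  expect_equal(adj$padj, rep(0.04, 4))   # min_j>=i p_j * m / j = 0.04 for all
  expect_true(all(adj$significant_up == c(TRUE, TRUE, FALSE, TRUE)))

  one <- bh_adjust(res[1], q = 0.10)
  expect_equal(one$padj, one$pvalue)

  flat <- data.table::copy(res)[, pvalue := 1]
  expect_false(any(bh_adjust(flat)$significant_up))
  # untested genes never receive padj
  mixed <- data.table::copy(res)[1, tested := FALSE]
  expect_true(is.na(bh_adjust(mixed)$padj[1]))
})

test_that("region calling finds the maximal PAR-adjacent run", {
  g <- fx_genome()
  cm <- simulate_sc_counts(g, make_dosage_designs(TRUE), seed = 53L)
  out <- run_dosage(cm, g, gonad = "T")
  di <- g$duplication_interval
  expect_equal(out$region$n_significant, 9L)
  expect_true(out$region$interval[1] >= di[1] &&
              out$region$interval[2] <= di[2])
  expect_lt(out$region$distance_to_par, 500)

  # brute-force oracle over runs with max_skip = 0 on a constructed pattern
  genes <- data.table::data.table(
    gene = paste0("x", 1:8), contig = "chrX",
    start = seq(1000L, 8000L, by = 1000L))
  genes[, end := start + 100L]
  sig_pattern <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  res <- data.table::data.table(
    gene = genes$gene, contig = "chrX", basemean = 100, log2fc = 1,
    se = 0.1, stat = 5,
    pvalue = ifelse(sig_pattern, 1e-6, 0.9), padj = NA_real_, tested = TRUE)
  res <- bh_adjust(res, q = 0.10)
  call0 <- call_upregulated_region(res, genes, par_boundary = 10000L,
                                   max_skip = 0L)
  runs <- rle(res$significant_up)
  best_len <- max(runs$lengths[runs$values])
  expect_equal(call0$n_significant, best_len)
  expect_equal(call0$genes, c("x4", "x5", "x6"))
  # skipping one untested gene bridges the run
  res_skip <- data.table::copy(res)
  res_skip[3, `:=`(tested = FALSE, pvalue = NA_real_,
                   padj = NA_real_, significant_up = FALSE)]
  call1 <- call_upregulated_region(res_skip, genes, par_boundary = 10000L,
                                   max_skip = 1L)
  expect_equal(call1$genes, paste0("x", 1:6))
  expect_equal(call1$n_significant, 5L)

  # zero significant genes -> empty call
  none <- data.table::copy(res)[, `:=`(pvalue = 0.9, padj = 0.9,
                                       significant_up = FALSE)]
  empty <- call_upregulated_region(none, genes, par_boundary = 10000L)
  expect_equal(empty$n_significant, 0L)
  expect_null(empty$interval)
})

test_that("cell-type masks silence genes and protect region calls", {
  g <- fx_genome()
  mask <- matrix(TRUE, nrow = 2, ncol = 2,
                 dimnames = list(c("Tlr7", "Tlr8"),
                                 c("hepatocyte", "kupffer")))
  mask["Tlr7", "hepatocyte"] <- FALSE
  mask["Tlr8", "hepatocyte"] <- FALSE
  cm <- simulate_sc_counts(
    g, make_dosage_designs(TRUE),
    params = list(celltypes = c(hepatocyte = 0.5, kupffer = 0.5),
                  mask = mask, n_cells = 300L),
    seed = 54L)
  hep <- cm$cells$celltype == "hepatocyte"
  expect_true(all(cm$counts[c("Tlr7", "Tlr8"), hep] == 0L))
  expect_gt(sum(cm$counts[c("Tlr7", "Tlr8"), !hep]), 0L)
  # per-celltype analysis: masked genes are never called in hepatocytes,
  # and the region call bridges them via max_skip
  out <- run_dosage(cm, g, gonad = "T", celltype = "hepatocyte",
                    min_umi = 100L, min_genes = 20L, max_skip = 2L)
  expect_false(any(c("Tlr7", "Tlr8") %in%
                   out$results[significant_up == TRUE, gene]))
  expect_equal(out$region$n_significant, 7L)
  expect_true(all(setdiff(cm$truth[in_duplication == TRUE, gene],
                          c("Tlr7", "Tlr8")) %in% out$region$genes))
  # unknown mask gene errors
  badmask <- matrix(TRUE, 1, 1, dimnames = list("nope", "hepatocyte"))
  expect_error(simulate_sc_counts(g, make_dosage_designs(TRUE),
                                  params = list(
                                    celltypes = c(hepatocyte = 1),
                                    mask = badmask), seed = 1L),
               "unknown genes")
})

test_that("pseudo-bulk dosage ratios match the configured multiplier", {
  g <- fx_genome()
  # multiplier 1: expected XY/XX ratio is 1 for every gene
  cm1 <- simulate_sc_counts(g, make_dosage_designs(FALSE),
                            params = list(multiplier = 1), seed = 55L)
  expect_true(all(cm1$truth$expected_fold_change == 1))
  # multiplier 2, 200 cells/sample: empirical pseudo-bulk ratio in [1.8, 2.2]
  cm2 <- simulate_sc_counts(g, make_dosage_designs(TRUE), seed = 56L)
  pb <- pseudobulk(cm2)
  dupg <- cm2$truth[in_duplication == TRUE, gene]
  xy <- pb$samples[sex_chr == "XY", sample_id]
  xx <- pb$samples[sex_chr == "XX", sample_id]
  ratio <- rowSums(pb$counts[dupg, xy]) / rowSums(pb$counts[dupg, xx])
  expect_gt(mean(ratio), 1.8); expect_lt(mean(ratio), 2.2)
})
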