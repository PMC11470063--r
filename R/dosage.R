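# Pseudo-bulk dosage testing of XY vs XX within a gonadal group: cell QC,
# per-mouse summation of raw UMI counts, a per-sample gene filter,
# median-of-ratios size factors, method-of-moments NB dispersion, a
# negative-binomial Wald test restricted to chrX genes, BH correction at
# FDR 10%, and calling of the maximal contiguous run of significant
# upregulated genes adjacent to the PAR.

#' Remove low-quality cells
#'
#' Cells with fewer than `min_umi` total UMIs or fewer than `min_genes`
#' detected genes are removed (strict less-than, so a cell exactly at the
#' threshold is retained).
#'
#' @param cm A `count_matrix`.
#' @param min_umi,min_genes QC thresholds (defaults follow the full-scale
#'   convention of 500/500; pass scaled values for toy gene panels).
#' @return The filtered `count_matrix`.
#' @export
filter_cells <- function(cm, min_umi = 500L, min_genes = 500L) {
  stopifnot(min_umi > 0, min_genes > 0)
  tot <- colSums(cm$counts)
  det <- colSums(cm$counts > 0L)
  keep <- !(tot < min_umi | det < min_genes)
  if (!any(keep)) warning("all cells removed by QC")
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm$cells <- cm$cells[keep]
  cm
}

#' Flag total-UMI outlier cells
#'
#' The default rule flags cells whose total UMI count is at least
#' `mean + 3 * sd` of all cells' totals. The literal product form
#' (`mean * 3 * sd`) is available via `rule = "mu_times_3sigma"`.
#'
#' @param cm A `count_matrix` (or a numeric vector of totals).
#' @param rule `"mean_plus_3sd"` (default) or `"mu_times_3sigma"`.
#' @return Logical vector of flags, one per cell.
#' @export
flag_umi_outliers <- function(cm, rule = c("mean_plus_3sd", "mu_times_3sigma")) {
  rule <- match.arg(rule)
  tot <- if (is.numeric(cm)) cm else colSums(cm$counts)
  if (length(tot) < 2L) stop("need at least 2 cells")
  s <- sd(tot)
  if (s == 0) return(rep(FALSE, length(tot)))
  thr <- if (rule == "mean_plus_3sd") mean(tot) + 3 * s else mean(tot) * 3 * s
  tot >= thr
}

#' Sum raw counts per mouse (pseudo-bulk)
#'
#' @param cm A `count_matrix`.
#' @param celltype Optional cell type restriction (per-celltype analyses).
#' @return A `pseudobulk`: list with `counts` (gene x sample matrix),
#'   `samples` (data.table: `sample_id`, `genotype`, `sex_chr`, `gonad`),
#'   `genes`.
#' @export
pseudobulk <- function(cm, celltype = NULL) {
  cells <- cm$cells
  counts <- cm$counts
  if (!is.null(celltype)) {
    sel <- cells$celltype == celltype
    cells <- cells[sel]; counts <- counts[, sel, drop = FALSE]
  }
  if (any(is.na(cells$sample_id)))
    stop("cells without a sample mapping: ",
         paste(cells$cell_id[is.na(cells$sample_id)], collapse = ","))
  sids <- unique(cells$sample_id)
  pb <- vapply(sids, function(s)
    rowSums(counts[, cells$sample_id == s, drop = FALSE]),
    numeric(nrow(counts)))
  if (is.null(dim(pb)))
    pb <- matrix(pb, nrow = nrow(counts),
                 dimnames = list(rownames(counts), sids))
  samples <- cells[!duplicated(sample_id),
                   .(sample_id, genotype, carrier = carrier)]
  samples[, `:=`(sex_chr = ifelse(genotype %in% c("XYO", "XYT"), "XY", "XX"),
                 gonad = ifelse(genotype %in% c("XXT", "XYT"), "T", "O"))]
  structure(list(counts = pb, samples = samples[match(sids, sample_id)],
                 genes = cm$genes),
            class = "pseudobulk")
}

#' Exclude lowly expressed genes from a pseudo-bulk table
#'
#' The default reading of "fewer than 10 reads per sample" is a per-sample
#' minimum: a gene is retained only if every sample reaches `min_reads`.
#' `mode = "total"` offers the total-count alternative.
#'
#' @param pb A `pseudobulk`.
#' @param min_reads Threshold (>= is retained).
#' @param mode `"per_sample"` or `"total"`.
#' @return The filtered `pseudobulk`.
#' @export
filter_genes <- function(pb, min_reads = 10L, mode = c("per_sample", "total")) {
  mode <- match.arg(mode)
  keep <- if (mode == "per_sample") {
    apply(pb$counts >= min_reads, 1L, all)
  } else {
    rowSums(pb$counts) >= min_reads
  }
  pb$counts <- pb$counts[keep, , drop = FALSE]
  pb$genes <- pb$genes[match(rownames(pb$counts), gene)]
  pb
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over reference genes (genes
#' with nonzero counts in every sample) of the ratio of the sample's count
#' to the gene's geometric mean across samples.
#'
#' @param pb A `pseudobulk` or a gene x sample count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(pb) {
  m <- if (inherits(pb, "pseudobulk")) pb$counts else pb
  ref <- rowSums(m == 0) == 0L
  if (!any(ref))
    stop("no gene with nonzero counts in all samples; ",
         "consider a pseudo-reference fallback")
  lg <- log(m[ref, , drop = FALSE])
  lgm <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(stats::median(col - lgm)))
}

#' Method-of-moments NB dispersion per gene
#'
#' On size-factor-normalised counts, pools within-group variances and
#' estimates `alpha = max((s^2 - m) / m^2, floor)`.
#'
#' With few replicates the raw per-gene estimate is noisy and, when it
#' undershoots, anti-conservative; `moderate = TRUE` additionally floors
#' every gene at the median raw estimate across genes, sharing information
#' across the panel the way moderated dispersion estimators do.
#'
#' @param pb A `pseudobulk`.
#' @param factors Size factors (from [size_factors()]).
#' @param groups Factor/character vector of group labels per sample.
#' @param floor Lower bound on alpha.
#' @param moderate Floor each gene at the across-gene median estimate.
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(pb, factors, groups, floor = 1e-8,
                                moderate = FALSE) {
  m <- if (inherits(pb, "pseudobulk")) pb$counts else pb
  k <- sweep(m, 2L, factors, "/")
  groups <- as.character(groups)
  tabs <- table(groups)
  if (any(tabs < 2L)) stop("need >= 2 samples per group")
  ss <- 0; df <- 0
  for (g in names(tabs)) {
    kg <- k[, groups == g, drop = FALSE]
    ng <- ncol(kg)
    ss <- ss + apply(kg, 1L, stats::var) * (ng - 1L)
    df <- df + ng - 1L
  }
  s2 <- ss / df
  mbar <- rowMeans(k)
  alpha <- pmax((s2 - mbar) / mbar^2, floor)
  alpha[!is.finite(alpha)] <- floor
  if (moderate && length(alpha) > 1L)
    alpha <- pmax(alpha, stats::median(alpha))
  setNames(alpha, rownames(m))
}

#' @keywords internal
nb_irls_two_group <- function(y, x, offset, alpha, max_iter = 50L, tol = 1e-8) {
  # log-link NB regression y ~ x with fixed dispersion alpha and offset;
  # returns coef, se of the group coefficient, convergence flag
  X <- cbind(1, x)
  beta <- c(log(mean(y / exp(offset)) + 1e-8), 0)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    w <- as.numeric(mu / (1 + alpha * mu))
    z <- (eta - offset) + (y - mu) / mu
    xtw <- crossprod(X, w * X)
    rhs <- crossprod(X, w * z)
    new_beta <- tryCatch(solve(xtw, rhs), error = function(e) NULL)
    if (is.null(new_beta)) break
    delta <- max(abs(new_beta - beta))
    beta <- as.numeric(new_beta)
    if (delta < tol) { ok <- TRUE; break }
  }
  se <- tryCatch({
    eta <- offset + X %*% beta
    mu <- as.numeric(pmin(exp(eta), 1e12))
    w <- mu / (1 + alpha * mu)
    sqrt(diag(solve(crossprod(X, w * X))))[2L]
  }, error = function(e) NA_real_)
  list(beta = beta, se = se, converged = ok && is.finite(se))
}

#' Negative-binomial Wald dosage test, XY vs XX within a gonadal group
#'
#' Per gene, a two-group NB log-link model with size-factor offsets and the
#' given fixed dispersion is fitted by iteratively reweighted least
#' squares; the Wald statistic is `log2FC / SE` with a two-sided normal
#' p-value. Only chrX genes are marked `tested` (the correction is
#' restricted to them downstream).
#'
#' @param pb A `pseudobulk` (already gene-filtered).
#' @param factors Size factors.
#' @param dispersions Per-gene alpha (from [estimate_dispersion()]).
#' @param gonad Gonadal group to test within (`"T"` or `"O"`), or `NULL`
#'   to use all samples.
#' @return data.table: `gene`, `contig`, `basemean`, `log2fc`, `se`,
#'   `stat`, `pvalue`, `padj` (NA until [bh_adjust()]), `tested`.
#' @export
nb_wald_test <- function(pb, factors, dispersions, gonad = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  sel <- if (is.null(gonad)) rep(TRUE, ncol(pb$counts))
         else pb$samples$gonad == gonad
  m <- pb$counts[, sel, drop = FALSE]
  sf <- factors[sel]
  x <- as.integer(pb$samples$sex_chr[sel] == "XY")
  if (all(x == 1L) || all(x == 0L)) stop("both XY and XX samples required")
  offset <- log(sf)
  genes <- rownames(m)
  res <- lapply(genes, function(g) {
    y <- m[g, ]
    fit <- nb_irls_two_group(y, x, offset, dispersions[[g]])
    l2 <- fit$beta[2L] / log(2)
    se2 <- fit$se / log(2)
    stat <- if (is.finite(se2) && se2 > 0) l2 / se2 else NA_real_
    data.table::data.table(
      gene = g, basemean = mean(y / sf), log2fc = l2, se = se2, stat = stat,
      pvalue = if (fit$converged && is.finite(stat)) 2 * pnorm(-abs(stat))
               else NA_real_)
  })
  out <- data.table::rbindlist(res)
  out[, contig := pb$genes$contig[match(gene, pb$genes$gene)]]
  out[, tested := contig == "chrX" & !is.na(pvalue)]
  out[, padj := NA_real_]
  data.table::setcolorder(out, c("gene", "contig", "basemean", "log2fc",
                                 "se", "stat", "pvalue", "padj", "tested"))
  out[]
}

#' Benjamini-Hochberg adjustment over tested chrX genes
#'
#' @param results Output of [nb_wald_test()].
#' @param q FDR threshold for the `significant_up` column (padj < q with
#'   positive fold change).
#' @return The results with `padj` filled for tested genes and a
#'   `significant_up` flag.
#' @export
bh_adjust <- function(results, q = 0.10) {
  results <- data.table::copy(results)
  idx <- which(results$tested)
  if (length(idx))
    results$padj[idx] <- p.adjust(results$pvalue[idx], method = "BH")
  results[, significant := !is.na(padj) & padj < q & log2fc > 0]
  data.table::setnames(results, "significant", "significant_up")
  results[]
}

#' Call the maximal PAR-adjacent run of significant upregulated genes
#'
#' chrX genes are ordered by coordinate; the call is the longest run of
#' `significant_up` genes in which at most `max_skip` untested or
#' unexpressed genes (never a tested non-significant gene) are bridged.
#' Ties are broken in favour of the run closest to the PAR.
#'
#' @param results Output of [bh_adjust()].
#' @param genes Gene coordinate table (`gene`, `contig`, `start`, `end`).
#' @param par_boundary PAR start coordinate on chrX (0-based).
#' @param max_skip Untested genes tolerated inside a run.
#' @return A `region_call`: list with `genes`, `interval` (0-based
#'   half-open union of gene intervals), `n_significant`,
#'   `distance_to_par`; all-empty when nothing is significant.
#' @export
call_upregulated_region <- function(results, genes, par_boundary,
                                    max_skip = 1L) {
  gx <- genes[contig == "chrX"][order(start)]
  if (!nrow(gx)) stop("no chrX genes to order")
  st <- results[match(gx$gene, gene),
                .(sig = !is.na(significant_up) & significant_up,
                  skip = !tested | is.na(pvalue))]
  st[is.na(sig), sig := FALSE]
  n <- nrow(gx)
  best <- NULL
  for (i in seq_len(n)) {
    if (!st$sig[i]) next
    budget <- max_skip
    last_sig <- i
    nsig <- 1L
    j <- i
    while (j < n) {
      j <- j + 1L
      if (st$sig[j]) { nsig <- nsig + 1L; last_sig <- j }
      else if (st$skip[j]) {
        if (budget == 0L) break
        budget <- budget - 1L
      } else break
    }
    cand <- list(from = i, to = last_sig, nsig = nsig)
    if (is.null(best) || cand$nsig > best$nsig ||
        (cand$nsig == best$nsig &&
         abs(par_boundary - gx$end[cand$to]) <
         abs(par_boundary - gx$end[best$to]))) best <- cand
  }
  if (is.null(best)) {
    return(structure(list(genes = character(), interval = NULL,
                          n_significant = 0L, distance_to_par = NA_real_),
                     class = "region_call"))
  }
  run_genes <- gx$gene[best$from:best$to]
  iv <- c(gx$start[best$from], gx$end[best$to])
  structure(list(genes = run_genes, interval = iv,
                 n_significant = best$nsig,
                 distance_to_par = par_boundary - iv[2]),
            class = "region_call")
}

#' Run the full dosage pipeline on a count matrix
#'
#' QC (cell filter + UMI outlier flags), pseudo-bulk, gene filter, size
#' factors, dispersion, NB Wald test within a gonadal group, BH at the
#' given FDR, and region calling.
#'
#' @param cm A `count_matrix`.
#' @param genome The `toy_genome` (PAR boundary for region calling).
#' @param gonad Gonadal group (`"T"` or `"O"`).
#' @param min_umi,min_genes Cell QC thresholds (toy-scale defaults).
#' @param min_reads Gene filter threshold.
#' @param fdr BH threshold.
#' @param celltype Optional cell type restriction.
#' @param max_skip Region-calling gap tolerance.
#' @return List with `results` (DE table), `region` (`region_call`),
#'   `pseudobulk`, `size_factors`, `outlier_flags`.
#' @export
run_dosage <- function(cm, genome, gonad = "T", min_umi = 200L,
                       min_genes = 25L, min_reads = 10L, fdr = 0.10,
                       celltype = NULL, max_skip = 1L) {
  cm <- filter_cells(cm, min_umi, min_genes)
  flags <- flag_umi_outliers(cm)
  cm$counts <- cm$counts[, !flags, drop = FALSE]
  cm$cells <- cm$cells[!flags]
  pb <- pseudobulk(cm, celltype = celltype)
  sel <- pb$samples$gonad == gonad
  pb$counts <- pb$counts[, sel, drop = FALSE]
  pb$samples <- pb$samples[sel]
  pb <- filter_genes(pb, min_reads)
  sf <- size_factors(pb)
  disp <- estimate_dispersion(pb, sf, pb$samples$sex_chr, moderate = TRUE)
  res <- nb_wald_test(pb, sf, disp)
  res <- bh_adjust(res, q = fdr)
  region <- call_upregulated_region(res, cm$genes,
                                    genome$par_interval$chrX[1],
                                    max_skip = max_skip)
  list(results = res, region = region, pseudobulk = pb, size_factors = sf,
       outlier_flags = flags)
}

#' Write a differential-expression result table as TSV
#' @param results Output of [bh_adjust()] / [nb_wald_test()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_results <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}
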