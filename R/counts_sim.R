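# Single-cell UMI count simulation. Counts are negative-binomial with
# mean = gene baseline x cell size factor x dosage multiplier, where the
# multiplier applies only to genes inside the duplication interval in
# samples that carry the Y-fused extra copy and only in cell types where
# the gene is expressed. X-linked baselines are genotype-independent
# (X inactivation balances XX against XY), so the translocation multiplier
# is the only source of XY-vs-XX dosage signal.

#' Default count-simulation parameters
#'
#' @return Named list: `baseline_meanlog`/`baseline_sdlog` (log-normal
#'   per-gene baseline mean counts per cell), `dispersion` (NB alpha),
#'   `sf_sdlog` (log-normal per-cell size factor sigma), `multiplier`
#'   (carrier dosage of duplicated genes, default 2), `n_cells` per sample,
#'   `celltypes` (named proportions), `mask` (optional gene x celltype
#'   logical matrix; FALSE = not expressed).
#' @export
count_sim_params <- function() {
  list(
    baseline_meanlog = log(10),
    baseline_sdlog = 0.6,
    dispersion = 0.1,
    sf_sdlog = 0.3,
    multiplier = 2.0,
    n_cells = 200L,
    celltypes = c(splenocyte = 1.0),
    mask = NULL
  )
}

#' Simulate single-cell UMI count matrices for a set of sample designs
#'
#' @param genome A `toy_genome` (provides gene annotations and the
#'   duplication interval).
#' @param designs List of `sample_design`s (at least 2 per genotype group
#'   for downstream testing).
#' @param params Overrides of [count_sim_params()].
#' @param seed Integer seed.
#' @return A `count_matrix`: list with `counts` (gene x cell integer
#'   matrix), `genes` (data.table with coordinates), `cells` (data.table:
#'   `cell_id`, `sample_id`, `genotype`, `carrier`, `celltype`,
#'   `size_factor`), `truth` (per-gene expected carrier-vs-noncarrier fold
#'   change), `params`.
#' @export
simulate_sc_counts <- function(genome, designs, params = list(), seed = 1L) {
  p <- utils::modifyList(count_sim_params(), params)
  stopifnot(p$multiplier > 0, p$dispersion >= 0, all(unlist(lapply(
    designs, inherits, "sample_design"))))
  genes <- data.table::copy(genome$genes)
  ng <- nrow(genes)
  cts <- names(p$celltypes)
  if (!is.null(p$mask)) {
    if (!all(rownames(p$mask) %in% genes$gene))
      stop("mask references unknown genes: ",
           paste(setdiff(rownames(p$mask), genes$gene), collapse = ","))
    if (!all(colnames(p$mask) %in% cts))
      stop("mask references unknown cell types")
  }
  set.seed(seed)
  base <- rlnorm(ng, p$baseline_meanlog, p$baseline_sdlog)
  names(base) <- genes$gene
  di <- genome$duplication_interval
  in_dup <- genes$contig == "chrX" & genes$start >= di[1] & genes$end <= di[2]

  cells_list <- list(); counts_list <- list()
  for (d in designs) {
    nc <- as.integer(p$n_cells)
    ct <- sample(cts, nc, replace = TRUE, prob = p$celltypes)
    sf <- rlnorm(nc, -p$sf_sdlog^2 / 2, p$sf_sdlog)
    mult <- if (d$carries_translocation) ifelse(in_dup, p$multiplier, 1) else rep(1, ng)
    mu <- outer(base * mult, sf)
    if (!is.null(p$mask)) {
      off <- !p$mask
      for (cc in colnames(off)) {
        gsel <- rownames(off)[off[, cc]]
        mu[match(gsel, genes$gene), ct == cc] <- 0
      }
    }
    m <- matrix(0L, ng, nc)
    pos <- mu > 0
    m[pos] <- if (p$dispersion > 0) {
      rnbinom(sum(pos), mu = mu[pos], size = 1 / p$dispersion)
    } else {
      stats::rpois(sum(pos), mu[pos])
    }
    cid <- sprintf("%s_c%04d", d$sample_id, seq_len(nc))
    colnames(m) <- cid
    rownames(m) <- genes$gene
    counts_list[[d$sample_id]] <- m
    cells_list[[d$sample_id]] <- data.table::data.table(
      cell_id = cid, sample_id = d$sample_id, genotype = d$genotype,
      carrier = d$carries_translocation, celltype = ct, size_factor = sf)
  }
  counts <- do.call(cbind, counts_list)
  cells <- data.table::rbindlist(cells_list)
  truth <- data.table::data.table(
    gene = genes$gene, contig = genes$contig, in_duplication = in_dup,
    expected_fold_change = ifelse(in_dup, p$multiplier, 1))
  structure(list(counts = counts, genes = genes, cells = cells,
                 truth = truth, params = p, seed = seed),
            class = "count_matrix")
}

#' Write / read a count matrix and its sidecars as TSV
#' @param cm A `count_matrix`.
#' @param prefix Path prefix; writes/reads `<prefix>_counts.tsv`,
#'   `<prefix>_genes.tsv`, `<prefix>_cells.tsv`.
#' @return Invisibly, the written paths; `read_count_matrix` returns the
#'   `count_matrix`.
#' @export
write_count_matrix <- function(cm, prefix) {
  p1 <- paste0(prefix, "_counts.tsv")
  data.table::fwrite(data.table::as.data.table(cm$counts, keep.rownames = "gene"),
                     p1, sep = "\t")
  p2 <- paste0(prefix, "_genes.tsv")
  data.table::fwrite(cm$genes, p2, sep = "\t")
  p3 <- paste0(prefix, "_cells.tsv")
  data.table::fwrite(cm$cells, p3, sep = "\t")
  invisible(c(p1, p2, p3))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  cdt <- data.table::fread(paste0(prefix, "_counts.tsv"), sep = "\t")
  counts <- as.matrix(cdt[, -1])
  rownames(counts) <- cdt[[1]]
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    genes = data.table::fread(paste0(prefix, "_genes.tsv"), sep = "\t"),
    cells = data.table::fread(paste0(prefix, "_cells.tsv"), sep = "\t"),
    truth = NULL, params = list(), seed = NA_integer_
  ), class = "count_matrix")
}
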