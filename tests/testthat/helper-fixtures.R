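# Shared fixtures, built once per test session. The default toy genome and
# its seed index are reused across files; all randomness is seeded.

.fx <- new.env(parent = emptyenv())

fx_genome <- function() {
  if (is.null(.fx$genome)) .fx$genome <- build_toy_genome(seed = 1L)
  .fx$genome
}

fx_variants <- function() {
  if (is.null(.fx$variants))
    .fx$variants <- derive_strain_variants(fx_genome(), seed = 2L)
  .fx$variants
}

fx_index <- function() {
  if (is.null(.fx$index)) .fx$index <- index_genome(fx_genome(), k = 21L)
  .fx$index
}

fx_carrier_haps <- function() {
  if (is.null(.fx$carrier_haps))
    .fx$carrier_haps <- build_sample_haplotypes(
      fx_genome(), fx_variants(),
      sample_design("xyt_f1", "XYT", "F1-B6xCAST", TRUE))
  .fx$carrier_haps
}

fx_noncarrier_haps <- function() {
  if (is.null(.fx$nc_haps))
    .fx$nc_haps <- build_sample_haplotypes(
      fx_genome(), fx_variants(),
      sample_design("xy_f1", "XYT", "F1-B6xCAST", FALSE))
  .fx$nc_haps
}

# carrier WGS alignment shared by coverage/haplotype tests
fx_carrier_aln <- function() {
  if (is.null(.fx$carrier_aln)) {
    rs <- simulate_wgs_reads(fx_carrier_haps(), depth = 20, seed = 3L)
    .fx$carrier_reads <- rs
    .fx$carrier_aln <- map_readset(fx_index(), rs)
  }
  .fx$carrier_aln
}

fx_carrier_reads <- function() {
  invisible(fx_carrier_aln())
  .fx$carrier_reads
}

fx_noncarrier_aln <- function() {
  if (is.null(.fx$nc_aln)) {
    rs <- simulate_wgs_reads(fx_noncarrier_haps(), depth = 20, seed = 4L)
    .fx$nc_aln <- map_readset(fx_index(), rs)
  }
  .fx$nc_aln
}

make_dosage_designs <- function(carrier = TRUE, n = 3L) {
  c(lapply(seq_len(n), function(i)
    sample_design(sprintf("xyt%d", i), "XYT", "pure-B6", carrier)),
    lapply(seq_len(n), function(i)
      sample_design(sprintf("xxt%d", i), "XXT", "pure-B6", FALSE)))
}

# minimal hand-built count_matrix for boundary tests
make_tiny_cm <- function(counts, contigs = NULL) {
  ng <- nrow(counts)
  genes <- data.table::data.table(
    gene = rownames(counts),
    contig = contigs %||% rep("chrA", ng),
    start = seq_len(ng) * 1000L)
  genes[, end := start + 100L]
  genes[, strand := "+"]
  cells <- data.table::data.table(
    cell_id = colnames(counts),
    sample_id = sub("_c.*", "", colnames(counts)),
    genotype = "XXT", carrier = FALSE, celltype = "splenocyte",
    size_factor = 1)
  structure(list(counts = counts, genes = genes, cells = cells,
                 truth = NULL, params = list(), seed = 0L),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# PAR intervals of the default genome as an exclude table
fx_par_dt <- function() {
  g <- fx_genome()
  data.table::data.table(
    contig = names(g$par_interval),
    start = vapply(g$par_interval, `[`, 1, 1L),
    end = vapply(g$par_interval, `[`, 1, 2L))
}
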