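# Toy genome construction: a three-contig mouse-like genome (chrA, chrX,
# chrY) at ~1/1000 linear scale, with a pseudoautosomal region (PAR) shared
# verbatim between chrX and chrY, a PAR-adjacent gene cluster inside the
# planned duplication interval, interspersed L1-like repeat copies (one of
# which spans the Y-integration site), and full ground-truth annotation.

#' Default toy genome configuration
#'
#' Sizes follow a ~1/1000 linear scaling of the mouse genome: chrX 170 kb
#' with a 1 kb distal PAR, a 3,220 bp duplication interval abutting the PAR,
#' chrY 91.7 kb with the X-segment integration site at position 90,210, and
#' a 100 kb autosome.
#'
#' @return Named list of configuration defaults.
#' @export
toy_genome_config <- function() {
  list(
    chrA_len = 100000L,
    chrX_len = 170000L,
    chrY_len = 91700L,
    par_len  = 1000L,
    dup_len  = 3220L,
    genes_in_duplication = 9L,
    extra_x_genes = 2L,
    n_autosomal_genes = 30L,
    gene_len = 200L,
    junction_site = 90210L,
    repeat_len = 400L
  )
}

#' Build the toy genome with ground-truth annotations
#'
#' Constructs random contig sequences and deterministic annotations: the PAR
#' occupies the distal `par_len` bases of chrX and chrY with identical
#' sequence; the duplication interval of length `dup_len` abuts the PAR on
#' chrX and contains `genes_in_duplication` genes (named after the nine
#' genes of the real PAR-adjacent cluster when the count is nine);
#' `extra_x_genes` further genes sit proximally on chrX and
#' `n_autosomal_genes` on chrA. Three identical copies of an L1-like repeat
#' are interspersed on chrA, chrX and chrY; the chrY copy spans
#' `junction_site`, the position where the duplicated X segment integrates
#' in translocation carriers.
#'
#' @param config Named list overriding entries of [toy_genome_config()].
#' @param seed Integer seed; the builder is a pure function of
#'   `(config, seed)`.
#' @return An object of class `toy_genome`: list with `contigs` (named
#'   character vector), `par_interval` (per-contig 0-based half-open
#'   intervals), `genes`, `repeats` (data.tables), `duplication_interval`,
#'   `junction_site`, `config`.
#' @export
build_toy_genome <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(toy_genome_config(), config)
  cfg <- lapply(cfg, function(x) if (is.numeric(x)) as.integer(round(x)) else x)
  with(cfg, {
    if (chrA_len < 50000L || chrX_len < 50000L || chrY_len < 50000L)
      stop("contig sizes must be >= 50 kb")
    if (genes_in_duplication + extra_x_genes < 6L)
      stop("gene count must be >= 6")
    if (par_len + dup_len > chrX_len)
      stop("PAR + duplication exceed chrX length")
    if (junction_site + repeat_len / 2 > chrY_len - par_len ||
        junction_site - repeat_len / 2 < 0)
      stop("junction repeat does not fit on chrY outside the PAR")
    if (gene_len * genes_in_duplication > dup_len)
      stop("duplication interval cannot hold the requested genes")
  })

  set.seed(seed)
  chrA <- random_dna(cfg$chrA_len)
  chrX <- random_dna(cfg$chrX_len)
  chrY <- random_dna(cfg$chrY_len)

  par_start_x <- cfg$chrX_len - cfg$par_len
  par_start_y <- cfg$chrY_len - cfg$par_len
  # PAR is the same sequence on both sex chromosomes
  substr(chrY, par_start_y + 1L, cfg$chrY_len) <-
    substr(chrX, par_start_x + 1L, cfg$chrX_len)

  dup_end <- par_start_x
  dup_start <- dup_end - cfg$dup_len

  # one L1-like repeat sequence, three interspersed copies; the chrY copy is
  # centred on the junction site so that the translocation boundary falls
  # inside a repeat, as in the real event
  rep_seq <- random_dna(cfg$repeat_len)
  half <- cfg$repeat_len %/% 2L
  rep_sites <- data.table::data.table(
    family = "L1-like",
    contig = c("chrA", "chrX", "chrY"),
    start = c(60000L, 60000L, cfg$junction_site - half)
  )
  rep_sites[, end := start + cfg$repeat_len]
  chrA <- `substr<-`(chrA, rep_sites$start[1] + 1L, rep_sites$end[1], value = rep_seq)
  chrX <- `substr<-`(chrX, rep_sites$start[2] + 1L, rep_sites$end[2], value = rep_seq)
  chrY <- `substr<-`(chrY, rep_sites$start[3] + 1L, rep_sites$end[3], value = rep_seq)

  dup_gene_names <- if (cfg$genes_in_duplication == 9L) {
    c("Tmsb4x", "Tlr8", "Tlr7", "Prps2", "Frmpd4", "Msl3", "Arhgap6",
      "Amelx", "Hccs")
  } else {
    sprintf("dupg%02d", seq_len(cfg$genes_in_duplication))
  }
  pitch <- cfg$dup_len %/% cfg$genes_in_duplication
  dup_starts <- dup_start + (seq_len(cfg$genes_in_duplication) - 1L) * pitch +
    (pitch - cfg$gene_len) %/% 2L
  extra_names <- c("Kdm6a", "Ddx3x", sprintf("xg%02d", seq_len(max(0L, cfg$extra_x_genes - 2L)) + 2L))
  extra_names <- extra_names[seq_len(cfg$extra_x_genes)]
  extra_starts <- as.integer(seq(20000L, 50000L, length.out = max(cfg$extra_x_genes, 2L)))[seq_len(cfg$extra_x_genes)]
  auto_names <- sprintf("a%02d", seq_len(cfg$n_autosomal_genes))
  auto_starts <- as.integer(seq(2000L, cfg$chrA_len - 2L * cfg$gene_len,
                                length.out = cfg$n_autosomal_genes))
  genes <- data.table::data.table(
    gene = c(auto_names, extra_names, dup_gene_names),
    contig = c(rep("chrA", cfg$n_autosomal_genes),
               rep("chrX", cfg$extra_x_genes + cfg$genes_in_duplication)),
    start = c(auto_starts, extra_starts, dup_starts)
  )
  genes[, end := start + cfg$gene_len]
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]

  g <- structure(
    list(
      contigs = c(chrA = chrA, chrX = chrX, chrY = chrY),
      par_interval = list(chrX = c(par_start_x, cfg$chrX_len),
                          chrY = c(par_start_y, cfg$chrY_len)),
      genes = genes,
      repeats = rep_sites,
      duplication_interval = c(dup_start, dup_end),
      junction_site = cfg$junction_site,
      config = cfg
    ),
    class = "toy_genome"
  )
  stopifnot(all(genes$end <= vapply(g$contigs[genes$contig], nchar, 1L)))
  g
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", paste(sprintf("%s (%d bp)", names(x$contigs),
                                   nchar(x$contigs)), collapse = ", "), "\n")
  cat(sprintf("  duplication chrX:[%d,%d)  junction chrY:%d  genes: %d\n",
              x$duplication_interval[1], x$duplication_interval[2],
              x$junction_site, nrow(x$genes)))
  invisible(x)
}

#' Contig lengths of a toy genome or haplotype set
#' @param contigs Named character vector of sequences.
#' @return Named integer vector.
#' @export
contig_lengths <- function(contigs) {
  vapply(contigs, nchar, integer(1L))
}

#' Write genome contigs to FASTA
#' @param genome A `toy_genome` or named character vector of sequences.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  contigs <- if (inherits(genome, "toy_genome")) genome$contigs else genome
  ss <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*", "", names(ss))
  out
}

#' Export ground-truth annotations (genes, repeats, duplication) as BED
#' @param genome A `toy_genome`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_truth_beds <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "genes.bed")
  write_bed(genome$genes[, .(contig, start, end, name = gene)], p1)
  p2 <- file.path(dir, "repeats.bed")
  write_bed(genome$repeats[, .(contig, start, end, name = family)], p2)
  p3 <- file.path(dir, "duplication.bed")
  write_bed(data.table::data.table(contig = "chrX",
                                   start = genome$duplication_interval[1],
                                   end = genome$duplication_interval[2],
                                   name = "duplication"), p3)
  invisible(c(p1, p2, p3))
}
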