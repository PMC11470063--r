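# Synthetic sci-RNA-seq3 raw reads: R1 carries the four concatenated
# barcodes (p7 + p5 + ligation + RT) and an 8-nt UMI; the truth table
# records the intended sample and whether a read was deliberately damaged
# beyond the hamming-1 rescue (two mismatches in one barcode), which a
# faithful demultiplexer must discard.

#' Generate random barcode whitelists and a sample sheet
#'
#' @param n_per_list Barcodes per whitelist.
#' @param n_samples Number of samples (combinations drawn without
#'   replacement).
#' @param frac_lig9 Fraction of ligation barcodes that are 9 nt.
#' @param seed Integer seed.
#' @return List with `files` (paths of the four whitelist files),
#'   `samplesheet` (path), written under `dir`.
#' @param dir Output directory.
#' @export
make_barcode_setup <- function(dir, n_per_list = 8L, n_samples = 4L,
                               frac_lig9 = 0.25, seed = 1L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rand_bc <- function(n, len) {
    repeat {
      bc <- vapply(seq_len(n), function(i) random_dna(len), "")
      # require pairwise hamming distance >= 4 so single mismatches are
      # rescued unambiguously and double mismatches can never be rescued
      if (n == 1L) return(bc)
      dmat <- outer(bc, bc, function(a, b)
        mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b))
      if (min(dmat[upper.tri(dmat)]) >= 4L) return(bc)
    }
  }
  n9 <- round(n_per_list * frac_lig9)
  wl <- list(
    p7 = rand_bc(n_per_list, 10L),
    p5 = rand_bc(n_per_list, 10L),
    ligation = c(rand_bc(n_per_list - n9, 10L), rand_bc(max(n9, 1L), 9L)[seq_len(n9)]),
    rt = rand_bc(n_per_list, 10L)
  )
  files <- lapply(names(wl), function(nm) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(wl[[nm]], p)
    p
  })
  names(files) <- names(wl)
  ss <- data.table::data.table(
    p7 = sample(wl$p7, n_samples, replace = TRUE),
    p5 = sample(wl$p5, n_samples, replace = TRUE),
    ligation = sample(wl$ligation, n_samples, replace = TRUE),
    rt = sample(wl$rt, n_samples),
    sample = sprintf("sample%02d", seq_len(n_samples))
  )
  ssp <- file.path(dir, "samplesheet.tsv")
  data.table::fwrite(ss, ssp, sep = "\t")
  list(files = files, samplesheet = ssp, whitelists = wl, sheet = ss)
}

#' @keywords internal
mutate_bases <- function(seqs, n_mut) {
  # introduce exactly n_mut substitutions per sequence
  for (i in seq_along(seqs)) {
    if (n_mut[i] == 0L) next
    L <- nchar(seqs[i])
    at <- sample.int(L, n_mut[i])
    for (p in at) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seqs
}

#' Simulate raw barcoded sci-RNA-seq3 read pairs with truth assignments
#'
#' R1 is p7(10) + p5(10) + ligation(9 or 10, as drawn from the sheet) +
#' RT(10) + UMI(8); R2 is random cDNA. The error profile injects single
#' mismatches (rescuable at hamming distance 1) and double mismatches
#' (marked `should_discard` in the truth table) into chosen barcodes.
#'
#' @param setup Output of [make_barcode_setup()] (or a compatible list with
#'   `sheet`).
#' @param n_reads Number of read pairs.
#' @param frac_1mm Fraction of reads receiving one mismatch in one barcode.
#' @param frac_2mm Fraction receiving two mismatches in one barcode
#'   (should be discarded by the demultiplexer).
#' @param cdna_len R2 length.
#' @param seed Integer seed.
#' @return List with `r1`, `r2` (FASTQ paths under `dir`), `truth`
#'   (data.table: `qname`, `sample`, `mutated_barcode`, `n_mismatch`,
#'   `should_discard`).
#' @param dir Output directory.
#' @export
simulate_scirnaseq_reads <- function(setup, dir, n_reads = 1000L,
                                     frac_1mm = 0.2, frac_2mm = 0.1,
                                     cdna_len = 50L, seed = 1L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- setup$sheet
  pick <- sample.int(nrow(sheet), n_reads, replace = TRUE)
  parts <- list(p7 = sheet$p7[pick], p5 = sheet$p5[pick],
                ligation = sheet$ligation[pick], rt = sheet$rt[pick])
  n_mut <- rep(0L, n_reads)
  which_bc <- rep(NA_character_, n_reads)
  shuffled <- sample.int(n_reads)
  n1 <- round(n_reads * frac_1mm); n2 <- round(n_reads * frac_2mm)
  idx1 <- shuffled[seq_len(n1)]
  idx2 <- shuffled[n1 + seq_len(n2)]
  n_mut[idx1] <- 1L; n_mut[idx2] <- 2L
  which_bc[c(idx1, idx2)] <- sample(names(parts), n1 + n2, replace = TRUE)
  for (bc in names(parts)) {
    sel <- which(which_bc == bc)
    if (length(sel))
      parts[[bc]][sel] <- mutate_bases(parts[[bc]][sel], n_mut[sel])
  }
  umi <- vapply(seq_len(n_reads), function(i) random_dna(UMI_LEN), "")
  r1 <- paste0(parts$p7, parts$p5, parts$ligation, parts$rt, umi)
  r2 <- vapply(seq_len(n_reads), function(i) random_dna(cdna_len), "")
  qname <- sprintf("sciread_%06d", seq_len(n_reads))
  truth <- data.table::data.table(
    qname = qname, sample = sheet$sample[pick],
    mutated_barcode = which_bc, n_mismatch = n_mut,
    should_discard = n_mut >= 2L)
  wr <- function(seqs, path) {
    ss <- Biostrings::DNAStringSet(seqs); names(ss) <- qname
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(ss))))
    path
  }
  list(r1 = wr(r1, file.path(dir, "sci_R1.fastq")),
       r2 = wr(r2, file.path(dir, "sci_R2.fastq")),
       truth = truth)
}
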