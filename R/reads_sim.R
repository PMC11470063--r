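# Read simulation from per-sample haplotype genomes. Fragments are sampled
# uniformly per haplotype copy; errors are substitutions only. The `depth`
# argument targets total coverage over diploid regions, i.e. each haplotype
# copy is sequenced at depth/2 — a male chrX therefore sits at half the
# autosomal coverage, as in real WGS.

#' @keywords internal
inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hits <- which(runif(total) < rate)
  if (!length(hits)) return(seqs)
  cum <- cumsum(lens)
  read_i <- findInterval(hits - 1L, cum) + 1L
  off <- hits - c(0L, cum)[read_i]
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(hits)) {
    i <- read_i[k]; o <- off[k]
    cur <- substr(seqs[i], o, o)
    substr(seqs[i], o, o) <- sample(setdiff(bases, cur), 1L)
  }
  seqs
}

#' Simulate paired-end WGS reads from a haplotype set
#'
#' Uniform fragment sampling per haplotype contig; R1 is the fragment
#' 5' end on the plus strand, R2 the reverse complement of the 3' end.
#' Truth alignments (haplotype contig, 0-based position, strand,
#' haplotype-of-origin) are recorded for every read.
#'
#' @param haplotypes A `haplotype_set`.
#' @param depth Target coverage over diploid regions (each haplotype copy is
#'   sampled at `depth/2`).
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment size distribution (normal, clipped
#'   to at least `2 * read_len`).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `read_set`: list with `reads` (data.table: `qname`, `mate`,
#'   `hap`, `contig`, `pos`, `strand`, `seq` in sequencing orientation),
#'   `read_len`, `type = "paired"`, `seed`.
#' @export
simulate_wgs_reads <- function(haplotypes, depth = 20, read_len = 100L,
                               insert_mean = 300, insert_sd = 30,
                               error_rate = 0, seed = 1L) {
  stopifnot(inherits(haplotypes, "haplotype_set"), depth > 0)
  set.seed(seed)
  out <- list()
  for (hap in c("maternal", "paternal")) {
    contigs <- haplotypes[[hap]]
    for (cn in names(contigs)) {
      len <- nchar(contigs[[cn]])
      if (read_len > len) stop("read_len exceeds contig length")
      nfrag <- as.integer(round(len * depth / 2 / (2 * read_len)))
      if (nfrag == 0L) next
      ins <- pmin(len, pmax(2L * read_len,
                            as.integer(round(rnorm(nfrag, insert_mean, insert_sd)))))
      f <- as.integer(floor(runif(nfrag, 0, len - ins + 1)))
      r1 <- substring(contigs[[cn]], f + 1L, f + read_len)
      r2 <- revcomp(substring(contigs[[cn]], f + ins - read_len + 1L, f + ins))
      qn <- sprintf("%s_%s_%s_%07d", haplotypes$design$sample_id, hap, cn,
                    seq_len(nfrag))
      out[[paste(hap, cn)]] <- data.table::data.table(
        qname = rep(qn, 2L),
        mate = rep(1:2, each = nfrag),
        hap = hap, contig = cn,
        pos = c(f, f + ins - read_len),
        strand = rep(c("+", "-"), each = nfrag),
        seq = c(r1, r2)
      )
    }
  }
  reads <- data.table::rbindlist(out)
  reads[, seq := inject_substitutions(seq, error_rate)]
  structure(list(reads = reads, read_len = read_len, type = "paired",
                 seed = seed, sample_id = haplotypes$design$sample_id),
            class = "read_set")
}

#' Simulate long single-end reads (nanopore-like, substitution errors only)
#'
#' Read lengths are gamma-distributed (shape 3, mean `mean_len`), clipped to
#' `[min_len, contig length]`; starts are uniform per haplotype copy at
#' `depth/2` coverage each. For translocation carriers, reads overlapping
#' the Y-insertion boundaries are junction-spanning by construction and are
#' flagged in the truth table.
#'
#' @param haplotypes A `haplotype_set`.
#' @param mean_len Mean read length (bp), at least 10x a short read.
#' @param depth Target diploid coverage (per-copy `depth/2`).
#' @param min_len Minimum read length.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `read_set` with `type = "long"`; truth columns include
#'   `spans_junction`.
#' @export
simulate_long_reads <- function(haplotypes, mean_len = 3000, depth = 30,
                                min_len = 300L, error_rate = 0, seed = 1L) {
  stopifnot(inherits(haplotypes, "haplotype_set"))
  if (mean_len < 1000) stop("mean_len must be at least 10x a short-read length")
  set.seed(seed)
  truth <- haplotypes$truth
  out <- list()
  for (hap in c("maternal", "paternal")) {
    contigs <- haplotypes[[hap]]
    for (cn in names(contigs)) {
      len <- nchar(contigs[[cn]])
      n <- as.integer(round(len * depth / 2 / mean_len))
      if (n == 0L) next
      L <- pmin(len, pmax(min_len, as.integer(round(
        stats::rgamma(n, shape = 3, scale = mean_len / 3)))))
      f <- as.integer(floor(runif(n, 0, len - L + 1)))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      sq <- substring(contigs[[cn]], f + 1L, f + L)
      sq[strand == "-"] <- revcomp(sq[strand == "-"])
      spans <- rep(FALSE, n)
      if (!is.null(truth) && hap == "paternal" && cn == "chrY") {
        b <- truth$insert_interval_hapY
        spans <- (f < b[1] & f + L > b[1]) | (f < b[2] & f + L > b[2])
      }
      qn <- sprintf("%s_%s_%s_long_%06d", haplotypes$design$sample_id, hap,
                    cn, seq_len(n))
      out[[paste(hap, cn)]] <- data.table::data.table(
        qname = qn, mate = 1L, hap = hap, contig = cn, pos = f,
        strand = strand, seq = sq,
        spans_junction = spans
      )
    }
  }
  reads <- data.table::rbindlist(out)
  reads[, seq := inject_substitutions(seq, error_rate)]
  structure(list(reads = reads, read_len = NA_integer_, type = "long",
                 seed = seed, sample_id = haplotypes$design$sample_id),
            class = "read_set")
}

#' Write a read set to FASTQ
#'
#' Paired sets write two files (R1/R2); long sets write one.
#'
#' @param rs A `read_set`.
#' @param prefix Output path prefix; files are `<prefix>_R1.fastq` (and
#'   `_R2`) or `<prefix>.fastq` for long reads.
#' @return Invisibly, the written paths.
#' @export
write_read_fastq <- function(rs, prefix) {
  write_one <- function(dt, path) {
    ss <- Biostrings::DNAStringSet(dt$seq)
    names(ss) <- dt$qname
    qual <- Biostrings::BStringSet(vapply(nchar(dt$seq),
      function(n) strrep("I", n), ""))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
    path
  }
  if (rs$type == "paired") {
    p1 <- write_one(rs$reads[mate == 1L], paste0(prefix, "_R1.fastq"))
    p2 <- write_one(rs$reads[mate == 2L], paste0(prefix, "_R2.fastq"))
    invisible(c(p1, p2))
  } else {
    invisible(write_one(rs$reads, paste0(prefix, ".fastq")))
  }
}

#' Write truth alignments of a read set as SAM against the haplotype genome
#'
#' Each read becomes one unpaired record at its truth coordinate, with the
#' haplotype of origin in the custom `XH:Z:` tag. SEQ is stored in reference
#' orientation per the SAM convention.
#'
#' @param rs A `read_set`.
#' @param haplotypes The `haplotype_set` the reads were simulated from.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_truth_sam <- function(rs, haplotypes, path) {
  lens <- c(contig_lengths(haplotypes$maternal),
            contig_lengths(haplotypes$paternal))
  lens <- lens[!duplicated(names(lens))]
  dt <- data.table::copy(rs$reads)
  dt[, seq := ifelse(strand == "-", revcomp(seq), seq)]
  aln <- data.table::data.table(
    qname = if (rs$type == "paired") paste0(dt$qname, "/", dt$mate)
            else dt$qname,
    flag = ifelse(dt$strand == "-", 16L, 0L),
    contig = dt$contig, pos = dt$pos,
    cigar = paste0(nchar(dt$seq), "M"),
    seq = dt$seq,
    tags = paste0("XH:Z:", dt$hap)
  )
  write_sam(aln, lens, path)
}
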