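# Shared helpers: seeded RNG, sequence utilities, interval conversions.
# All genomic intervals inside the package are 0-based half-open [start, end);
# conversion to 1-based (GRanges, VCF, SAM) happens only at I/O edges.

#' Derive a reproducible sub-seed for a pipeline stage
#'
#' Each randomised stage of the pipeline consumes its own sub-seed derived
#' from the root seed and the stage name, so that stages can be re-run in
#' isolation with identical results.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 97651L) * 21701 + (h * 1663) %% 2147480000) %% 2147483647L
}

#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
interval_len <- function(iv) iv[2L] - iv[1L]

# data.table with columns contig, start, end (0-based half-open) -> GRanges
#' @keywords internal
dt_to_granges <- function(dt, extra_cols = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = dt$contig,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
  for (cc in extra_cols) S4Vectors::mcols(gr)[[cc]] <- dt[[cc]]
  gr
}

#' Write 0-based half-open intervals to a BED file
#'
#' @param dt data.table with columns `contig`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(dt, path) {
  gr <- dt_to_granges(data.table::as.data.table(dt))
  if ("name" %in% names(dt)) names(gr) <- dt$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval table
#'
#' @param path BED file path.
#' @return data.table with columns `contig`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_
  )
}

#' @keywords internal
write_bedgraph <- function(contig, starts0, ends0, values, path) {
  keep <- is.finite(values)
  gr <- GenomicRanges::GRanges(
    seqnames = contig[keep],
    ranges = IRanges::IRanges(start = starts0[keep] + 1L, end = ends0[keep]),
    score = values[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
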