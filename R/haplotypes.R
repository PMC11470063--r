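# Per-sample haplotype genomes for the four FCG genotypes on a pure-B6 or
# F1 B6xCAST background. In the F1 cross the mother is CAST (contributing
# the X) and the father is the B6 FCG male (contributing the Y, or an X for
# XX offspring), matching the published cross. Translocation carriers get a
# copy of the B6 duplication-interval sequence inserted on the Y at the
# junction site.

#' Construct a sample design
#'
#' @param sample_id Sample identifier.
#' @param genotype One of `"XXO"`, `"XXT"`, `"XYO"`, `"XYT"`.
#' @param background `"pure-B6"` or `"F1-B6xCAST"`.
#' @param carries_translocation Logical; only XY genotypes may carry the
#'   Y-linked translocation.
#' @return A `sample_design` list.
#' @export
sample_design <- function(sample_id, genotype,
                          background = c("pure-B6", "F1-B6xCAST"),
                          carries_translocation = FALSE) {
  genotype <- match.arg(genotype, c("XXO", "XXT", "XYO", "XYT"))
  background <- match.arg(background)
  is_xy <- genotype %in% c("XYO", "XYT")
  if (!is_xy && carries_translocation)
    stop("XX genotypes cannot carry the Y-linked translocation")
  maternal <- if (background == "F1-B6xCAST") "CAST" else "B6"
  structure(list(
    sample_id = sample_id, genotype = genotype, background = background,
    carries_translocation = carries_translocation,
    maternal_strain = maternal, paternal_strain = "B6",
    is_xy = is_xy
  ), class = "sample_design")
}

#' Build per-haplotype genome sequences for a sample
#'
#' The maternal haplotype carries the maternal strain's alleles on chrA and
#' chrX; the paternal haplotype is B6 on chrA plus either chrX (XX designs)
#' or chrY (XY designs). For translocation carriers the paternal chrY gains
#' an inserted copy of the B6 duplication-interval sequence at
#' `junction_site`.
#'
#' @param genome A `toy_genome`.
#' @param variants A `strain_variants` table.
#' @param design A `sample_design`.
#' @return A `haplotype_set`: list with `maternal` and `paternal` named
#'   contig vectors, the `design`, and `truth` (junction coordinates on the
#'   carrier Y, or NULL).
#' @export
build_sample_haplotypes <- function(genome, variants, design) {
  stopifnot(inherits(design, "sample_design"))
  if (!design$is_xy && design$carries_translocation)
    stop("XX genotypes cannot carry the Y-linked translocation")
  ref <- genome$contigs
  hap_contig <- function(cn, strain) apply_strain_alleles(ref[[cn]], cn, variants, strain)

  maternal <- c(chrA = hap_contig("chrA", design$maternal_strain),
                chrX = hap_contig("chrX", design$maternal_strain))
  if (design$is_xy) {
    chrY <- hap_contig("chrY", design$paternal_strain)
    truth <- NULL
    if (design$carries_translocation) {
      di <- genome$duplication_interval
      dup_seq <- substr(ref[["chrX"]], di[1] + 1L, di[2])
      j <- genome$junction_site
      chrY <- paste0(substr(chrY, 1L, j), dup_seq,
                     substr(chrY, j + 1L, nchar(chrY)))
      truth <- list(
        insert_interval_hapY = c(j, j + (di[2] - di[1])),
        x_interval = di,
        junction_site = j
      )
    }
    paternal <- c(chrA = hap_contig("chrA", design$paternal_strain), chrY = chrY)
  } else {
    paternal <- c(chrA = hap_contig("chrA", design$paternal_strain),
                  chrX = hap_contig("chrX", design$paternal_strain))
    truth <- NULL
  }
  structure(list(maternal = maternal, paternal = paternal,
                 design = design, truth = truth),
            class = "haplotype_set")
}
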