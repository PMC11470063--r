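# Strain SNPs distinguishing the B6 reference from the CAST haplotype.
# The reference sequence *is* the B6 allele; CAST carries the alternate.
# No SNPs are placed inside the PAR (it recombines and is treated as shared),
# which also keeps the haplotype-fraction signal clean.

#' Derive a table of B6-vs-CAST strain SNPs
#'
#' Positions are drawn per base with probability `snp_rate` on every contig,
#' excluding the PAR intervals. The B6 allele equals the reference base; the
#' CAST allele is a uniformly chosen different base.
#'
#' @param genome A `toy_genome`.
#' @param snp_rate Per-bp SNP probability (default 0.007, the approximate
#'   genome-wide B6-vs-CAST SNP density), in (0, 0.1) (0 gives an empty
#'   table).
#' @param seed Integer seed.
#' @return `strain_variants` object: data.table with columns `contig`,
#'   `pos` (0-based), `b6`, `cast`, positions strictly increasing per contig.
#' @export
derive_strain_variants <- function(genome, snp_rate = 0.007, seed = 1L) {
  if (snp_rate < 0 || snp_rate >= 0.1)
    stop("snp_rate must lie in [0, 0.1)")
  set.seed(seed)
  out <- lapply(names(genome$contigs), function(cn) {
    len <- nchar(genome$contigs[[cn]])
    if (snp_rate == 0) return(NULL)
    pos <- which(runif(len) < snp_rate) - 1L
    par <- genome$par_interval[[cn]]
    if (!is.null(par)) pos <- pos[pos < par[1] | pos >= par[2]]
    if (!length(pos)) return(NULL)
    ref <- substring(genome$contigs[[cn]], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    data.table::data.table(contig = cn, pos = pos, b6 = ref, cast = unname(alt))
  })
  v <- data.table::rbindlist(out)
  if (!nrow(v)) v <- data.table::data.table(contig = character(), pos = integer(),
                                            b6 = character(), cast = character())
  data.table::setkey(v, contig, pos)
  structure(v, class = c("strain_variants", class(v)))
}

#' Write strain SNPs as a site-only VCF v4.2
#'
#' Coordinates are converted to the 1-based VCF convention.
#'
#' @param variants A `strain_variants` table.
#' @param genome The `toy_genome` (for contig headers).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_strain_vcf <- function(variants, genome, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fcgscout",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$contigs),
            nchar(genome$contigs)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$contig,
            variants$pos + 1L, variants$b6, variants$cast)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read strain SNPs from a VCF written by [write_strain_vcf()]
#'
#' Uses `vcfR` for parsing and converts back to 0-based positions.
#'
#' @param path VCF path.
#' @return A `strain_variants` table.
#' @export
read_strain_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vv <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vv)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = as.integer(length(fx) > 0), ncol = 8,
                                     dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")))
  v <- data.table::data.table(
    contig = as.character(fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]) - 1L,
    b6 = as.character(fx[, "REF"]),
    cast = as.character(fx[, "ALT"])
  )
  data.table::setkey(v, contig, pos)
  structure(v, class = c("strain_variants", class(v)))
}

#' @keywords internal
apply_strain_alleles <- function(seq, contig_name, variants, strain) {
  if (strain == "B6" || !nrow(variants)) return(seq)
  vv <- variants[contig == contig_name]
  if (!nrow(vv)) return(seq)
  r <- charToRaw(seq)
  r[vv$pos + 1L] <- as.raw(utf8ToInt(paste(vv$cast, collapse = "")))
  rawToChar(r)
}
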