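# Plain-text SAM interchange. Alignments travel through the package as
# data.tables with 0-based positions and match/soft-clip-only CIGARs; the
# SAM text form (1-based) is the on-disk interface, carrying the custom
# XH:Z (haplotype of origin) tag where applicable.

#' Write an alignment table as SAM
#'
#' @param aln data.table with columns `qname`, `flag`, `contig`, `pos`
#'   (0-based; ignored for unmapped records), `cigar`, `seq`, and optionally
#'   `mapq` and `tags` (pre-formatted, tab-joined if several).
#' @param contig_lens Named integer vector of reference lengths for the
#'   `@SQ` header.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(aln, contig_lens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lens),
                   as.integer(contig_lens)))
  if (nrow(aln)) {
    aln <- data.table::as.data.table(aln)
    unmapped <- bitwAnd(aln$flag, 4L) != 0L
    ord <- order(match(aln$contig, names(contig_lens)), aln$pos)
    aln <- aln[ord]
    unmapped <- unmapped[ord]
    mapq <- if ("mapq" %in% names(aln)) aln$mapq else ifelse(unmapped, 0L, 60L)
    body <- paste(aln$qname, aln$flag,
                  ifelse(unmapped, "*", aln$contig),
                  ifelse(unmapped, 0L, aln$pos + 1L),
                  mapq,
                  ifelse(unmapped, "*", aln$cigar),
                  "*", 0L, 0L, aln$seq,
                  strrep("I", nchar(aln$seq)), sep = "\t")
    if ("tags" %in% names(aln)) {
      has <- !is.na(aln$tags) & nzchar(aln$tags)
      body[has] <- paste(body[has], aln$tags[has], sep = "\t")
    }
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @keywords internal
parse_cigar_ms <- function(cigar) {
  # decompose CIGARs restricted to the soft-clip/match alphabet into
  # (clip_left, mlen, clip_right); "*" gives zeros
  grab <- function(pattern) {
    out <- integer(length(cigar))
    m <- regexpr(pattern, cigar, perl = TRUE)
    hit <- m > 0L
    out[hit] <- as.integer(regmatches(cigar, m))
    out
  }
  list(clip_left = grab("^\\d+(?=S)"),
       mlen = grab("\\d+(?=M)"),
       clip_right = grab("\\d+(?=S$)"))
}

#' Read a SAM file written by this package
#'
#' Supports the match/soft-clip CIGAR alphabet used throughout; positions are
#' returned 0-based. Optional tags are kept verbatim in `tags`; the
#' haplotype-of-origin tag, when present, is extracted into `hap`.
#'
#' @param path SAM path.
#' @return List with `aln` (data.table: `qname`, `flag`, `contig`, `pos`,
#'   `cigar`, `seq`, `mapq`, `tags`, `hap`, `mapped`, `is_supp`,
#'   `clip_left`, `mlen`, `clip_right`) and `contig_lens`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  contig_lens <- setNames(
    as.integer(sub(".*\tLN:(\\d+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  body <- lines[!is_hdr]
  if (!length(body)) {
    return(list(aln = data.table::data.table(
      qname = character(), flag = integer(), contig = character(),
      pos = integer(), cigar = character(), seq = character(),
      mapq = integer(), tags = character(), hap = character(),
      mapped = logical(), is_supp = logical(), clip_left = integer(),
      mlen = integer(), clip_right = integer()), contig_lens = contig_lens))
  }
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE, fill = NA_character_)
  n_mand <- 11L
  bad <- is.na(parts[[n_mand]])
  if (any(bad)) stop(sprintf("malformed SAM line %d (fewer than 11 fields)",
                             which(bad)[1] + sum(is_hdr)))
  tags <- if (length(parts) > n_mand) {
    extra <- do.call(cbind, parts[(n_mand + 1L):length(parts)])
    apply(extra, 1L, function(r) paste(r[!is.na(r)], collapse = "\t"))
  } else rep("", length(body))
  aln <- data.table::data.table(
    qname = parts[[1]],
    flag = as.integer(parts[[2]]),
    contig = parts[[3]],
    pos = as.integer(parts[[4]]) - 1L,
    mapq = as.integer(parts[[5]]),
    cigar = parts[[6]],
    seq = parts[[10]],
    tags = tags
  )
  aln[, mapped := bitwAnd(flag, 4L) == 0L]
  aln[, is_supp := bitwAnd(flag, 2048L) != 0L]
  aln[, hap := ifelse(grepl("XH:Z:", tags),
                      sub(".*XH:Z:([^\t]+).*", "\\1", tags), NA_character_)]
  cg <- parse_cigar_ms(aln$cigar)
  aln[, `:=`(clip_left = cg$clip_left, mlen = cg$mlen,
             clip_right = cg$clip_right)]
  list(aln = aln, contig_lens = contig_lens)
}
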