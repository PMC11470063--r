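# Exact-seed toy read mapper. Unique reference k-mers anchor reads;
# collinear seed groups (same contig and diagonal) are accepted as
# full-length matches, and reads whose seeds fall into two groups are
# resolved into primary + supplementary split alignments by exact
# base-level extension — which localises the X-Y fusion junction at
# single-base resolution even though the junction sits inside a repeat
# (extension through the repeat is anchored by unique seeds beyond it).
# Reads whose every seed is repeated (e.g. drawn wholly from an L1-like
# copy or from the PAR, which is present verbatim on both sex chromosomes)
# are reported unmapped.

#' Build a unique-k-mer seed index over a reference
#'
#' Forward-strand k-mers occurring exactly once in the whole reference are
#' position-mapped; k-mers occurring more than once are recorded as
#' repeated and never used as anchors. Reverse-complement queries are
#' resolved to the minus strand at lookup time.
#'
#' @param genome A `toy_genome` or named character vector of contigs.
#' @param k Odd k-mer length in `[11, 51]`.
#' @return A `seed_index`: list with `k`, `table` (keyed data.table
#'   `kmer -> contig, pos`), `repeated` (character vector), `contig_lens`,
#'   `contigs` (the sequences, kept for extension).
#' @export
index_genome <- function(genome, k = 21L) {
  contigs <- if (inherits(genome, "toy_genome")) genome$contigs else genome
  if (k < 11L || k > 51L || k %% 2L == 0L)
    stop("k must be odd and in [11, 51]")
  lens <- contig_lengths(contigs)
  if (k > min(lens)) stop("k exceeds the shortest contig length")
  tabs <- lapply(names(contigs), function(cn) {
    n <- lens[[cn]] - k + 1L
    data.table::data.table(
      kmer = substring(contigs[[cn]], 1:n, k:(n + k - 1L)),
      contig = cn,
      pos = 0:(n - 1L)
    )
  })
  tab <- data.table::rbindlist(tabs)
  tab[, n_hits := .N, by = kmer]
  repeated <- unique(tab[n_hits > 1L, kmer])
  tab <- tab[n_hits == 1L][, n_hits := NULL]
  data.table::setkey(tab, kmer)
  structure(list(k = as.integer(k), table = tab, repeated = repeated,
                 contig_lens = lens, contigs = contigs),
            class = "seed_index")
}

#' Look up query k-mers in a seed index
#'
#' @param index A `seed_index`.
#' @param kmers Character vector of k-mers.
#' @return data.table with one row per query: `contig`, `pos`, `strand`
#'   (`+` for a forward hit, `-` when the reverse complement hits),
#'   `status` (`unique`, `repeated`, `absent`).
#' @export
lookup_kmers <- function(index, kmers) {
  hit <- index$table[data.table::data.table(kmer = kmers), on = "kmer"]
  out <- data.table::data.table(kmer = kmers, contig = hit$contig,
                                pos = hit$pos, strand = "+")
  miss <- is.na(out$pos)
  if (any(miss)) {
    rc <- revcomp(kmers[miss])
    hit2 <- index$table[data.table::data.table(kmer = rc), on = "kmer"]
    out$contig[miss] <- hit2$contig
    out$pos[miss] <- hit2$pos
    out$strand[miss] <- "-"
  }
  out[, status := ifelse(!is.na(pos), "unique",
                         ifelse(kmer %chin% index$repeated |
                                revcomp(kmer) %chin% index$repeated,
                                "repeated", "absent"))]
  out
}

#' @keywords internal
common_prefix_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

#' @keywords internal
rev_chars <- function(x) rawToChar(rev(charToRaw(x)))

# extend a seed anchor (read offset `aoff` 1-based maps to ref pos0 `apos`)
# to its maximal exact block; returns read span [a, b] (1-based) and ref
# start0
#' @keywords internal
extend_anchor <- function(read, contig_seq, aoff, apos) {
  L <- nchar(read)
  clen <- nchar(contig_seq)
  ext_r <- common_prefix_len(substr(read, aoff, L),
                             substr(contig_seq, apos + 1L, min(clen, apos + L - aoff + 1L)))
  lead_read <- if (aoff > 1L) rev_chars(substr(read, 1L, aoff - 1L)) else ""
  lead_ref <- if (apos > 0L)
    rev_chars(substr(contig_seq, max(1L, apos - aoff + 2L), apos)) else ""
  ext_l <- common_prefix_len(lead_read, lead_ref)
  list(a = aoff - ext_l, b = aoff + ext_r - 1L,
       ref_start = apos - ext_l)
}

#' Map a single read against a seed index
#'
#' Seeds are taken at a stride along the read and both orientations are
#' tried; the orientation with more unique hits wins. Collinear seed groups
#' define candidate blocks: one group yields a full-length match record
#' (mismatches tolerated inside, per seed voting); two groups on different
#' loci yield a primary plus a supplementary record whose soft clips
#' describe the split, with block bounds refined by exact extension.
#'
#' @param index A `seed_index`.
#' @param seq Read sequence.
#' @return data.table of alignment records (possibly a single unmapped
#'   record): `contig`, `pos`, `strand`, `cigar`, `mapped`, `is_supp`,
#'   `clip_left`, `mlen`, `clip_right`, `seq` (reference orientation).
#' @export
map_read <- function(index, seq) {
  k <- index$k
  L <- nchar(seq)
  unmapped <- data.table::data.table(
    contig = "*", pos = -1L, strand = "+", cigar = "*", mapped = FALSE,
    is_supp = FALSE, clip_left = 0L, mlen = 0L, clip_right = 0L, seq = seq)
  if (L < k) return(unmapped)
  stride <- if (L <= 500L) max(1L, (L - k) %/% 30L + 1L) else 250L
  offs <- unique(c(seq.int(1L, L - k + 1L, by = stride), L - k + 1L))

  hits_for <- function(s) {
    km <- substring(s, offs, offs + k - 1L)
    h <- index$table[data.table::data.table(kmer = km), on = "kmer"]
    ok <- !is.na(h$pos)
    data.table::data.table(off = offs[ok], contig = h$contig[ok],
                           pos = h$pos[ok])
  }
  fwd <- hits_for(seq)
  rc_seq <- revcomp(seq)
  rev_ <- hits_for(rc_seq)
  if (nrow(fwd) == 0L && nrow(rev_) == 0L) return(unmapped)
  minus <- nrow(rev_) > nrow(fwd)
  hits <- if (minus) rev_ else fwd
  work <- if (minus) rc_seq else seq
  strand <- if (minus) "-" else "+"

  hits[, diag := pos - (off - 1L)]
  grp <- hits[, .(votes = .N, aoff = off[1L], apos = pos[1L],
                  omin = min(off), omax = max(off)),
              by = .(contig, diag)]
  data.table::setorder(grp, -votes, contig, diag)
  g1 <- grp[1L]
  rec <- function(a, b, ref_start, contig, supp) {
    clip_l <- a - 1L; m <- b - a + 1L; clip_r <- L - b
    cigar <- paste0(if (clip_l) paste0(clip_l, "S"), m, "M",
                    if (clip_r) paste0(clip_r, "S"))
    data.table::data.table(contig = contig, pos = ref_start, strand = strand,
                           cigar = cigar, mapped = TRUE, is_supp = supp,
                           clip_left = clip_l, mlen = m, clip_right = clip_r,
                           seq = work)
  }
  if (nrow(grp) == 1L) {
    # single locus: mismatch-tolerant full-length match by seed voting
    return(rec(1L, L, g1$diag, g1$contig, FALSE))
  }
  # split candidate: refine the two best disjoint groups by exact extension
  e1 <- extend_anchor(work, index$contigs[[g1$contig]], g1$aoff, g1$apos)
  g2 <- NULL
  for (i in 2:nrow(grp)) {
    cand <- grp[i]
    if (cand$omin > e1$b || cand$omax < e1$a) { g2 <- cand; break }
  }
  if (is.null(g2)) {
    return(rec(e1$a, e1$b, e1$ref_start, g1$contig, FALSE))
  }
  e2 <- extend_anchor(work, index$contigs[[g2$contig]], g2$aoff, g2$apos)
  segs <- list(list(e = e1, contig = g1$contig), list(e = e2, contig = g2$contig))
  segs <- segs[order(vapply(segs, function(s) s$e$a, 1L))]
  left <- segs[[1L]]; right <- segs[[2L]]
  # trim chance overlap in read coordinates in favour of the left block
  ov <- left$e$b - right$e$a + 1L
  if (ov > 0L) {
    right$e$a <- right$e$a + ov
    right$e$ref_start <- right$e$ref_start + ov
  }
  r_left <- rec(left$e$a, left$e$b, left$e$ref_start, left$contig, FALSE)
  r_right <- rec(right$e$a, right$e$b, right$e$ref_start, right$contig, FALSE)
  lens <- c(r_left$mlen, r_right$mlen)
  primary <- which.max(lens)
  recs <- data.table::rbindlist(list(r_left, r_right))
  recs[, is_supp := seq_len(.N) != primary]
  recs
}

#' Map a full read set, returning a coordinate-sorted alignment table
#'
#' Short fixed-length reads are mapped in a single batched seed-join pass;
#' reads whose seeds disagree (split or error-perturbed) and long reads go
#' through [map_read()]. SEQ in the result is in reference orientation; the
#' haplotype of origin is carried in the `XH:Z:` tag column.
#'
#' @param index A `seed_index`.
#' @param rs A `read_set`.
#' @return List with `aln` (data.table with SAM-like columns) and
#'   `contig_lens`; pass to [write_sam()] for the file form.
#' @export
map_readset <- function(index, rs) {
  stopifnot(inherits(index, "seed_index"), inherits(rs, "read_set"))
  reads <- rs$reads
  qnames <- if (rs$type == "paired") paste0(reads$qname, "/", reads$mate)
            else reads$qname
  n <- nrow(reads)
  if (n == 0L) {
    aln <- data.table::data.table(qname = character(), flag = integer(),
      contig = character(), pos = integer(), cigar = character(),
      seq = character(), tags = character(), mapped = logical(),
      is_supp = logical(), clip_left = integer(), mlen = integer(),
      clip_right = integer())
    return(list(aln = aln, contig_lens = index$contig_lens))
  }
  k <- index$k
  lens <- nchar(reads$seq)

  pieces <- list()
  # batched seed pass for every read, whatever its length: per-read seed
  # offsets (dense stride for short reads, 250 bp for long ones), one big
  # keyed join per orientation, then diagonal-group voting; only reads with
  # several seed groups (splits, repeat straddlers) take the per-read path
  offs_list <- lapply(seq_len(n), function(i) {
    L <- lens[i]
    if (L < k) return(integer())
    stride <- if (L <= 500L) max(1L, (L - k) %/% 7L + 1L) else 250L
    unique(c(seq.int(1L, L - k + 1L, by = stride), L - k + 1L))
  })
  n_offs <- lengths(offs_list)
  idx_v <- rep.int(seq_len(n), n_offs)
  off_v <- unlist(offs_list)
  rc <- revcomp(reads$seq)
  gather <- function(seqs, strand) {
    h <- index$table[data.table::data.table(
      kmer = substring(seqs[idx_v], off_v, off_v + k - 1L)), on = "kmer"]
    keep <- !is.na(h$pos)
    data.table::data.table(idx = idx_v[keep], off = off_v[keep],
                           contig = h$contig[keep], pos = h$pos[keep],
                           strand = strand)
  }
  hits <- data.table::rbindlist(list(gather(reads$seq, "+"),
                                     gather(rc, "-")))
  hits[, diag := pos - (off - 1L)]
  grp <- hits[, .(votes = .N), by = .(idx, strand, contig, diag)]
  single <- grp[, .(g = .N), by = idx][g == 1L, idx]
  gg <- grp[idx %in% single]
  if (nrow(gg)) {
    L1 <- lens[gg$idx]
    pieces$batch <- data.table::data.table(
      idx = gg$idx, contig = gg$contig, pos = gg$diag, strand = gg$strand,
      cigar = paste0(L1, "M"), mapped = TRUE, is_supp = FALSE,
      clip_left = 0L, mlen = L1, clip_right = 0L,
      seq = ifelse(gg$strand == "-", rc[gg$idx], reads$seq[gg$idx]))
  }
  nohit <- setdiff(seq_len(n), unique(hits$idx))
  if (length(nohit)) {
    pieces$unmapped <- data.table::data.table(
      idx = nohit, contig = "*", pos = -1L, strand = "+", cigar = "*",
      mapped = FALSE, is_supp = FALSE, clip_left = 0L, mlen = 0L,
      clip_right = 0L, seq = reads$seq[nohit])
  }
  slow_idx <- setdiff(seq_len(n), c(single, nohit))
  if (length(slow_idx)) {
    slow_res <- lapply(slow_idx, function(i) {
      r <- map_read(index, reads$seq[i])
      r[, idx := i]
      r
    })
    pieces$slow <- data.table::rbindlist(slow_res, use.names = TRUE)
  }
  aln <- data.table::rbindlist(pieces, use.names = TRUE)
  aln[, qname := qnames[idx]]
  aln[, tags := paste0("XH:Z:", reads$hap[idx])]
  aln[, idx := NULL]
  aln[, flag := ifelse(!mapped, 4L, 0L) +
        ifelse(mapped & strand == "-", 16L, 0L) +
        ifelse(mapped & is_supp, 2048L, 0L)]
  data.table::setorder(aln, contig, pos, qname)
  list(aln = aln[, .(qname, flag, contig, pos, cigar, seq, tags, mapped,
                     is_supp, clip_left, mlen, clip_right, strand)],
       contig_lens = index$contig_lens)
}
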