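# Fusion-junction localisation from split alignments: each read whose
# primary and supplementary records sit on two contigs contributes one
# junction-evidence point; single-linkage clustering of the evidence gives
# consensus breakpoint calls, which are then annotated with any overlapping
# repeat family (the real X-Y boundary falls inside an L1 element).

#' Collect junction evidence from split alignments
#'
#' For every read with aligned segments on two contigs, the clip structure
#' identifies the left and right block in read orientation; the junction is
#' the last reference base of the left block and the first reference base
#' of the right block. When the two contigs are chrX and chrY the evidence
#' is reported in (X-side, Y-side) coordinates with orientation `"XY"`
#' (X block first in the read) or `"YX"`.
#'
#' @param sam SAM path or [map_readset()] result.
#' @return data.table: `qname`, `left_contig`, `left_end` (last aligned
#'   base, 0-based), `right_contig`, `right_start`, `x_side`, `y_side`,
#'   `orientation`, `clip_left`, `clip_right`.
#' @export
collect_split_reads <- function(sam) {
  res <- as_aln(sam)
  aln <- res$aln[mapped == TRUE]
  supp_q <- unique(aln[is_supp == TRUE, qname])
  orphan <- setdiff(supp_q, aln[is_supp == FALSE, qname])
  if (length(orphan))
    warning(length(orphan), " supplementary record(s) without a primary; skipped")
  empty <- data.table::data.table(
    qname = character(), left_contig = character(), left_end = integer(),
    right_contig = character(), right_start = integer(), x_side = integer(),
    y_side = integer(), orientation = character(), clip_left = integer(),
    clip_right = integer())
  keep <- setdiff(supp_q, orphan)
  if (!length(keep)) return(empty)
  out <- lapply(keep, function(q) {
    segs <- aln[qname == q]
    if (length(unique(segs$contig)) < 2L) return(NULL)
    segs <- segs[order(clip_left)]
    left <- segs[1L]; right <- segs[2L]
    xy <- c(left$contig, right$contig)
    ev <- data.table::data.table(
      qname = q, left_contig = left$contig,
      left_end = left$pos + left$mlen - 1L,
      right_contig = right$contig, right_start = right$pos,
      x_side = NA_integer_, y_side = NA_integer_,
      orientation = NA_character_,
      clip_left = right$clip_left, clip_right = left$clip_right)
    if (identical(xy, c("chrX", "chrY"))) {
      ev[, `:=`(x_side = left_end, y_side = right_start, orientation = "XY")]
    } else if (identical(xy, c("chrY", "chrX"))) {
      ev[, `:=`(x_side = right_start, y_side = left_end, orientation = "YX")]
    }
    ev
  })
  out <- data.table::rbindlist(Filter(Negate(is.null), out))
  if (!nrow(out)) empty else out
}

#' Cluster junction evidence into consensus breakpoint calls
#'
#' Single-linkage clustering in (X-side, Y-side) coordinate space with the
#' given radius, separately per orientation; the consensus is the per-side
#' median, and clusters with fewer than `min_support` reads are dropped.
#'
#' @param evidence Output of [collect_split_reads()] (rows with defined
#'   X/Y sides are used).
#' @param radius Single-linkage merge radius (bp).
#' @param min_support Minimum evidence reads per call.
#' @return data.table of calls: `x_consensus`, `y_consensus`, `support`,
#'   `spread_x`, `spread_y`, `orientation`, `repeat_family`.
#' @export
cluster_junctions <- function(evidence, radius = 50L, min_support = 3L) {
  empty <- data.table::data.table(
    x_consensus = numeric(), y_consensus = numeric(), support = integer(),
    spread_x = numeric(), spread_y = numeric(), orientation = character(),
    repeat_family = character())
  ev <- evidence[!is.na(x_side) & !is.na(y_side)]
  if (!nrow(ev)) return(empty)
  out <- list()
  for (ori in unique(ev$orientation)) {
    e <- ev[orientation == ori]
    cl <- if (nrow(e) == 1L) 1L else {
      d <- dist(cbind(e$x_side, e$y_side), method = "maximum")
      cutree(hclust(d, method = "single"), h = radius)
    }
    for (ci in unique(cl)) {
      sub <- e[cl == ci]
      if (nrow(sub) < min_support) next
      out[[length(out) + 1L]] <- data.table::data.table(
        x_consensus = stats::median(sub$x_side),
        y_consensus = stats::median(sub$y_side),
        support = nrow(sub),
        spread_x = if (nrow(sub) > 1L) sd(sub$x_side) else 0,
        spread_y = if (nrow(sub) > 1L) sd(sub$y_side) else 0,
        orientation = ori, repeat_family = NA_character_)
    }
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)
}

#' Annotate breakpoint calls with overlapping repeat families
#'
#' A call's repeat family is recorded when its Y-side consensus, extended by
#' `radius`, intersects a repeat interval.
#'
#' @param calls Output of [cluster_junctions()].
#' @param repeats A repeats data.table (`family`/`name`, `contig`, `start`,
#'   `end`) or a BED path (chrY intervals, name = family).
#' @param radius Extension around the consensus (bp).
#' @return The calls with `repeat_family` filled in where overlapping.
#' @export
annotate_repeats <- function(calls, repeats, radius = 50L) {
  if (is.character(repeats)) {
    repeats <- read_bed(repeats)
    data.table::setnames(repeats, "name", "family")
  }
  calls <- data.table::copy(calls)
  reps <- repeats[repeats$contig == "chrY"]
  if (!nrow(reps) || !nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    y <- calls$y_consensus[i]
    hit <- reps[reps$start < y + radius + 1 & reps$end > y - radius]
    if (nrow(hit)) calls$repeat_family[i] <- hit$family[1L]
  }
  calls
}
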