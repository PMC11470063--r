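# Windowed read-depth coverage, autosomal-median normalisation and
# threshold segmentation of elevated windows into duplication calls.
# Each mapped primary record contributes one count to the window holding
# its alignment midpoint; normalising every window by the median autosomal
# window count puts diploid sequence at 1.0 and a single-copy male chrX at
# ~0.5, so a Y-linked extra copy of an X segment lifts the affected chrX
# windows from 0.5 towards 1.0.

#' @keywords internal
as_aln <- function(x) {
  if (is.character(x) && length(x) == 1L) read_sam(x)
  else if (is.list(x) && !is.null(x$aln)) x
  else stop("expected a SAM path or a map_readset()/read_sam() result")
}

#' Compute a per-window coverage track from alignments
#'
#' @param sam A SAM path or the result of [map_readset()] / [read_sam()].
#' @param window Window size in bp (>= 100).
#' @return A `coverage_track`: list with `window`, `counts` (named list of
#'   integer vectors, one per contig; `ceiling(len / window)` windows),
#'   `contig_lens`, `total_reads`.
#' @export
window_coverage <- function(sam, window = 1000L) {
  if (window < 100L) stop("window must be >= 100 bp")
  res <- as_aln(sam)
  aln <- res$aln[mapped == TRUE & is_supp == FALSE]
  lens <- res$contig_lens
  mids <- aln$pos + aln$mlen %/% 2L
  win <- mids %/% as.integer(window)
  counts <- lapply(names(lens), function(cn) {
    nw <- as.integer(ceiling(lens[[cn]] / window))
    sel <- aln$contig == cn
    tabulate(win[sel] + 1L, nbins = nw)
  })
  names(counts) <- names(lens)
  structure(list(window = as.integer(window), counts = counts,
                 contig_lens = lens, total_reads = nrow(aln)),
            class = "coverage_track")
}

#' @keywords internal
full_windows <- function(track, cn) {
  # indices of windows fully contained in the contig (drops a short tail)
  nw <- length(track$counts[[cn]])
  full <- track$contig_lens[[cn]] %/% track$window
  seq_len(min(nw, full))
}

#' Normalise a coverage track to the median autosomal window count
#'
#' @param track A `coverage_track`.
#' @param autosomes Character vector of autosomal contig names.
#' @return A `normalized_track`: the track plus `norm_constant` and
#'   `values` (per-contig numeric vectors; autosomal median = 1 by
#'   construction).
#' @export
normalize_to_autosomal_median <- function(track, autosomes = "chrA") {
  stopifnot(inherits(track, "coverage_track"))
  auto <- unlist(lapply(intersect(autosomes, names(track$counts)),
                        function(cn) track$counts[[cn]][full_windows(track, cn)]))
  if (sum(auto > 0) < 10L)
    stop("need at least 10 autosomal windows with nonzero counts")
  med <- stats::median(auto)
  if (med == 0) stop("median autosomal window count is zero")
  values <- lapply(track$counts, function(v) v / med)
  structure(c(unclass(track),
              list(norm_constant = med, values = values,
                   autosomes = autosomes)),
            class = c("normalized_track", "coverage_track"))
}

#' Segment elevated windows into duplication calls
#'
#' Windows whose normalised value exceeds the midpoint between the contig's
#' baseline copy state and one extra copy (`baseline + 0.25`) are candidate
#' duplication windows; candidate runs are merged across at most `max_gap`
#' sub-threshold windows and reported when they span at least `min_windows`
#' windows.
#'
#' @param normtrack A `normalized_track`.
#' @param baseline Named numeric vector of per-contig baselines (0.5 for a
#'   single-copy contig in a male, 1.0 for diploid).
#' @param min_windows Minimum run length in windows.
#' @param max_gap Maximum number of interior sub-threshold windows bridged.
#' @param exclude Optional data.table (`contig`, `start`, `end`, 0-based
#'   half-open) of intervals whose windows are never candidates (e.g. the
#'   PAR, which is diploid in males).
#' @return data.table of calls: `contig`, `start`, `end` (window-aligned,
#'   0-based half-open), `n_windows`, `mean_inside`, `baseline`.
#' @export
call_duplication <- function(normtrack, baseline, min_windows = 3L,
                             max_gap = 1L, exclude = NULL) {
  stopifnot(inherits(normtrack, "normalized_track"))
  w <- normtrack$window
  out <- list()
  for (cn in names(baseline)) {
    if (!cn %in% names(normtrack$values)) next
    v <- normtrack$values[[cn]]
    thr <- baseline[[cn]] + 0.25
    cand <- which(v > thr)
    if (!is.null(exclude)) {
      ex <- exclude[contig == cn]
      if (nrow(ex)) {
        bad <- unlist(lapply(seq_len(nrow(ex)), function(i)
          seq.int(ex$start[i] %/% w, (ex$end[i] - 1L) %/% w) + 1L))
        cand <- setdiff(cand, bad)
      }
    }
    if (!length(cand)) next
    brk <- c(0L, which(diff(cand) > max_gap + 1L), length(cand))
    for (j in seq_len(length(brk) - 1L)) {
      run <- cand[(brk[j] + 1L):brk[j + 1L]]
      span <- run[length(run)] - run[1L] + 1L
      if (span < min_windows) next
      s <- (run[1L] - 1L) * w
      e <- min(run[length(run)] * w, normtrack$contig_lens[[cn]])
      inside <- v[run[1L]:run[length(run)]]
      out[[length(out) + 1L]] <- data.table::data.table(
        contig = cn, start = s, end = e, n_windows = span,
        mean_inside = mean(inside), baseline = baseline[[cn]])
    }
  }
  if (!length(out)) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), n_windows = integer(),
                                  mean_inside = numeric(),
                                  baseline = numeric()))
  }
  data.table::rbindlist(out)
}

#' Per-window ratio of two normalised coverage tracks
#'
#' Both tracks are re-normalised after adding a 0.5-read pseudocount to
#' every raw window count, keeping ratios finite in empty windows.
#'
#' @param track_a,track_b `coverage_track`s with identical windowing.
#' @param autosomes Autosome names for re-normalisation.
#' @return List of per-contig numeric ratio vectors (a / b).
#' @export
genotype_coverage_ratio <- function(track_a, track_b, autosomes = "chrA") {
  if (track_a$window != track_b$window ||
      !identical(lapply(track_a$counts, length),
                 lapply(track_b$counts, length)))
    stop("tracks have mismatched windowing")
  renorm <- function(tr) {
    auto <- unlist(lapply(intersect(autosomes, names(tr$counts)),
                          function(cn) tr$counts[[cn]][full_windows(tr, cn)]))
    med <- stats::median(auto + 0.5)
    lapply(tr$counts, function(v) (v + 0.5) / med)
  }
  va <- renorm(track_a); vb <- renorm(track_b)
  setNames(lapply(names(va), function(cn) va[[cn]] / vb[[cn]]), names(va))
}

#' Write a normalised track as bedGraph
#' @param normtrack A `normalized_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track_bedgraph <- function(normtrack, path) {
  w <- normtrack$window
  dt <- data.table::rbindlist(lapply(names(normtrack$values), function(cn) {
    v <- normtrack$values[[cn]]
    data.table::data.table(
      contig = cn, start = (seq_along(v) - 1L) * w,
      end = pmin(seq_along(v) * w, normtrack$contig_lens[[cn]]), value = v)
  }))
  write_bedgraph(dt$contig, dt$start, dt$end, dt$value, path)
}
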