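# Haplotype-resolved coverage in an F1 cross. Reads are assigned to the
# parental strains via the diagnostic SNP alleles they cover (B6 = paternal,
# CAST = maternal in the published cross), binned into windows, and
# summarised as the bounded paternal fraction B6/(B6+CAST). A maternally
# inherited single-copy X shows fraction ~0; a region where a paternal B6
# copy coexists with the maternal CAST copy shows ~0.5 — the step-function
# signature of the Y-fused duplication.

#' Mask SNP positions in a genome with N
#'
#' @param genome A `toy_genome` or named character vector of contigs.
#' @param variants A `strain_variants` table.
#' @return Named character vector of masked contigs.
#' @export
mask_reference <- function(genome, variants) {
  contigs <- if (inherits(genome, "toy_genome")) genome$contigs else genome
  bad <- setdiff(unique(variants$contig), names(contigs))
  if (length(bad)) stop("variants on unknown contig: ", paste(bad, collapse = ","))
  for (cn in unique(variants$contig)) {
    vv <- variants[contig == cn]
    if (any(vv$pos < 0L | vv$pos >= nchar(contigs[[cn]])))
      stop("variant outside contig bounds on ", cn)
    r <- charToRaw(contigs[[cn]])
    r[vv$pos + 1L] <- charToRaw("N")
    contigs[[cn]] <- rawToChar(r)
  }
  contigs
}

#' @keywords internal
assign_labels <- function(aln, variants, paternal_strain = "B6") {
  # vectorised SNP-based parental assignment of aligned records
  n <- nrow(aln)
  n_b6 <- integer(n); n_cast <- integer(n)
  for (cn in unique(aln$contig)) {
    vv <- variants[contig == cn]
    if (!nrow(vv)) next
    sel <- which(aln$contig == cn)
    pos <- aln$pos[sel]; mlen <- aln$mlen[sel]
    i1 <- findInterval(pos - 0.5, vv$pos) + 1L
    i2 <- findInterval(pos + mlen - 0.5, vv$pos)
    has <- i1 <= i2
    if (!any(has)) next
    reps <- pmax(0L, i2 - i1 + 1L)
    rid <- rep(sel, reps)
    sidx <- sequence(reps[has], from = i1[has])
    p <- vv$pos[sidx]
    off <- aln$clip_left[rid] + (p - aln$pos[rid]) + 1L
    base <- substr(aln$seq[rid], off, off)
    b6hit <- base == vv$b6[sidx]
    casthit <- base == vv$cast[sidx]
    tb <- rowsum(cbind(b6 = as.integer(b6hit), cast = as.integer(casthit)),
                 group = rid)
    ids <- as.integer(rownames(tb))
    n_b6[ids] <- tb[, "b6"]
    n_cast[ids] <- tb[, "cast"]
  }
  lab <- rep("unassigned", n)
  pat <- if (paternal_strain == "B6") n_b6 else n_cast
  mat <- if (paternal_strain == "B6") n_cast else n_b6
  lab[pat > 0L & mat == 0L] <- "paternal"
  lab[mat > 0L & pat == 0L] <- "maternal"
  lab[pat > 0L & mat > 0L] <- "conflicting"
  lab
}

#' Assign a single aligned read to a parental haplotype
#'
#' Collects the read bases at SNP positions covered by the aligned block:
#' all informative bases from one strain give that parent; a mixture is
#' `conflicting`; no informative base is `unassigned`. Bases matching
#' neither allele (sequencing errors) are ignored.
#'
#' @param alignment One-row alignment (as produced by [map_readset()]):
#'   needs `contig`, `pos`, `mlen`, `clip_left`, `seq`.
#' @param variants A `strain_variants` table.
#' @param paternal_strain Strain contributed by the father (default B6).
#' @return One of `"paternal"`, `"maternal"`, `"unassigned"`,
#'   `"conflicting"`.
#' @export
assign_read <- function(alignment, variants, paternal_strain = "B6") {
  assign_labels(data.table::as.data.table(alignment)[1L], variants,
                paternal_strain)
}

#' Haplotype-resolved windowed coverage
#'
#' @param sam SAM path or [map_readset()] result.
#' @param variants A `strain_variants` table.
#' @param window Window size (bp).
#' @param min_informative Minimum paternal+maternal reads per window for the
#'   paternal fraction to be defined.
#' @param paternal_strain Strain contributed by the father.
#' @return A `haplotype_tracks`: list with `window`, per-contig data.tables
#'   (`paternal`, `maternal`, `unassigned`, `conflicting`, `total`,
#'   `paternal_fraction`), and `contig_lens`.
#' @export
haplotype_window_coverage <- function(sam, variants, window = 1000L,
                                      min_informative = 5L,
                                      paternal_strain = "B6") {
  if (window < 100L) stop("window must be >= 100 bp")
  res <- as_aln(sam)
  aln <- res$aln[mapped == TRUE & is_supp == FALSE]
  lens <- res$contig_lens
  lab <- assign_labels(aln, variants, paternal_strain)
  mids <- aln$pos + aln$mlen %/% 2L
  win <- mids %/% as.integer(window)
  tracks <- lapply(names(lens), function(cn) {
    nw <- as.integer(ceiling(lens[[cn]] / window))
    sel <- aln$contig == cn
    tab <- function(which_lab)
      tabulate(win[sel & lab == which_lab] + 1L, nbins = nw)
    p <- tab("paternal"); m <- tab("maternal")
    u <- tab("unassigned"); cf <- tab("conflicting")
    fr <- ifelse(p + m >= min_informative, p / (p + m), NA_real_)
    data.table::data.table(window_idx = seq_len(nw) - 1L, paternal = p,
                           maternal = m, unassigned = u, conflicting = cf,
                           total = p + m + u + cf, paternal_fraction = fr)
  })
  names(tracks) <- names(lens)
  structure(list(window = as.integer(window), tracks = tracks,
                 contig_lens = lens, min_informative = min_informative),
            class = "haplotype_tracks")
}

#' Infer the parental origin of a duplicated interval
#'
#' Compares the mean paternal fraction of informative windows inside the
#' interval with the rest of the contig (excluding the interval and any
#' `exclude` regions such as the PAR). A paternal duplication on a
#' maternally inherited X shows fraction ~0.5 inside and ~0 outside; a
#' plain maternal X-linked duplication would show inside ~ outside.
#'
#' @param tracks A `haplotype_tracks`.
#' @param interval 0-based half-open interval `c(start, end)`.
#' @param contig Contig of the interval (default `"chrX"`).
#' @param inside_min Minimum mean inside fraction for a paternal verdict.
#' @param outside_max Maximum mean outside fraction for a paternal verdict.
#' @param exclude Optional data.table of intervals to drop from the outside
#'   summary.
#' @return An `origin_call`: list with `verdict`
#'   (`"paternal-duplication"`, `"maternal-duplication"` or
#'   `"inconclusive"`), `mean_inside`, `mean_outside`, `n_inside`,
#'   `n_outside`, `reason`.
#' @export
infer_parental_origin <- function(tracks, interval, contig = "chrX",
                                  inside_min = 0.3, outside_max = 0.1,
                                  exclude = NULL) {
  stopifnot(inherits(tracks, "haplotype_tracks"))
  tr <- tracks$tracks[[contig]]
  if (is.null(tr)) stop("no track for contig ", contig)
  w <- tracks$window
  # prefer windows fully contained in the interval (partial edge windows
  # dilute the fraction); fall back to overlapping windows for very short
  # intervals
  lo <- as.integer(ceiling(interval[1] / w)); hi <- interval[2] %/% w - 1L
  wi <- if (lo <= hi) seq.int(lo, hi)
        else seq.int(interval[1] %/% w, (interval[2] - 1L) %/% w)
  inside <- tr$paternal_fraction[tr$window_idx %in% wi]
  out_idx <- setdiff(tr$window_idx, wi)
  if (!is.null(exclude)) {
    ex <- exclude[exclude$contig == contig]
    if (nrow(ex)) {
      bad <- unlist(lapply(seq_len(nrow(ex)), function(i)
        seq.int(ex$start[i] %/% w, (ex$end[i] - 1L) %/% w)))
      out_idx <- setdiff(out_idx, bad)
    }
  }
  outside <- tr$paternal_fraction[tr$window_idx %in% out_idx]
  mi <- mean(inside, na.rm = TRUE); mo <- mean(outside, na.rm = TRUE)
  ni <- sum(!is.na(inside)); no <- sum(!is.na(outside))
  verdict <- "inconclusive"; reason <- ""
  if (ni == 0L) {
    verdict <- "inconclusive"; reason <- "no informative windows inside"
    mi <- NA_real_
  } else if (!is.na(mi) && !is.na(mo) && mi >= inside_min && mo <= outside_max) {
    verdict <- "paternal-duplication"
  } else if (!is.na(mi) && !is.na(mo) && mi <= (1 - inside_min) &&
             mo >= (1 - outside_max)) {
    verdict <- "maternal-duplication"
  } else {
    reason <- "inside/outside fractions do not separate"
  }
  structure(list(verdict = verdict, mean_inside = mi, mean_outside = mo,
                 n_inside = ni, n_outside = no, interval = interval,
                 contig = contig, reason = reason),
            class = "origin_call")
}
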