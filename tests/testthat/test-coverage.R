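# build a minimal alignment-result object from explicit midpoint positions
aln_from_positions <- function(pos, contig, contig_lens, mlen = 100L) {
  aln <- data.table::data.table(
    qname = sprintf("r%04d", seq_along(pos)), flag = 0L, contig = contig,
    pos = as.integer(pos), cigar = paste0(mlen, "M"),
    seq = strrep("A", mlen), tags = "", mapped = TRUE, is_supp = FALSE,
    clip_left = 0L, mlen = mlen, clip_right = 0L, strand = "+")
  list(aln = aln, contig_lens = contig_lens)
}

test_that("window counts follow alignment midpoints and conserve totals", {
  lens <- c(c1 = 5000L)
  # 10 reads whose midpoints fall in [0, 1000)
  a <- aln_from_positions(seq(0L, 900L, by = 100L), "c1", lens)
  tr <- window_coverage(a, window = 1000L)
  expect_equal(tr$counts$c1, c(10L, 0L, 0L, 0L, 0L))
  expect_equal(sum(unlist(tr$counts)), nrow(a$aln))
  expect_equal(length(tr$counts$c1), ceiling(5000 / 1000))
  # a read at 950 with mlen 100 has midpoint 1000 -> second window
  a2 <- aln_from_positions(950L, "c1", lens)
  expect_equal(window_coverage(a2, window = 1000L)$counts$c1[2], 1L)
  # supplementary and unmapped records are excluded
  a3 <- aln_from_positions(c(0L, 0L), "c1", lens)
  a3$aln[2, `:=`(flag = 2048L, is_supp = TRUE)]
  expect_equal(sum(window_coverage(a3, 1000L)$counts$c1), 1L)
  # empty alignment -> all-zero track; malformed window rejected
  a0 <- a; a0$aln <- a$aln[0]
  expect_true(all(unlist(window_coverage(a0, 1000L)$counts) == 0L))
  expect_error(window_coverage(a, window = 50L), ">= 100")
})

test_that("SAM parse errors carry the line number", {
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:c1\tLN:1000",
               "r1\t0\tc1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
               "broken\tline"), p)
  expect_error(read_sam(p), "line 4")
})

test_that("autosomal-median normalisation fixes diploid sequence at 1.0", {
  lens <- c(chrA = 20000L, chrX = 10000L)
  # 20 reads per chrA window, 10 per chrX window (male X at half coverage)
  pos_a <- rep(seq(0L, 19000L, by = 1000L), each = 20) + 500L
  pos_x <- rep(seq(0L, 9000L, by = 1000L), each = 10) + 500L
  a <- aln_from_positions(c(pos_a, pos_x),
                          rep(c("chrA", "chrX"), c(length(pos_a), length(pos_x))),
                          lens)
  nt <- normalize_to_autosomal_median(window_coverage(a, 1000L))
  expect_true(all(nt$values$chrA == 1.0))
  expect_true(all(nt$values$chrX == 0.5))
  expect_equal(nt$norm_constant, 20)
  # degenerate input: zero autosomal coverage
  ax <- aln_from_positions(pos_x, "chrX", lens)
  expect_error(normalize_to_autosomal_median(window_coverage(ax, 1000L)),
               "autosomal")
})

test_that("simulated male coverage shows the 0.5 chrX baseline and ~1.0 inside the duplication", {
  g <- fx_genome()
  nt <- normalize_to_autosomal_median(window_coverage(fx_carrier_aln(),
                                                      window = 1000L))
  di <- g$duplication_interval
  par_x <- g$par_interval$chrX
  w <- 1000L
  dup_w <- seq(di[1] %/% w + 2L, di[2] %/% w)      # fully-inside windows
  # outside windows: skip the duplication (incl. its partial edge window)
  # and the repeat copy around 60 kb, whose reads are unmappable
  x_out <- setdiff(seq_len(par_x[1] %/% w), c(seq(di[1] %/% w + 1L,
                                                  di[2] %/% w), 60:62))
  expect_equal(mean(nt$values$chrX[x_out]), 0.5, tolerance = 0.05)
  # the duplicated block sits near 1.0 (one maternal X copy plus the
  # Y-linked B6 copy mapping back); junction-edge losses and window noise
  # allow a little slack
  m_dup <- mean(nt$values$chrX[dup_w])
  expect_gt(m_dup, 0.85); expect_lt(m_dup, 1.1)
  expect_true(all(nt$values$chrX[dup_w] > 0.75))   # above the call threshold
  expect_equal(mean(nt$values$chrA[1:50]), 1.0, tolerance = 0.05)
})

test_that("duplication calling segments constructed tracks exactly", {
  mk_norm <- function(v, contig = "chrX", window = 100L) {
    structure(list(window = window,
                   counts = setNames(list(as.integer(v * 100)), contig),
                   contig_lens = setNames(length(v) * window, contig),
                   total_reads = sum(v * 100), norm_constant = 100,
                   values = setNames(list(v), contig), autosomes = "chrA"),
              class = c("normalized_track", "coverage_track"))
  }
  # flat track -> no calls
  flat <- mk_norm(rep(0.5, 100))
  expect_equal(nrow(call_duplication(flat, c(chrX = 0.5))), 0L)
  # a 32-window block at 1.0 on the 0.5 baseline -> exactly that block
  v <- rep(0.5, 100); v[21:52] <- 1.0
  call <- call_duplication(mk_norm(v), c(chrX = 0.5))
  expect_equal(nrow(call), 1L)
  expect_equal(call$start, 20L * 100L)
  expect_equal(call$end, 52L * 100L)
  expect_equal(call$n_windows, 32L)
  # one interior dip is bridged at max_gap = 1, split at max_gap = 0
  v2 <- v; v2[35] <- 0.5
  expect_equal(nrow(call_duplication(mk_norm(v2), c(chrX = 0.5),
                                     max_gap = 1L)), 1L)
  expect_equal(nrow(call_duplication(mk_norm(v2), c(chrX = 0.5),
                                     max_gap = 0L)), 2L)
  # runs shorter than min_windows are dropped
  v3 <- rep(0.5, 100); v3[10:11] <- 1.0
  expect_equal(nrow(call_duplication(mk_norm(v3), c(chrX = 0.5),
                                     min_windows = 3L)), 0L)
  # excluded intervals (e.g. PAR) are never candidates
  v4 <- rep(0.5, 100); v4[91:100] <- 1.0
  ex <- data.table::data.table(contig = "chrX", start = 9000L, end = 10000L)
  expect_equal(nrow(call_duplication(mk_norm(v4), c(chrX = 0.5),
                                     exclude = ex)), 0L)
})

test_that("coverage ratio uses pseudocounts and identifies the carrier duplication", {
  ta <- window_coverage(fx_carrier_aln(), window = 1000L)
  # identical tracks give ratio 1 everywhere
  r_self <- genotype_coverage_ratio(ta, ta)
  expect_true(all(abs(unlist(r_self) - 1) < 1e-12))
  tb <- window_coverage(fx_noncarrier_aln(), window = 1000L)
  r <- genotype_coverage_ratio(ta, tb)
  expect_true(all(is.finite(unlist(r))))   # pseudocount keeps ratios finite
  g <- fx_genome()
  di <- g$duplication_interval
  dup_w <- seq(di[1] %/% 1000L + 1L, di[2] %/% 1000L)
  expect_equal(mean(r$chrX[dup_w]), 2.0, tolerance = 0.15)
  out_w <- 1:50
  expect_equal(mean(r$chrX[out_w]), 1.0, tolerance = 0.1)
  # mismatched windowing errors
  expect_error(genotype_coverage_ratio(ta, window_coverage(fx_noncarrier_aln(),
                                                           window = 500L)),
               "mismatch")
})

test_that("bedGraph export round-trips through rtracklayer", {
  nt <- normalize_to_autosomal_median(window_coverage(fx_carrier_aln(),
                                                      window = 1000L))
  p <- tempfile(fileext = ".bedGraph")
  write_track_bedgraph(nt, p)
  gr <- rtracklayer::import(p, format = "bedGraph")
  expect_equal(length(gr), sum(lengths(nt$values)))
  expect_equal(gr$score[1], nt$values$chrA[1])
})
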