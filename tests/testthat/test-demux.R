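wl_fixture <- function(seed = 5L) {
  dir <- tempfile("wl")
  setup <- make_barcode_setup(dir, n_per_list = 8L, n_samples = 4L,
                              frac_lig9 = 0.25, seed = seed)
  list(setup = setup,
       wl = load_whitelists(setup$files, setup$samplesheet))
}

test_that("whitelist loading pads 9-nt ligation barcodes and validates input", {
  fx <- wl_fixture()
  wl <- fx$wl
  expect_true(all(nchar(wl$ligation) == 10L))
  for (b9 in wl$lig9) expect_true(paste0(b9, "G") %in% wl$ligation)

  d <- tempfile("badwl"); dir.create(d)
  writeLines(c("ACGTACGTAC", "ACGTACGTAC"), file.path(d, "dup.txt"))
  writeLines("ACGTACGTA", file.path(d, "short_rt.txt"))
  writeLines("ACGTNCGTAC", file.path(d, "bad_base.txt"))
  good <- fx$setup$files
  expect_warning(
    load_whitelists(list(p7 = file.path(d, "dup.txt"), p5 = good$p5,
                         ligation = good$ligation, rt = good$rt),
                    fx$setup$samplesheet),
    "duplicate")
  expect_error(
    load_whitelists(list(p7 = good$p7, p5 = good$p5, ligation = good$ligation,
                         rt = file.path(d, "short_rt.txt")),
                    fx$setup$samplesheet),
    "length")
  expect_error(
    load_whitelists(list(p7 = file.path(d, "bad_base.txt"), p5 = good$p5,
                         ligation = good$ligation, rt = good$rt),
                    fx$setup$samplesheet),
    "malformed")
})

test_that("barcode matching implements exact / ham1 / ambiguous / none", {
  wl <- c("AAAAAAAAAA", "CCAAAAAAAA", "GGGGGGGGGG")
  expect_equal(match_barcode("AAAAAAAAAA", wl)$outcome, "exact")
  m <- match_barcode("AAAAAAAAAT", wl)
  expect_equal(m$outcome, "ham1")
  expect_equal(m$barcode, "AAAAAAAAAA")
  # distance 1 from two entries (AAAA... and CCAA...) -> ambiguous
  expect_equal(match_barcode("CAAAAAAAAA", wl)$outcome, "ambiguous")
  expect_equal(match_barcode("TTTTTAAAAA", wl)$outcome, "none")
  expect_error(match_barcode("AAAA", wl), "length")

  # exhaustive check against a brute-force hamming oracle on a small space
  wl4 <- c("AAAAAAAAAA", "TTTTTTTTTT")
  ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  set.seed(1)
  for (i in 1:50) {
    obs <- paste(sample(c("A", "T"), 10, replace = TRUE), collapse = "")
    d <- vapply(wl4, ham, 1L, a = obs)
    want <- if (min(d) == 0) "exact"
            else if (sum(d == 1L) == 1L) "ham1"
            else if (sum(d == 1L) > 1L) "ambiguous" else "none"
    expect_equal(match_barcode(obs, wl4)$outcome, want)
  }
})

test_that("read pairs demultiplex at fixed offsets with 48-nt rewrites", {
  fx <- wl_fixture()
  wl <- fx$wl; sheet <- fx$setup$sheet
  row10 <- sheet[nchar(sheet$ligation) == 10L][1L]
  umi <- "ACGTACGT"
  r1 <- paste0(row10$p7, row10$p5, row10$ligation, row10$rt, umi)

  rec <- demux_readpair(r1, strrep("A", 50), wl)
  expect_equal(unname(rec$sample), row10$sample)
  expect_true(all(rec$outcomes == "exact"))
  expect_equal(nchar(rec$rewritten_r1), 48L)
  expect_equal(rec$rewritten_r1, r1)

  # one mismatch in p7 is rescued and rewritten to the whitelist sequence
  r1_mm <- r1
  substr(r1_mm, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(r1, 1, 1))[1]
  rec_mm <- demux_readpair(r1_mm, strrep("A", 50), wl)
  expect_equal(unname(rec_mm$sample), row10$sample)
  expect_equal(rec_mm$outcomes[["p7"]], "ham1")
  expect_equal(rec_mm$rewritten_r1, r1)

  # two mismatches in RT cannot be rescued; the reason names RT
  r1_rt <- r1
  for (p in c(31L, 33L))
    substr(r1_rt, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r1, p, p))[1]
  rec_rt <- demux_readpair(r1_rt, strrep("A", 50), wl)
  expect_true(is.na(rec_rt$sample))
  expect_match(rec_rt$reason, "rt")

  # a 9-nt ligation read (R1 47 nt) is assigned via the padded alias
  row9 <- fx$setup$sheet[nchar(fx$setup$sheet$ligation) == 9L]
  if (nrow(row9) == 0L) {
    sheet9 <- data.table::copy(sheet)
    sheet9$ligation[1] <- wl$lig9[1]
    wl9 <- wl
    wl9$lookup <- setNames(sheet9$sample,
                           paste(sheet9$p7, sheet9$p5,
                                 ifelse(nchar(sheet9$ligation) == 9L,
                                        paste0(sheet9$ligation, "G"),
                                        sheet9$ligation),
                                 sheet9$rt, sep = "|"))
    row9 <- sheet9[1L]; wl_use <- wl9
  } else {
    row9 <- row9[1L]; wl_use <- wl
  }
  r1_47 <- paste0(row9$p7, row9$p5, row9$ligation, row9$rt, umi)
  expect_equal(nchar(r1_47), 47L)
  rec9 <- demux_readpair(r1_47, strrep("A", 50), wl_use)
  expect_equal(unname(rec9$sample), row9$sample)
  expect_equal(nchar(rec9$rewritten_r1), 48L)
  expect_equal(substr(rec9$rewritten_r1, 21, 30), paste0(row9$ligation, "G"))

  # truncated R1
  rec_tr <- demux_readpair(substr(r1, 1, 40), strrep("A", 50), wl)
  expect_equal(rec_tr$reason, "truncated")
})

test_that("run_demux partitions reads and recovers truth exactly", {
  fx <- wl_fixture(seed = 6L)
  dir <- tempfile("sci")
  sim <- simulate_scirnaseq_reads(fx$setup, dir, n_reads = 800L,
                                  frac_1mm = 0.2, frac_2mm = 0.1, seed = 8L)
  out <- run_demux(sim$r1, sim$r2, fx$wl, file.path(dir, "demux"))
  st <- out$stats
  expect_equal(st$assigned + st$discarded, st$total)
  expect_equal(st$total, 800L)

  joined <- merge(out$assignments, sim$truth, by = "qname")
  # reads with <= 1 mismatch per barcode: 100% truth agreement
  clean <- joined[joined$should_discard == FALSE, ]
  expect_equal(clean$sample.x, clean$sample.y)
  # 2-mismatch injections: 100% discarded
  dirty <- joined[joined$should_discard == TRUE, ]
  expect_true(all(is.na(dirty$sample.x)))
  expect_equal(st$discarded, sum(sim$truth$should_discard))
  # every rewritten R1 is 48 nt
  expect_true(all(nchar(joined$rewritten[!is.na(joined$sample.x)]) == 48L))

  # per-sample files contain only their own reads, and the partition is
  # complete
  fq_ids <- function(p) sub("^@", "", grep("^@", readLines(p), value = TRUE))
  all_ids <- character()
  for (s in unique(stats::na.omit(joined$sample.x))) {
    ids <- fq_ids(file.path(dir, "demux", paste0(s, "_R1.fastq")))
    expect_true(all(sim$truth$sample[match(ids, sim$truth$qname)] == s))
    all_ids <- c(all_ids, ids)
  }
  disc <- fq_ids(file.path(dir, "demux", "discarded_R1.fastq"))
  expect_setequal(c(all_ids, disc), sim$truth$qname)
})

test_that("error-free demultiplexing assigns everything; empty input zeroes out", {
  fx <- wl_fixture(seed = 7L)
  dir <- tempfile("sci0")
  sim <- simulate_scirnaseq_reads(fx$setup, dir, n_reads = 300L,
                                  frac_1mm = 0, frac_2mm = 0, seed = 9L)
  out <- run_demux(sim$r1, sim$r2, fx$wl, file.path(dir, "demux"))
  expect_equal(out$stats$assigned, 300L)
  expect_equal(out$stats$discarded, 0L)
  joined <- merge(out$assignments, sim$truth, by = "qname")
  expect_equal(joined$sample.x, joined$sample.y)

  # empty input
  e1 <- tempfile(fileext = ".fastq"); e2 <- tempfile(fileext = ".fastq")
  writeLines(character(), e1); writeLines(character(), e2)
  out0 <- run_demux(e1, e2, fx$wl, file.path(dir, "demux0"))
  expect_equal(out0$stats$total, 0L)
  expect_equal(out0$stats$assigned, 0L)
})
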