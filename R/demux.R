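# sci-RNA-seq3 sample demultiplexing. Sample identity is encoded in R1 as
# four concatenated barcodes — p7 (10 nt), p5 (10 nt), ligation (9 or 10
# nt) and RT (10 nt) — followed by an 8 nt UMI. Each observed barcode is
# matched against its whitelist at hamming distance <= 1; assigned reads
# have R1 rewritten to the whitelisted sequences plus UMI, always 48 nt
# (9-nt ligation barcodes are padded with a G, and the ligation whitelist
# gains the corresponding padded aliases).

BARCODE_LEN <- c(p7 = 10L, p5 = 10L, ligation = 10L, rt = 10L)
UMI_LEN <- 8L

#' Load barcode whitelists and the sample sheet
#'
#' @param files Named list/vector with paths for `p7`, `p5`, `ligation`,
#'   `rt` (one uppercase ACGT barcode per line; ligation entries may be
#'   9 or 10 nt, all others exactly 10 nt).
#' @param samplesheet Path to a TSV with columns `p7`, `p5`, `ligation`,
#'   `rt`, `sample`, or a data.frame of the same shape.
#' @return A `barcode_whitelists`: list of per-barcode character vectors
#'   (ligation includes G-padded 10-nt aliases of 9-nt entries, with
#'   `lig9` recording the originals), plus `samplesheet` and `lookup`.
#' @export
load_whitelists <- function(files, samplesheet) {
  read_list <- function(path, role) {
    bc <- readLines(path)
    bc <- bc[nzchar(bc)]
    bad <- grepl("[^ACGT]", bc)
    if (any(bad))
      stop(sprintf("malformed barcode in %s line %d: %s", role,
                   which(bad)[1], bc[which(bad)[1]]))
    want <- BARCODE_LEN[[role]]
    lens <- nchar(bc)
    ok_len <- if (role == "ligation") lens %in% c(9L, 10L) else lens == want
    if (!all(ok_len))
      stop(sprintf("barcode of wrong length in %s line %d: %s", role,
                   which(!ok_len)[1], bc[which(!ok_len)[1]]))
    if (anyDuplicated(bc)) {
      warning("duplicate entries in ", role, " whitelist; deduplicated")
      bc <- unique(bc)
    }
    bc
  }
  wl <- list(
    p7 = read_list(files[["p7"]], "p7"),
    p5 = read_list(files[["p5"]], "p5"),
    ligation = read_list(files[["ligation"]], "ligation"),
    rt = read_list(files[["rt"]], "rt")
  )
  lig9 <- wl$ligation[nchar(wl$ligation) == 9L]
  wl$lig9 <- lig9
  wl$ligation <- unique(c(wl$ligation[nchar(wl$ligation) == 10L],
                          paste0(lig9, "G")))
  ss <- if (is.character(samplesheet))
    data.table::fread(samplesheet, sep = "\t", colClasses = "character")
  else data.table::as.data.table(samplesheet)
  need <- c("p7", "p5", "ligation", "rt", "sample")
  if (!all(need %in% names(ss)))
    stop("samplesheet needs columns ", paste(need, collapse = ", "))
  ss <- ss[, ..need]
  # pad 9-nt ligation barcodes in the sheet the same way
  short <- nchar(ss$ligation) == 9L
  ss$ligation[short] <- paste0(ss$ligation[short], "G")
  lookup <- ss$sample
  names(lookup) <- paste(ss$p7, ss$p5, ss$ligation, ss$rt, sep = "|")
  structure(c(wl, list(samplesheet = ss, lookup = lookup)),
            class = "barcode_whitelists")
}

#' @keywords internal
hamming1_match <- function(observed, whitelist) {
  # vectorised over observed; whitelist entries all one length
  n <- length(observed)
  L <- nchar(whitelist[1])
  exact <- match(observed, whitelist)
  out_bc <- whitelist[exact]
  outcome <- ifelse(!is.na(exact), "exact", "none")
  todo <- which(is.na(exact) & nchar(observed) == L)
  if (length(todo)) {
    obs_mat <- matrix(unlist(strsplit(observed[todo], "")), ncol = L,
                      byrow = TRUE)
    wl_mat <- matrix(unlist(strsplit(whitelist, "")), ncol = L, byrow = TRUE)
    for (i in seq_along(todo)) {
      d <- colSums(t(wl_mat) != obs_mat[i, ])
      hits <- which(d == 1L)
      if (length(hits) == 1L) {
        outcome[todo[i]] <- "ham1"
        out_bc[todo[i]] <- whitelist[hits]
      } else if (length(hits) > 1L) {
        outcome[todo[i]] <- "ambiguous"
      }
    }
  }
  bad_len <- nchar(observed) != L
  outcome[bad_len] <- "none"
  list(outcome = outcome, barcode = out_bc)
}

#' Match one observed barcode against a whitelist
#'
#' Exact match wins; otherwise a unique hamming-1 neighbour gives `ham1`,
#' two or more neighbours `ambiguous`, none `none`.
#'
#' @param observed Observed barcode sequence.
#' @param whitelist Character vector of whitelist entries (one length).
#' @return List with `outcome` (`exact`/`ham1`/`ambiguous`/`none`) and
#'   `barcode` (the matched whitelist entry or NA).
#' @export
match_barcode <- function(observed, whitelist) {
  if (length(unique(nchar(whitelist))) != 1L)
    stop("whitelist entries must share one length")
  if (nchar(observed) != nchar(whitelist[1]))
    stop("observed length does not match whitelist")
  r <- hamming1_match(observed, whitelist)
  list(outcome = r$outcome[1], barcode = r$barcode[1])
}

#' @keywords internal
demux_batch <- function(r1, wl) {
  n <- length(r1)
  res <- data.table::data.table(
    idx = seq_len(n),
    p7 = "none", p5 = "none", ligation = "none", rt = "none",
    assigned_sample = NA_character_, reason = NA_character_,
    rewritten = NA_character_)
  trunc <- nchar(r1) < 47L
  res$reason[trunc] <- "truncated"
  ok <- which(!trunc)
  if (!length(ok)) return(res)
  s <- r1[ok]
  m_p7 <- hamming1_match(substr(s, 1L, 10L), wl$p7)
  m_p5 <- hamming1_match(substr(s, 11L, 20L), wl$p5)
  # 9-vs-10 nt ligation barcodes shift the RT/UMI frame, and with G-padded
  # aliases in the whitelist the 10-nt window of a 9-nt read is always
  # within hamming distance 1 of its alias; the frame is therefore resolved
  # jointly: a frame is accepted only if its ligation AND its RT window both
  # match, trying the 10-nt frame first. Both frames matching is ambiguous.
  frame <- function(width) {
    ligw <- if (width == 10L) substr(s, 21L, 30L)
            else paste0(substr(s, 21L, 29L), "G")
    ml <- hamming1_match(ligw, wl$ligation)
    rt_start <- 21L + width
    mr <- hamming1_match(substr(s, rt_start, rt_start + 9L), wl$rt)
    ok <- ml$outcome %in% c("exact", "ham1") &
      mr$outcome %in% c("exact", "ham1")
    list(lig = ml, rt = mr, ok = ok,
         umi = substr(s, rt_start + 10L, rt_start + 10L + UMI_LEN - 1L))
  }
  f10 <- frame(10L); f9 <- frame(9L)
  both <- f10$ok & f9$ok &
    (f10$lig$barcode != f9$lig$barcode | f10$rt$barcode != f9$rt$barcode)
  use9 <- f9$ok & !f10$ok
  pickc <- function(a, b) ifelse(use9, b, a)
  lig_out <- ifelse(both, "ambiguous", pickc(f10$lig$outcome, f9$lig$outcome))
  lig_bc <- ifelse(both, NA_character_, pickc(f10$lig$barcode, f9$lig$barcode))
  m_rt <- list(outcome = ifelse(both, "ambiguous",
                                pickc(f10$rt$outcome, f9$rt$outcome)),
               barcode = ifelse(both, NA_character_,
                                pickc(f10$rt$barcode, f9$rt$barcode)))
  umi <- pickc(f10$umi, f9$umi)

  res$p7[ok] <- m_p7$outcome
  res$p5[ok] <- m_p5$outcome
  res$ligation[ok] <- lig_out
  res$rt[ok] <- m_rt$outcome
  good <- m_p7$outcome %in% c("exact", "ham1") &
    m_p5$outcome %in% c("exact", "ham1") &
    lig_out %in% c("exact", "ham1") &
    m_rt$outcome %in% c("exact", "ham1") &
    nchar(umi) == UMI_LEN
  key <- paste(m_p7$barcode, m_p5$barcode, lig_bc, m_rt$barcode, sep = "|")
  samp <- wl$lookup[key]
  good <- good & !is.na(samp)
  res$assigned_sample[ok[good]] <- unname(samp[good])
  res$rewritten[ok[good]] <- paste0(m_p7$barcode[good], m_p5$barcode[good],
                                    lig_bc[good], m_rt$barcode[good],
                                    umi[good])
  failing <- function(i) {
    oc <- c(p7 = m_p7$outcome[i], p5 = m_p5$outcome[i],
            ligation = lig_out[i], rt = m_rt$outcome[i])
    bad <- names(oc)[!oc %in% c("exact", "ham1")]
    if (length(bad)) paste0("barcode:", paste(bad, collapse = "+"))
    else "no-sample-for-combination"
  }
  nf <- which(!good)
  res$reason[ok[nf]] <- vapply(nf, failing, "")
  res
}

#' Demultiplex one read pair
#'
#' Barcodes are extracted at fixed R1 offsets (p7 0-10, p5 10-20, ligation
#' 20-29/30, RT the next 10, UMI the final 8); the 9-vs-10 nt ligation
#' width is resolved by trying the 10-nt window first and falling back to
#' the G-padded 9-nt window. Assigned reads have R1 rewritten to the
#' whitelisted barcode sequences plus UMI (48 nt).
#'
#' @param r1,r2 Read sequences (R2 is passed through).
#' @param whitelists A `barcode_whitelists`.
#' @return A `demux_record`: list with per-barcode `outcomes`, `sample`
#'   (or NA), `reason` for discards, `rewritten_r1`, `r2`.
#' @export
demux_readpair <- function(r1, r2, whitelists) {
  res <- demux_batch(r1, whitelists)[1L]
  structure(list(
    outcomes = c(p7 = res$p7, p5 = res$p5, ligation = res$ligation,
                 rt = res$rt),
    sample = res$assigned_sample, reason = res$reason,
    rewritten_r1 = res$rewritten, r2 = r2), class = "demux_record")
}

#' Demultiplex a FASTQ pair into per-sample files
#'
#' @param r1_path,r2_path Input FASTQ paths.
#' @param whitelists A `barcode_whitelists`.
#' @param out_dir Output directory; per-sample `<sample>_R1.fastq` /
#'   `_R2.fastq` pairs plus `discarded_R1.fastq` / `_R2.fastq`, and a
#'   `demux_summary.json`.
#' @return Invisibly, list with `stats` (per-category counts), and
#'   `assignments` (data.table: read id, sample or NA, reason).
#' @export
run_demux <- function(r1_path, r2_path, whitelists, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  f2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  ids <- sub("\\s.*", "", names(f1))
  res <- demux_batch(as.character(f1), whitelists)
  res[, qname := ids]
  write_pair <- function(sel, prefix) {
    r1s <- Biostrings::DNAStringSet(
      ifelse(is.na(res$rewritten[sel]), as.character(f1[sel]),
             res$rewritten[sel]))
    names(r1s) <- ids[sel]
    r2s <- f2[sel]
    q1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(r1s)))
    q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(r2s)))
    Biostrings::writeXStringSet(r1s, file.path(out_dir, paste0(prefix, "_R1.fastq")),
                                format = "fastq", qualities = q1)
    Biostrings::writeXStringSet(r2s, file.path(out_dir, paste0(prefix, "_R2.fastq")),
                                format = "fastq", qualities = q2)
  }
  assigned <- !is.na(res$assigned_sample)
  for (s in unique(res$assigned_sample[assigned]))
    write_pair(which(res$assigned_sample == s), s)
  write_pair(which(!assigned), "discarded")
  stats <- list(
    total = nrow(res),
    assigned = sum(assigned),
    discarded = sum(!assigned),
    per_sample = as.list(table(res$assigned_sample[assigned])),
    discard_reasons = as.list(table(res$reason[!assigned]))
  )
  jsonlite::write_json(stats, file.path(out_dir, "demux_summary.json"),
                       auto_unbox = TRUE)
  invisible(list(stats = stats,
                 assignments = res[, .(qname, sample = assigned_sample,
                                       reason, rewritten)]))
}
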