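# End-to-end orchestration: simulate a carrier (or control) cohort, run the
# three evidence lines — single-cell dosage testing, coverage CNV calling,
# haplotype-resolved parental origin — plus split-read breakpoint
# localisation, and integrate them into one report that states whether the
# evidence concordantly supports an X-to-Y translocation of one interval.

#' Default pipeline configuration
#' @return Nested named list of defaults for every stage.
#' @export
pipeline_config <- function() {
  list(
    genome = list(),          # overrides of toy_genome_config()
    snp_rate = 0.007,
    genotype = "XYT",
    background = "F1-B6xCAST",
    carrier = TRUE,
    wgs = list(depth = 20, read_len = 100L, insert_mean = 300,
               insert_sd = 30, error_rate = 0),
    long_reads = list(mean_len = 3000, depth = 30),
    window = 1000L,
    counts = list(n_per_group = 3L),  # plus count_sim_params() overrides
    dosage = list(gonad = "T", min_umi = 200L, min_genes = 25L,
                  min_reads = 10L, fdr = 0.10, max_skip = 1L,
                  min_region_genes = 2L),
    haplotype = list(min_informative = 5L, inside_min = 0.3,
                     outside_max = 0.1),
    breakpoint = list(radius = 50L, min_support = 3L),
    k = 21L
  )
}

#' Validate and normalise a pipeline configuration
#'
#' @param config A named list of overrides, or a YAML file path.
#' @param strict Error (rather than warn) on unknown keys.
#' @return The merged configuration with defaults filled in.
#' @export
validate_config <- function(config = list(), strict = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config()
  problems <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
    if (strict) problems <- c(problems, msg) else warning(msg)
    config <- config[setdiff(names(config), unknown)]
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$wgs$depth <= 0) problems <- c(problems, "wgs depth must be > 0")
  if (cfg$long_reads$depth <= 0) problems <- c(problems, "long-read depth must be > 0")
  if (cfg$window < 100L) problems <- c(problems, "window must be >= 100")
  if (!cfg$genotype %in% c("XXO", "XXT", "XYO", "XYT"))
    problems <- c(problems, "genotype must be one of XXO/XXT/XYO/XYT")
  if (cfg$carrier && cfg$genotype %in% c("XXO", "XXT"))
    problems <- c(problems, "XX genotypes cannot carry the translocation")
  if (cfg$counts$n_per_group < 2L)
    problems <- c(problems, "need >= 2 mice per genotype group")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  cfg
}

#' Run the full inference pipeline on synthetic data
#'
#' Builds the toy genome and strain SNPs, simulates WGS and long reads for
#' the configured sample plus single-cell counts for a carrier-vs-control
#' cohort, maps everything with the seed mapper, and runs all inference
#' stages. Every stage consumes a sub-seed derived from `seed` and the
#' stage name ([derive_seed()]), so stages are independently reproducible.
#'
#' @param config Configuration list or YAML path (see [validate_config()]).
#' @param seed Root integer seed.
#' @param out_dir Optional directory for artefact files (report JSON,
#'   tracks, calls).
#' @return An `integrated_report`: list with `dosage`, `cnv`, `origin`,
#'   `breakpoint`, `concordance`, `truth`, `metadata`.
#' @export
run_full <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- validate_config(config)
  genome <- build_toy_genome(cfg$genome, seed = derive_seed(seed, "genome"))
  variants <- derive_strain_variants(genome, cfg$snp_rate,
                                     seed = derive_seed(seed, "variants"))
  design <- sample_design("wgs1", cfg$genotype, cfg$background, cfg$carrier)
  haps <- build_sample_haplotypes(genome, variants, design)
  index <- index_genome(genome, cfg$k)
  par_dt <- data.table::data.table(
    contig = names(genome$par_interval),
    start = vapply(genome$par_interval, `[`, 1, 1L),
    end = vapply(genome$par_interval, `[`, 1, 2L))

  # --- coverage CNV line ---
  wgs <- simulate_wgs_reads(haps, depth = cfg$wgs$depth,
                            read_len = cfg$wgs$read_len,
                            insert_mean = cfg$wgs$insert_mean,
                            insert_sd = cfg$wgs$insert_sd,
                            error_rate = cfg$wgs$error_rate,
                            seed = derive_seed(seed, "wgs"))
  wgs_aln <- map_readset(index, wgs)
  track <- window_coverage(wgs_aln, window = cfg$window)
  norm <- normalize_to_autosomal_median(track, autosomes = "chrA")
  is_xy <- design$is_xy
  baseline <- c(chrX = if (is_xy) 0.5 else 1.0, chrY = 0.5)
  cnv <- call_duplication(norm, baseline, exclude = par_dt)
  cnv_x <- cnv[contig == "chrX"][order(-n_windows)]

  # --- haplotype origin line (F1 backgrounds only) ---
  origin <- NULL
  htracks <- NULL
  if (design$background == "F1-B6xCAST") {
    htracks <- haplotype_window_coverage(
      wgs_aln, variants, window = cfg$window,
      min_informative = cfg$haplotype$min_informative)
    query_iv <- if (nrow(cnv_x)) c(cnv_x$start[1], cnv_x$end[1])
                else genome$duplication_interval
    origin <- infer_parental_origin(
      htracks, query_iv, contig = "chrX",
      inside_min = cfg$haplotype$inside_min,
      outside_max = cfg$haplotype$outside_max, exclude = par_dt)
  }

  # --- breakpoint line ---
  long <- simulate_long_reads(haps, mean_len = cfg$long_reads$mean_len,
                              depth = cfg$long_reads$depth,
                              seed = derive_seed(seed, "long"))
  long_aln <- map_readset(index, long)
  evidence <- collect_split_reads(long_aln)
  bp <- cluster_junctions(evidence, radius = cfg$breakpoint$radius,
                          min_support = cfg$breakpoint$min_support)
  bp <- annotate_repeats(bp, genome$repeats, radius = cfg$breakpoint$radius)
  bp_xy <- bp[orientation == "XY"]

  # --- dosage line ---
  npg <- cfg$counts$n_per_group
  designs <- c(
    lapply(seq_len(npg), function(i)
      sample_design(sprintf("xyt%d", i), "XYT", "pure-B6", cfg$carrier)),
    lapply(seq_len(npg), function(i)
      sample_design(sprintf("xxt%d", i), "XXT", "pure-B6", FALSE)))
  cparams <- cfg$counts[setdiff(names(cfg$counts), "n_per_group")]
  cm <- simulate_sc_counts(genome, designs, params = cparams,
                           seed = derive_seed(seed, "counts"))
  dos <- run_dosage(cm, genome, gonad = cfg$dosage$gonad,
                    min_umi = cfg$dosage$min_umi,
                    min_genes = cfg$dosage$min_genes,
                    min_reads = cfg$dosage$min_reads,
                    fdr = cfg$dosage$fdr, max_skip = cfg$dosage$max_skip)

  # --- concordance ---
  w <- cfg$window
  conc <- list()
  # a one-gene "region" is not a PAR-adjacent cluster; require a run of
  # at least min_region_genes significant genes to count as an event
  have_dosage <- dos$region$n_significant >= cfg$dosage$min_region_genes
  have_cnv <- nrow(cnv_x) > 0L
  have_bp <- nrow(bp_xy) > 0L
  if (have_dosage && have_cnv) {
    conc$dosage_region_in_cnv <-
      dos$region$interval[1] >= cnv_x$start[1] - w &&
      dos$region$interval[2] <= cnv_x$end[1] + w
  }
  if (have_bp && have_cnv) {
    conc$breakpoint_at_cnv_edge <-
      abs(bp_xy$x_consensus[1] - (cnv_x$end[1] - 1L)) <= w
  }
  positives <- c(have_dosage, have_cnv, have_bp,
                 if (!is.null(origin)) origin$verdict == "paternal-duplication")
  verdict <- if (!any(positives)) "no event"
  else if (all(positives) && all(unlist(conc))) "concordant translocation"
  else "discordant evidence"

  report <- structure(list(
    dosage = dos$region,
    dosage_results = dos$results,
    cnv = cnv,
    origin = origin,
    breakpoint = bp,
    concordance = conc,
    verdict = verdict,
    truth = list(duplication_interval = genome$duplication_interval,
                 junction_site = genome$junction_site,
                 carrier = cfg$carrier),
    metadata = list(seed = seed,
                    stage_seeds = sapply(
                      c("genome", "variants", "wgs", "long", "counts"),
                      function(s) derive_seed(seed, s)),
                    config_hash = config_hash(cfg))
  ), class = "integrated_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_truth_beds(genome, out_dir)
    write_track_bedgraph(norm, file.path(out_dir, "coverage_norm.bedGraph"))
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (nrow(cnv))
      write_bed(cnv[, .(contig, start, end, name = "duplication_call")],
                file.path(out_dir, "cnv_calls.bed"))
  }
  report
}

#' @keywords internal
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' @keywords internal
report_to_json <- function(report) {
  list(
    verdict = report$verdict,
    dosage_region = if (length(report$dosage$genes)) list(
      genes = report$dosage$genes,
      interval = report$dosage$interval,
      n_significant = report$dosage$n_significant) else NULL,
    cnv_calls = if (nrow(report$cnv)) report$cnv else NULL,
    origin = if (!is.null(report$origin)) list(
      verdict = report$origin$verdict,
      mean_inside = report$origin$mean_inside,
      mean_outside = report$origin$mean_outside) else NULL,
    breakpoint = if (nrow(report$breakpoint)) report$breakpoint else NULL,
    concordance = report$concordance,
    truth = report$truth,
    metadata = report$metadata
  )
}

#' @export
print.integrated_report <- function(x, ...) {
  cat("integrated report — verdict:", x$verdict, "\n")
  if (length(x$dosage$genes))
    cat(sprintf("  dosage region: %d genes [%d,%d)\n",
                x$dosage$n_significant, x$dosage$interval[1],
                x$dosage$interval[2]))
  if (nrow(x$cnv))
    cat(sprintf("  CNV: %s:[%d,%d) mean %.2f\n", x$cnv$contig[1],
                x$cnv$start[1], x$cnv$end[1], x$cnv$mean_inside[1]))
  if (!is.null(x$origin))
    cat(sprintf("  origin: %s (inside %.2f / outside %.2f)\n",
                x$origin$verdict, x$origin$mean_inside, x$origin$mean_outside))
  bx <- x$breakpoint[x$breakpoint$orientation == "XY", ]
  if (nrow(bx))
    cat(sprintf("  breakpoint: chrX:%d | chrY:%d (support %d, repeat %s)\n",
                as.integer(bx$x_consensus[1]), as.integer(bx$y_consensus[1]),
                bx$support[1], bx$repeat_family[1]))
  invisible(x)
}
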