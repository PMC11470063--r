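# DNA FISH simulation and quantification. Each cell has one Y-chromosome
# domain centroid and one or two X-segment domain centroids (in µm); in
# two-domain cells one X domain is placed close to the Y domain, emulating
# the translocated copy residing on the Y territory.

#' Simulate per-cell FISH spot-centroid records
#'
#' Exactly `floor(two_domain_fraction * n_cells)` cells receive a second X
#' domain (deterministic allocation in randomised order, so headline
#' percentages reproduce exactly). The second X domain sits at a distance
#' drawn from `proximity_params` of the Y centroid; all other domains are
#' uniform in a nucleus box.
#'
#' @param n_cells Number of cells.
#' @param genotype Genotype label for the records.
#' @param two_domain_fraction Fraction of cells with two X domains.
#' @param proximity_params List: `near_mean`, `near_sd` (µm distance of
#'   the translocated X domain from Y), `box` (nucleus dimensions, µm).
#' @param seed Integer seed.
#' @return data.table in long spot-table form: `cell_id`, `genotype`,
#'   `domain` (`X`/`Y`), `x`, `y`, `z` (µm).
#' @export
simulate_fish_cells <- function(n_cells, genotype = "XYT",
                                two_domain_fraction = 0.92,
                                proximity_params = list(near_mean = 0.8,
                                                        near_sd = 0.3,
                                                        box = c(10, 10, 5)),
                                seed = 1L) {
  stopifnot(two_domain_fraction >= 0, two_domain_fraction <= 1)
  set.seed(seed)
  box <- proximity_params$box %||% c(10, 10, 5)
  n_two <- floor(two_domain_fraction * n_cells)
  two <- rep(FALSE, n_cells)
  two[sample.int(n_cells, n_two)] <- TRUE
  unif_pt <- function(n) cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                               runif(n, 0, box[3]))
  ycent <- unif_pt(n_cells)
  x1 <- unif_pt(n_cells)
  rows <- list(
    data.table::data.table(cell_id = sprintf("cell%04d", seq_len(n_cells)),
                           genotype = genotype, domain = "Y",
                           x = ycent[, 1], y = ycent[, 2], z = ycent[, 3]),
    data.table::data.table(cell_id = sprintf("cell%04d", seq_len(n_cells)),
                           genotype = genotype, domain = "X",
                           x = x1[, 1], y = x1[, 2], z = x1[, 3])
  )
  if (n_two > 0L) {
    sel <- which(two)
    d <- pmax(0.05, rnorm(n_two, proximity_params$near_mean %||% 0.8,
                          proximity_params$near_sd %||% 0.3))
    u <- matrix(rnorm(3 * n_two), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    x2 <- ycent[sel, , drop = FALSE] + u * d
    rows[[3]] <- data.table::data.table(
      cell_id = sprintf("cell%04d", sel), genotype = genotype, domain = "X",
      x = x2[, 1], y = x2[, 2], z = x2[, 3])
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, cell_id, domain)
  out[]
}

#' Count X domains per cell and summarise the distribution
#'
#' @param records Spot table (`cell_id`, `genotype`, `domain`, `x`, `y`,
#'   `z`), one genotype.
#' @return List with `n_cells`, `histogram` (named count vector over X
#'   domain numbers), `percent_two_domain`.
#' @export
count_domains <- function(records) {
  records <- data.table::as.data.table(records)
  if (!nrow(records)) stop("records must be non-empty")
  ycells <- records[domain == "Y"]
  if (anyDuplicated(ycells$cell_id))
    stop("duplicate cell ids: ",
         paste(unique(ycells$cell_id[duplicated(ycells$cell_id)]), collapse = ","))
  nx <- records[domain == "X", .N, by = cell_id]
  all_cells <- unique(records$cell_id)
  counts <- setNames(rep(0L, length(all_cells)), all_cells)
  counts[nx$cell_id] <- nx$N
  hist <- table(factor(counts, levels = sort(unique(counts))))
  n <- length(all_cells)
  list(n_cells = n,
       histogram = setNames(as.integer(hist), names(hist)),
       percent_two_domain = 100 * sum(counts == 2L) / n)
}

#' Distance from each cell's Y domain to its nearest X domain
#'
#' 3D Euclidean by default; `dims = c("x", "y")` gives the 2D projected
#' variant. Cells without a Y domain or without X domains are excluded and
#' counted.
#'
#' @param records Spot table as in [count_domains()].
#' @param dims Coordinate columns used for the distance.
#' @return List with `distances` (named per-cell nearest distances, µm),
#'   `median`, `sd`, `n_excluded`.
#' @export
nearest_xy_distance <- function(records, dims = c("x", "y", "z")) {
  records <- data.table::as.data.table(records)
  ys <- records[domain == "Y"]
  xs <- records[domain == "X"]
  cells <- unique(records$cell_id)
  d <- vapply(cells, function(cid) {
    yc <- ys[cell_id == cid]
    xc <- xs[cell_id == cid]
    if (nrow(yc) != 1L || nrow(xc) == 0L) return(NA_real_)
    dd <- sqrt(rowSums((as.matrix(xc[, ..dims]) -
                        matrix(as.numeric(yc[, ..dims]), nrow(xc),
                               length(dims), byrow = TRUE))^2))
    min(dd)
  }, numeric(1))
  ok <- !is.na(d)
  list(distances = d[ok], median = stats::median(d[ok]), sd = sd(d[ok]),
       n_excluded = sum(!ok))
}

#' Full FISH summary for one genotype's spot table
#'
#' @param records Spot table.
#' @param dims Distance dimensions (3D default).
#' @return A `fish_summary`: list combining [count_domains()] and
#'   [nearest_xy_distance()] output.
#' @export
fish_summary <- function(records, dims = c("x", "y", "z")) {
  cd <- count_domains(records)
  nd <- nearest_xy_distance(records, dims)
  structure(c(cd, list(distance_median = nd$median, distance_sd = nd$sd,
                       distances = nd$distances,
                       n_excluded = nd$n_excluded)),
            class = "fish_summary")
}

#' Write / read FISH spot tables as TSV
#' @param records Spot table.
#' @param path TSV path.
#' @return Invisibly `path`; `read_fish_table` returns the data.table.
#' @export
write_fish_table <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}

#' @rdname write_fish_table
#' @export
read_fish_table <- function(path) {
  data.table::fread(path, sep = "\t")
}
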