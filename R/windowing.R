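#' Build a fixed-width window grid over a genome
#'
#' Windows tile each chromosome as `[k*W, (k+1)*W)` with the final window
#' truncated at the chromosome length; per-chromosome window count is
#' `ceiling(length / W)`.
#'
#' @param index a [genome_index()].
#' @param window_size window width in bp (default 10 kb).
#' @return A `window_grid` object.
#' @export
make_grid <- function(index, window_size = 10000) {
  stopifnot(inherits(index, "genome_index"))
  if (!is.finite(window_size) || window_size <= 0)
    param_error("window_size must be positive, got %s", window_size)
  windows <- rbindlist(lapply(seq_len(nrow(index)), function(i) {
    len <- index$length[i]
    nw <- ceiling(len / window_size)
    k <- seq_len(nw) - 1
    data.table(chrom = index$chrom[i], window = k,
               start = k * window_size,
               end = pmin((k + 1) * window_size, len))
  }))
  g <- list(index = index, window_size = window_size, windows = windows)
  class(g) <- "window_grid"
  g
}

#' Count SNPs per window
#'
#' Bins distinct SNP keys (`chrom`, `pos`, `alt`) into the grid's windows.
#' Duplicate records for the same key count once.
#'
#' @param snps a [snp_records()] table (0-based positions).
#' @param grid a [make_grid()] grid.
#' @param label label carried on the result (defaults to the records'
#'   accession id).
#' @return A `window_counts` object: list with `grid`, `label`, and a
#'   `windows` data.table (`chrom, window, start, end, count`) covering every
#'   window, zero counts included.
#' @export
bin_snps <- function(snps, grid, label = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  dt <- unique(as.data.table(snps)[, .(chrom, pos, alt)])
  dt <- normalize_snps(dt, grid$index)
  if (is.null(label))
    label <- if (nrow(snps)) as.character(snps$accession_id[1]) else
      NA_character_
  W <- grid$window_size
  win <- copy(grid$windows)
  if (nrow(dt)) {
    tab <- dt[, .(count = .N), by = .(chrom, window = pos %/% W)]
    win[tab, count := i.count, on = c("chrom", "window")]
    win[is.na(count), count := 0]
  } else win[, count := 0]
  win[, count := as.numeric(count)]
  wc <- list(grid = grid, label = label, windows = win[])
  class(wc) <- "window_counts"
  wc
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts '%s': %d windows of %g bp on %d chromosome(s), %g SNPs\n",
              x$label, nrow(x$windows), x$grid$window_size,
              nrow(x$grid$index), sum(x$windows$count)))
  invisible(x)
}

snp_keys <- function(snps) {
  unique(as.data.table(snps)[, .(chrom, pos, alt)])
}

#' SNP keys shared between two accessions
#'
#' A SNP is shared when chromosome, position and the alternate allele all
#' match; position-only coincidences (different alt) are independent
#' mutations and do not count. Symmetric in its arguments.
#'
#' @param a,b [snp_records()] tables called against the same reference.
#' @return data.table of shared keys (`chrom, pos, alt`).
#' @export
shared_snps <- function(a, b) {
  ka <- snp_keys(a); kb <- snp_keys(b)
  merge(ka, kb, by = c("chrom", "pos", "alt"))[order(chrom, pos, alt)]
}

#' Donor-unique SNPs of a query accession
#'
#' The breakpoint-delineation SNP set: keys shared by the query and one
#' candidate donor, absent from every accession of an exclusion panel, whose
#' query record passes strict read-support filters (depth > `min_depth` and
#' alternate-allele fraction > `min_alt_fraction`; records lacking an allele
#' fraction fail). Defaults mirror the published filter: coverage greater
#' than 10x, allele frequency greater than 90%.
#'
#' @param query,donor [snp_records()] tables versus the same reference.
#' @param exclusion_panel list of [snp_records()] tables whose keys are
#'   subtracted.
#' @param min_depth exclusive depth cutoff (default 10).
#' @param min_alt_fraction exclusive allele-fraction cutoff (default 0.9).
#' @return data.table of retained keys (`chrom, pos, alt`).
#' @export
unique_donor_snps <- function(query, donor, exclusion_panel = list(),
                              min_depth = 10, min_alt_fraction = 0.9) {
  if (nrow(donor) == 0) {
    warning("empty donor SNP list: returning no donor-unique SNPs")
    return(data.table(chrom = character(), pos = numeric(),
                      alt = character()))
  }
  q <- collapse_snp_keys(query)
  keys <- merge(as.data.table(q), snp_keys(donor),
                by = c("chrom", "pos", "alt"))
  for (ex in exclusion_panel) {
    if (nrow(keys) == 0) break
    keys <- keys[!snp_keys(ex), on = c("chrom", "pos", "alt")]
  }
  keys <- keys[!is.na(depth) & depth > min_depth &
                 !is.na(alt_fraction) & alt_fraction > min_alt_fraction]
  keys[order(chrom, pos, alt), .(chrom, pos, alt)]
}
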