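#' Scan sparse array-marker genotypes for candidate introgressions
#'
#' Implements the chip criterion: a candidate introgression is a region with
#' at least `min_markers` polymorphic markers within `span` bp (defaults: 3
#' polymorphic SNPs in 100 kb). Two modes:
#' \describe{
#'   \item{`cluster` (default)}{seeds are every run of `min_markers`
#'     consecutive polymorphic markers whose outermost positions fit within
#'     `span`; overlapping or bookended seed intervals merge. Detection is
#'     then independent of any window phase — appropriate for sparse array
#'     markers. Monomorphic and missing markers are ignored for seeding and
#'     never break a region.}
#'   \item{`tiled`}{fixed `span`-sized genomic tiles; tiles holding at least
#'     `min_markers` polymorphic markers qualify and adjacent qualifying
#'     tiles merge.}
#' }
#' Region boundaries are the outermost contributing marker positions;
#' `n_polymorphic` counts polymorphic markers inside the final region.
#'
#' @param markers marker table from [read_marker_table()] (columns
#'   `marker_id, chrom, pos, status`), sorted by (chrom, pos).
#' @param span window span in bp (default 100 kb).
#' @param min_markers minimum polymorphic markers within `span` (default 3).
#' @param mode `"cluster"` or `"tiled"`.
#' @return data.table `chrom, start, end, n_polymorphic` (positions on the
#'   input's 1-based scale), sorted as the input.
#' @export
scan_marker_regions <- function(markers, span = 100000, min_markers = 3,
                                mode = c("cluster", "tiled")) {
  mode <- match.arg(mode)
  if (span <= 0 || min_markers < 1) param_error("invalid span/min_markers")
  mk <- as.data.table(markers)
  if (any(mk[, is.unsorted(pos), by = rleid(chrom)]$V1) ||
      anyDuplicated(rle(mk$chrom)$values))
    contract_error("markers must be sorted by (chrom, pos)")
  poly <- mk[status == "polymorphic"]
  empty <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), n_polymorphic = integer())
  if (nrow(poly) < min_markers) return(empty)

  one_chrom <- function(pos) {
    m <- length(pos)
    if (m < min_markers) return(NULL)
    i <- seq_len(m - min_markers + 1)
    ok <- pos[i + min_markers - 1] - pos[i] <= span
    if (!any(ok)) return(NULL)
    seed <- data.table(s = pos[i][ok], e = pos[i + min_markers - 1][ok])
    # merge overlapping/bookended seed intervals
    grp <- cumsum(c(1, as.integer(seed$s[-1] > cummax(seed$e)[-nrow(seed)])))
    reg <- seed[, .(start = min(s), end = max(e)), by = grp][, grp := NULL]
    reg[, n_polymorphic := vapply(seq_len(.N), function(k)
      sum(pos >= start[k] & pos <= end[k]), 0L)]
    reg
  }

  one_chrom_tiled <- function(pos) {
    tile <- pos %/% span
    tab <- data.table(tile = tile, pos = pos)[, .N, by = tile][N >= min_markers]
    if (!nrow(tab)) return(NULL)
    tiles <- sort(tab$tile)
    grp <- cumsum(c(1, as.integer(diff(tiles) > 1)))
    reg <- data.table(tile = tiles, grp = grp)[, .(
      start = min(pos[pos %/% span %in% tile]),
      end = max(pos[pos %/% span %in% tile])), by = grp][, grp := NULL]
    reg[, n_polymorphic := vapply(seq_len(.N), function(k)
      sum(pos >= start[k] & pos <= end[k]), 0L)]
    reg
  }

  f <- if (mode == "cluster") one_chrom else one_chrom_tiled
  parts <- lapply(unique(poly$chrom), function(ch) {
    r <- f(poly[chrom == ch]$pos)
    if (!is.null(r)) r[, chrom := ch]
    r
  })
  out <- rbindlist(parts)
  if (!nrow(out)) return(empty)
  setcolorder(out, c("chrom", "start", "end", "n_polymorphic"))
  out[]
}
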