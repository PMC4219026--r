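#' Plot per-window SNP density with peak shading
#'
#' One panel per chromosome: SNPs per window as vertical bars, called peak
#' intervals shaded, and an optional second series of per-window shared-SNP
#' counts overlaid in a contrasting color (the visual used to compare a
#' query's SNP peaks with the SNPs it shares with a donor or heirloom).
#'
#' @param counts a `window_counts` object.
#' @param peaks optional `peak_regions` table to shade.
#' @param shared_overlay optional second `window_counts` on the same grid.
#' @param out output file; `.pdf` (default device, always available
#'   headless) or `.png`.
#' @param threshold optional horizontal line at the per-window threshold.
#' @return `out`, invisibly.
#' @export
plot_density <- function(counts, peaks = NULL, shared_overlay = NULL,
                         out = "snp_density.pdf", threshold = NULL) {
  win <- counts$windows
  if (nrow(win) == 0) input_error("empty window counts; nothing to plot")
  chroms <- counts$grid$index$chrom
  ext <- tolower(tools::file_ext(out))
  if (ext == "png") png(out, width = 1200, height = 300 * length(chroms))
  else pdf(out, width = 10, height = 2.8 * length(chroms))
  on.exit(dev.off())
  op <- par(mfrow = c(length(chroms), 1), mar = c(4, 4, 2, 1))
  on.exit(par(op), add = TRUE)
  for (ch in chroms) {
    sub <- win[chrom == ch][order(window)]
    x <- (sub$start + sub$end) / 2e6
    plot(x, sub$count, type = "h", col = "grey25", lwd = 1,
         xlab = sprintf("%s position (Mb)", ch),
         ylab = sprintf("SNPs / %g kb", counts$grid$window_size / 1000),
         main = sprintf("%s - %s", counts$label %||% "", ch))
    if (!is.null(peaks) && nrow(peaks)) {
      pk <- as.data.table(peaks)[chrom == ch]
      if (nrow(pk))
        rect(pk$start / 1e6, 0, pk$end / 1e6, max(sub$count),
             col = grDevices::adjustcolor("orange", 0.25), border = NA)
    }
    if (!is.null(shared_overlay)) {
      ov <- shared_overlay$windows[chrom == ch][order(window)]
      lines((ov$start + ov$end) / 2e6, ov$count, type = "h",
            col = grDevices::adjustcolor("gold", 0.8))
    }
    if (!is.null(threshold)) abline(h = threshold, col = "red", lty = 2)
  }
  invisible(out)
}
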