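#' Parameters of the SNP-peak caller
#'
#' Defaults follow the published rule: a peak has at least 10 SNPs per 10-kb
#' window, spans at least 50 kb, and may contain continuous internal gaps of
#' up to 40 kb of below-threshold windows (each maximal gap run, not a total
#' budget). `max_gap` must stay below `min_region_size` and both must be
#' multiples of `window_size`.
#'
#' @param min_snps_per_window inclusive per-window SNP threshold (default 10).
#' @param min_region_size minimum peak span in bp (default 50 kb).
#' @param max_gap maximum span of one internal below-threshold run (default
#'   40 kb).
#' @param window_size window width in bp (default 10 kb).
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_snps_per_window = 10, min_region_size = 50000,
                        max_gap = 40000, window_size = 10000) {
  p <- list(min_snps_per_window = min_snps_per_window,
            min_region_size = min_region_size,
            max_gap = max_gap, window_size = window_size)
  if (any(!vapply(p, function(x) is.finite(x) && x > 0, TRUE) &
          names(p) != "max_gap") || max_gap < 0)
    param_error("all peak parameters must be positive (max_gap >= 0)")
  if (max_gap >= min_region_size)
    param_error("max_gap (%g) must be smaller than min_region_size (%g)",
                max_gap, min_region_size)
  if (min_region_size %% window_size != 0 || max_gap %% window_size != 0)
    param_error("min_region_size and max_gap must be multiples of window_size")
  class(p) <- "peak_params"
  p
}

#' Call SNP-density peak regions (candidate introgressions)
#'
#' Per chromosome, returns every maximal run of windows such that (i) the
#' first and last window each reach `min_snps_per_window`, (ii) every maximal
#' interior run of below-threshold windows spans at most `max_gap`, (iii) the
#' region spans at least `min_region_size`, and (iv) it contains at least
#' `min_region_size / window_size` qualifying windows. Maximal segments under
#' the per-gap rule are unique, so no tie-breaking arises; emitted peaks are
#' disjoint, window-aligned and sorted by (chromosome order, start).
#'
#' @param counts a `window_counts` object from [bin_snps()].
#' @param params a [peak_params()].
#' @return A `peak_regions` data.table: `chrom, start, end, n_windows,
#'   n_qualifying_windows, n_snps, gap_bp`.
#' @export
call_peaks <- function(counts, params = peak_params()) {
  stopifnot(inherits(counts, "window_counts"), inherits(params, "peak_params"))
  if (counts$grid$window_size != params$window_size)
    param_error("grid window size (%g) differs from params window_size (%g)",
                counts$grid$window_size, params$window_size)
  W <- params$window_size
  gap_w <- params$max_gap %/% W
  min_w <- ceiling(params$min_region_size / W)

  one_chrom <- function(sub) {
    cnt <- sub$count
    qual <- which(cnt >= params$min_snps_per_window)
    if (!length(qual)) return(NULL)
    # chain qualifying windows whose inter-gap (in windows) stays <= gap_w
    brk <- which(diff(qual) - 1 > gap_w)
    first <- qual[c(1, brk + 1)]
    last <- qual[c(brk, length(qual))]
    seg <- data.table(first = first, last = last)
    seg[, `:=`(
      start = sub$start[first], end = sub$end[last],
      n_windows = last - first + 1L,
      n_qualifying_windows = vapply(seq_len(.N), function(i)
        sum(qual >= first[i] & qual <= last[i]), 0L),
      n_snps = vapply(seq_len(.N), function(i)
        sum(cnt[first[i]:last[i]]), 0),
      chrom = sub$chrom[1])]
    seg[, gap_bp := (n_windows - n_qualifying_windows) * W]
    seg <- seg[end - start >= params$min_region_size &
                 n_qualifying_windows >= min_w]
    if (!nrow(seg)) return(NULL)
    seg[, .(chrom, start, end, n_windows, n_qualifying_windows, n_snps,
            gap_bp)]
  }

  win <- counts$windows
  parts <- lapply(counts$grid$index$chrom, function(ch)
    one_chrom(win[chrom == ch][order(window)]))
  peaks <- rbindlist(parts)
  if (nrow(peaks) == 0)
    peaks <- data.table(chrom = character(), start = numeric(),
                        end = numeric(), n_windows = integer(),
                        n_qualifying_windows = integer(), n_snps = numeric(),
                        gap_bp = numeric())
  setattr(peaks, "params", params)
  setattr(peaks, "class", c("peak_regions", class(peaks)))
  peaks[]
}

#' Window counts outside all called peaks
#'
#' @param counts the `window_counts` the peaks were called from.
#' @param peaks a `peak_regions` table.
#' @param exclude_chroms chromosomes removed entirely (e.g. chromosomes whose
#'   peaks cover most of their length, excluded from calibration).
#' @return numeric vector of per-window SNP counts in non-peak windows.
#' @export
nonpeak_window_counts <- function(counts, peaks,
                                  exclude_chroms = character()) {
  win <- counts$windows[!chrom %in% exclude_chroms]
  if (nrow(peaks)) {
    pk <- as.data.table(peaks)[, .(chrom, pstart = start, pend = end)]
    hit <- win[pk, on = .(chrom, start >= pstart, start < pend),
               nomatch = NULL, which = TRUE]
    if (length(hit)) win <- win[-unique(hit)]
  }
  win$count
}

#' Calibrate the per-window SNP threshold
#'
#' For each candidate threshold, calls peaks, then compares the mean SNPs per
#' window over the entire (non-excluded) genome against the mean over
#' non-peak windows with a two-sample two-sided Student's t-test (pooled
#' variance; Welch available via `var_equal = FALSE`). The logic: if peaks
#' capture a real excess of SNPs, the genome-wide mean is significantly
#' higher than the non-peak mean.
#'
#' @param counts a `window_counts` object.
#' @param candidates candidate thresholds (default `c(3, 5, 10, 15, 20)`).
#' @param params_template [peak_params()] supplying the non-threshold rules.
#' @param exclude_chroms chromosomes removed from both samples before
#'   testing (used when peaks cover most of a chromosome).
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @return data.table with one row per candidate: `candidate_threshold,
#'   n_peaks, genome_mean, nonpeak_mean, t_statistic, p_value, degenerate,
#'   excluded_chromosomes`.
#' @export
calibrate_threshold <- function(counts, candidates = c(3, 5, 10, 15, 20),
                                params_template = peak_params(),
                                exclude_chroms = character(),
                                var_equal = TRUE) {
  if (!length(candidates)) param_error("candidates must be non-empty")
  keep <- counts$windows[!chrom %in% exclude_chroms]
  if (!nrow(keep)) param_error("all chromosomes excluded")
  sub <- counts
  sub$windows <- keep
  sub$grid <- make_grid(
    genome_index(setdiff(counts$grid$index$chrom, exclude_chroms),
                 counts$grid$index$length[
                   !counts$grid$index$chrom %in% exclude_chroms]),
    counts$grid$window_size)

  rows <- lapply(candidates, function(cand) {
    p <- params_template
    p$min_snps_per_window <- cand
    peaks <- call_peaks(sub, p)
    genome <- sub$windows$count
    nonpeak <- nonpeak_window_counts(sub, peaks)
    degenerate <- length(nonpeak) == 0
    if (degenerate) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (length(nonpeak) == length(genome)) {
      tt <- list(statistic = 0, p.value = 1)    # identical samples, no peaks
    } else {
      tt <- tryCatch(
        t.test(genome, nonpeak, var.equal = var_equal),
        error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    }
    data.table(candidate_threshold = cand, n_peaks = nrow(peaks),
               genome_mean = mean(genome),
               nonpeak_mean = if (degenerate) NA_real_ else mean(nonpeak),
               t_statistic = unname(tt$statistic),
               p_value = unname(tt$p.value),
               degenerate = degenerate,
               excluded_chromosomes = paste(exclude_chroms, collapse = ","))
  })
  rbindlist(rows)
}

#' Recommend a per-window SNP threshold from a calibration table
#'
#' Returns the smallest candidate threshold at which the genome-wide mean
#' exceeds the non-peak mean with `p_value < alpha` — i.e. peaks at that
#' threshold absorb a statistically significant excess of SNPs — or `NA`
#' when no candidate qualifies.
#'
#' @param rows output of [calibrate_threshold()].
#' @param alpha significance level (default 0.05).
#' @return integer candidate threshold, or `NA_integer_` for "none".
#' @export
recommend_threshold <- function(rows, alpha = 0.05) {
  rows <- as.data.table(rows)
  if (!nrow(rows)) param_error("calibration table is empty")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    param_error("alpha must be in (0, 1)")
  if (all(rows$degenerate)) {
    warning("all calibration rows degenerate; no threshold recommended")
    return(NA_integer_)
  }
  ok <- rows[!degenerate & is.finite(p_value) &
               genome_mean > nonpeak_mean & p_value < alpha]
  if (!nrow(ok)) return(NA_integer_)
  as.integer(min(ok$candidate_threshold))
}
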