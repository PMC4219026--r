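#' Summarize a peak-region table
#'
#' The bookkeeping metrics reported for an introgression scan: number of
#' regions, total span, SNPs inside regions, and smallest / largest / mean /
#' median region size.
#'
#' @param peaks a `peak_regions` table.
#' @return one-row data.table: `n_regions, total_bp, n_snps, smallest_bp,
#'   largest_bp, mean_bp, median_bp`.
#' @export
summarize_regions <- function(peaks) {
  dt <- as.data.table(peaks)
  if (nrow(dt) == 0)
    return(data.table(n_regions = 0L, total_bp = 0, n_snps = 0,
                      smallest_bp = NA_real_, largest_bp = NA_real_,
                      mean_bp = NA_real_, median_bp = NA_real_))
  sz <- dt$end - dt$start
  data.table(n_regions = nrow(dt), total_bp = sum(sz),
             n_snps = sum(dt$n_snps), smallest_bp = min(sz),
             largest_bp = max(sz), mean_bp = mean(sz),
             median_bp = median(sz))
}

#' Load a run configuration from JSON
#'
#' @param path JSON file with fields: `genome_index`, `query_vcf`,
#'   `query_id`, optional `panel` (array of `{accession_id, role, vcf}`),
#'   optional `params` (peak parameters), `calibrate` (logical),
#'   `candidates`, `exclude_chroms`, `breakpoint` (`{donor, min_depth,
#'   min_af}`), `match_min`, `majority_fraction`, `out_dir`.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) input_error("config file not found: %s", path)
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e) parse_error("cannot parse config %s: %s",
                                           path, conditionMessage(e)))
}

#' Run the full detection pipeline
#'
#' read -> bin -> (optional) calibrate -> call peaks -> classify ->
#' breakpoints. Writes, under `config$out_dir`: `peaks.bed`,
#' `windows_<query>.tsv`, `calibration.tsv` (when calibration is on),
#' `evidence.tsv` (when a panel is given), `breakpoints.tsv` (when a
#' breakpoint donor is named), `summary.tsv`, `run_log.txt` and
#' `config_echo.json`. Outputs are byte-deterministic for identical config
#' and inputs (no timestamps).
#'
#' @param config list as per [read_run_config()] (or built in code).
#' @return list with `peaks`, `summary`, `calibration`, `breakpoints`,
#'   `files`, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  out_dir <- cfg$out_dir %||% input_error("config lacks out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    invisible(NULL)
  }

  index <- read_genome_index(cfg$genome_index %||%
                               input_error("config lacks genome_index"))
  query_id <- cfg$query_id %||% "query"
  query <- read_vcf_snps(cfg$query_vcf %||%
                           input_error("config lacks query_vcf"),
                         query_id, index)
  note("stage read: %d SNP records for query '%s'", nrow(query), query_id)

  wsize <- cfg$params$window_size %||% 10000
  grid <- make_grid(index, wsize)
  counts <- bin_snps(query, grid)
  note("stage bin: %d windows of %g bp", nrow(counts$windows), wsize)

  params <- peak_params(
    min_snps_per_window = cfg$params$min_snps_per_window %||% 10,
    min_region_size = cfg$params$min_region_size %||% 50000,
    max_gap = cfg$params$max_gap %||% 40000,
    window_size = wsize)

  calib <- NULL
  if (isTRUE(cfg$calibrate)) {
    calib <- calibrate_threshold(
      counts, candidates = cfg$candidates %||% c(3, 5, 10, 15, 20),
      params_template = params,
      exclude_chroms = cfg$exclude_chroms %||% character())
    rec <- suppressWarnings(recommend_threshold(calib,
                                                cfg$alpha %||% 0.05))
    note("stage calibrate: recommended threshold = %s",
         if (is.na(rec)) "none" else rec)
    if (!is.na(rec) && isTRUE(cfg$use_recommended))
      params$min_snps_per_window <- rec
  }

  peaks <- call_peaks(counts, params)
  note("stage peaks: %d peaks, %.2f Mb, %g SNPs inside",
       nrow(peaks), sum(peaks$end - peaks$start) / 1e6, sum(peaks$n_snps))

  panel <- list()
  if (length(cfg$panel)) {
    pl <- cfg$panel
    if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
    panel <- lapply(pl, function(p)
      panel_accession(p$accession_id, p$role,
                      read_vcf_snps(p$vcf, p$accession_id, index)))
    peaks <- classify_peaks(peaks, query, panel, grid,
                            match_min = cfg$match_min %||% 10,
                            majority_fraction = cfg$majority_fraction %||%
                              0.5)
    note("stage classify: %d panel accessions", length(panel))
  } else {
    note("stage classify: skipped (no panel accessions configured)")
  }

  breakpoints <- NULL
  if (!is.null(cfg$breakpoint$donor) && length(panel)) {
    ids <- vapply(panel, `[[`, "", "accession_id")
    don <- panel[[match(cfg$breakpoint$donor, ids)]]
    if (is.null(don)) input_error("breakpoint donor '%s' not in panel",
                                  cfg$breakpoint$donor)
    excl <- panel[ids != cfg$breakpoint$donor]
    uk <- unique_donor_snps(query, don$snps, lapply(excl, `[[`, "snps"),
                            min_depth = cfg$breakpoint$min_depth %||% 10,
                            min_alt_fraction = cfg$breakpoint$min_af %||%
                              0.9)
    note("stage breakpoints: %d donor-unique SNPs for '%s'", nrow(uk),
         cfg$breakpoint$donor)
    bps <- lapply(seq_len(nrow(peaks)), function(i)
      delineate_breakpoints(as.data.table(peaks)[i], uk))
    keep <- !vapply(bps, is.null, TRUE)
    breakpoints <- if (any(keep)) rbindlist(lapply(which(keep), function(i)
      data.table(chrom = peaks$chrom[i], start = peaks$start[i],
                 end = peaks$end[i],
                 first_unique_pos = bps[[i]]$first_unique_pos,
                 last_unique_pos = bps[[i]]$last_unique_pos,
                 n_unique = bps[[i]]$n_unique)))
    else data.table()
  }

  smry <- summarize_regions(peaks)
  files <- c(peaks = file.path(out_dir, "peaks.bed"),
             windows = file.path(out_dir,
                                 paste0("windows_", query_id, ".tsv")),
             summary = file.path(out_dir, "summary.tsv"),
             log = file.path(out_dir, "run_log.txt"),
             config = file.path(out_dir, "config_echo.json"))
  write_bed(peaks, files["peaks"])
  write_window_table(counts, files["windows"])
  fwrite(smry, files["summary"], sep = "\t")
  if (!is.null(calib)) {
    files["calibration"] <- file.path(out_dir, "calibration.tsv")
    fwrite(calib, files["calibration"], sep = "\t")
  }
  ev <- attr(peaks, "evidence")
  if (!is.null(ev) && nrow(ev)) {
    files["evidence"] <- file.path(out_dir, "evidence.tsv")
    fwrite(ev, files["evidence"], sep = "\t")
  }
  if (!is.null(breakpoints)) {
    files["breakpoints"] <- file.path(out_dir, "breakpoints.tsv")
    fwrite(breakpoints, files["breakpoints"], sep = "\t")
  }
  jsonlite::write_json(cfg, files["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, files["log"])

  invisible(list(peaks = peaks, counts = counts, summary = smry,
                 calibration = calib, breakpoints = breakpoints,
                 files = files))
}
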