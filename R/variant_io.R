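#' Construct a table of SNP records
#'
#' The internal SNP model: one biallelic single-nucleotide substitution of an
#' accession versus the reference, with read depth and alternate-allele
#' fraction. Positions are 0-based internally; conversion from VCF (1-based)
#' and to BED happens only at I/O boundaries.
#'
#' @param accession_id single text label.
#' @param chrom,pos,ref,alt vectors describing each call (`pos` 0-based).
#' @param depth non-negative integer read depth (`NA` allowed).
#' @param alt_fraction fraction of reads supporting the alternate allele in
#'   `[0, 1]`, or `NA` when the VCF carried no allelic depths.
#' @return A `snp_records` data.table sorted input order, columns
#'   `accession_id, chrom, pos, ref, alt, depth, alt_fraction`.
#' @export
snp_records <- function(accession_id, chrom, pos, ref, alt,
                        depth = NA_integer_, alt_fraction = NA_real_) {
  n <- length(pos)
  dt <- data.table(
    accession_id = rep_len(as.character(accession_id), n),
    chrom = as.character(chrom), pos = as.numeric(pos),
    ref = as.character(ref), alt = as.character(alt),
    depth = rep_len(as.numeric(depth), n),
    alt_fraction = rep_len(as.numeric(alt_fraction), n))
  nuc <- c("A", "C", "G", "T")
  if (n) {
    if (any(!dt$ref %in% nuc) || any(!dt$alt %in% nuc))
      input_error("alleles must be single nucleotides in {A,C,G,T}")
    if (any(dt$ref == dt$alt))
      input_error("ref and alt allele identical at %s:%d",
                  dt$chrom[dt$ref == dt$alt][1],
                  as.integer(dt$pos[dt$ref == dt$alt][1]))
    if (any(dt$pos < 0)) coord_error("negative SNP position")
    if (any(dt$depth < 0, na.rm = TRUE)) input_error("negative depth")
  }
  setattr(dt, "class", c("snp_records", class(dt)))
  dt[]
}

empty_snp_records <- function(accession_id = NA_character_) {
  snp_records(accession_id, character(), numeric(), character(), character())
}

# Collapse duplicate (chrom, pos, alt) keys within one accession, keeping the
# record with highest depth (set semantics for all comparisons).
collapse_snp_keys <- function(snps) {
  dt <- as.data.table(snps)
  if (nrow(dt) == 0) return(snps)
  dt <- dt[order(chrom, pos, alt, -ifelse(is.na(depth), -1, depth))]
  dt <- unique(dt, by = c("chrom", "pos", "alt"))
  setattr(dt, "class", unique(c("snp_records", class(dt))))
  dt[]
}

#' Read biallelic substitution calls from a VCF file
#'
#' Parses a VCF (v4.x, plain or bgzipped) with VariantAnnotation, splits
#' multi-allelic sites into one candidate record per ALT allele, and keeps
#' only single-nucleotide REF/ALT pairs (indels are dropped; the upstream
#' pipeline tallies SNPs and indels separately). Depth is taken from the
#' per-sample `DP` field; the alternate-allele fraction from `AD` as
#' `alt / (ref + alt)` when `AD` is present, else recorded as `NA` (such
#' records later fail the allele-fraction breakpoint filter, by design:
#' frequency must be evidenced). Only records whose FILTER is in
#' `keep_filter` are retained.
#'
#' @param path VCF file path.
#' @param accession_id label attached to every record.
#' @param index a [genome_index()] covering all contigs in the file.
#' @param keep_filter FILTER values accepted (default `PASS` and `.`).
#' @param sample which sample column to use (default first).
#' @return A [snp_records()] table sorted by (index chromosome order, pos),
#'   positions 0-based.
#' @export
read_vcf_snps <- function(path, accession_id, index,
                          keep_filter = c("PASS", "."), sample = 1L) {
  if (!file.exists(path)) input_error("VCF file not found: %s", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) parse_error("malformed VCF %s: %s", path,
                                    conditionMessage(e)))
  if (nrow(vcf) == 0) return(empty_snp_records(accession_id))
  vcf <- tryCatch(VariantAnnotation::expand(vcf), error = function(e)
    parse_error("cannot expand multi-allelic records in %s: %s", path,
                conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0) return(empty_snp_records(accession_id))

  chrom <- as.character(GenomicRanges::seqnames(rr))
  bad <- setdiff(unique(chrom), index$chrom)
  if (length(bad))
    coord_error("record on contig '%s' absent from genome index", bad[1])

  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  filt <- VariantAnnotation::filt(vcf)
  filt[is.na(filt)] <- "."

  g <- VariantAnnotation::geno(vcf)
  depth <- rep(NA_real_, n)
  if ("DP" %in% names(g)) {
    dp <- g$DP
    depth <- as.numeric(if (length(dim(dp)) >= 2) dp[, sample] else dp)
  }
  altfrac <- rep(NA_real_, n)
  if ("AD" %in% names(g)) {
    ad <- g$AD
    if (length(dim(ad)) == 3) {        # expanded Number=R: ref, alt planes
      rd <- as.numeric(ad[, sample, 1]); av <- as.numeric(ad[, sample, 2])
      tot <- rd + av
      altfrac <- ifelse(is.na(tot) | tot == 0, NA_real_, av / tot)
    }
  }

  keep <- filt %in% keep_filter &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  snps <- snp_records(accession_id, chrom[keep],
                      GenomicRanges::start(rr)[keep] - 1, # to 0-based
                      ref[keep], alt[keep],
                      depth[keep], altfrac[keep])
  out <- normalize_snps(snps, index)
  setattr(out, "class", unique(c("snp_records", class(out))))
  out[]
}

#' Read an array-marker genotype table
#'
#' Tab-separated with header `marker_id, chrom, pos, genotype_A, genotype_B`
#' (one genotype column per compared accession). A marker is `polymorphic`
#' when both genotype calls are present and differ, `missing` when either is
#' absent (`--`, `-`, `NA`, `NN` or empty), else `monomorphic`.
#'
#' @param path TSV file path.
#' @param index a [genome_index()].
#' @return data.table `marker_id, chrom, pos, status` sorted by
#'   (chromosome order, pos); `pos` 1-based as in the input.
#' @export
read_marker_table <- function(path, index) {
  if (!file.exists(path)) input_error("marker table not found: %s", path)
  dt <- tryCatch(fread(path, sep = "\t", header = TRUE,
                       colClasses = list(character = c(1, 2))),
                 error = function(e)
                   parse_error("cannot parse marker table %s: %s", path,
                               conditionMessage(e)))
  need <- c("marker_id", "chrom", "pos", "genotype_A", "genotype_B")
  if (!all(need %in% names(dt)))
    parse_error("marker table %s lacks columns: %s", path,
                paste(setdiff(need, names(dt)), collapse = ", "))
  if (anyDuplicated(dt$marker_id))
    input_error("duplicate marker_id: %s",
                dt$marker_id[duplicated(dt$marker_id)][1])
  pos <- suppressWarnings(as.numeric(dt$pos))
  if (anyNA(pos)) parse_error("non-numeric pos in marker table %s", path)
  if (any(pos < 1)) coord_error("marker position < 1")
  is_missing <- function(g) {
    g <- toupper(trimws(as.character(g)))
    is.na(g) | g %in% c("", "-", "--", "NA", "NN", "./.")
  }
  ga <- as.character(dt$genotype_A); gb <- as.character(dt$genotype_B)
  status <- fifelse(is_missing(ga) | is_missing(gb), "missing",
                    fifelse(ga != gb, "polymorphic", "monomorphic"))
  out <- data.table(marker_id = dt$marker_id, chrom = dt$chrom,
                    pos = pos, status = status)
  bad <- setdiff(unique(out$chrom), index$chrom)
  if (length(bad))
    coord_error("marker on contig '%s' absent from genome index", bad[1])
  out[order(match(chrom, index$chrom), pos)]
}

#' Write peak regions as BED6(+1)
#'
#' Columns: chrom, 0-based start, half-open end, name (classification label,
#' `unassigned` when none), score (SNP count capped at 1000 for BED
#' compliance), strand `.`, raw SNP count. Regions must already be sorted by
#' (chromosome, start); a header comment line describes the columns.
#'
#' @param regions peak-region data.table from [call_peaks()] (optionally
#'   carrying an `origin` column from [classify_peaks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  dt <- as.data.table(regions)
  hdr <- "#chrom\tstart\tend\tname\tscore\tstrand\tn_snps"
  if (nrow(dt) == 0) { writeLines(hdr, path); return(invisible(path)) }
  grp <- rleid(dt$chrom)
  if (anyDuplicated(rle(dt$chrom)$values) ||
      any(diff(dt$start) <= 0 & diff(grp) == 0))
    contract_error("regions must be sorted by (chrom, start) and disjoint")
  name <- if ("origin" %in% names(dt)) dt$origin else "unassigned"
  name[is.na(name) | name == ""] <- "unassigned"
  bed <- data.table(dt$chrom, as.integer(dt$start), as.integer(dt$end),
                    name, pmin(as.integer(dt$n_snps), 1000L), ".",
                    as.integer(dt$n_snps))
  writeLines(hdr, path)
  fwrite(bed, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write per-window SNP counts as TSV
#'
#' One row per window including zero-count windows; columns `chrom`,
#' `window_start` (0-based), `window_end` (half-open, truncated at chromosome
#' end), `snp_count`.
#'
#' @param counts a window-counts object from [bin_snps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(counts, path) {
  dt <- counts$windows[, .(chrom, window_start = as.integer(start),
                           window_end = as.integer(end),
                           snp_count = as.integer(count))]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Re-read a window table written by [write_window_table()]
#'
#' Reconstructs the window grid from the table itself (window size = modal
#' width; chromosome length = last window end).
#'
#' @param path TSV path.
#' @param label accession/class label for the counts object.
#' @return a window-counts object (see [bin_snps()]).
#' @export
read_window_table <- function(path, label = NA_character_) {
  if (!file.exists(path)) input_error("window table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = 1))
  need <- c("chrom", "window_start", "window_end", "snp_count")
  if (!all(need %in% names(dt)))
    parse_error("window table %s lacks columns: %s", path,
                paste(setdiff(need, names(dt)), collapse = ", "))
  w <- dt$window_end - dt$window_start
  wsize <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
  lens <- dt[, .(length = max(window_end)), by = chrom]
  grid <- make_grid(genome_index(lens$chrom, lens$length), wsize)
  wc <- list(grid = grid, label = label,
             windows = dt[, .(chrom, window = window_start %/% wsize,
                              start = as.numeric(window_start),
                              end = as.numeric(window_end),
                              count = as.numeric(snp_count))])
  class(wc) <- "window_counts"
  wc
}
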