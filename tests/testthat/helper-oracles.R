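# Independent oracles and fixture builders shared by unit and acceptance
# tests. Oracles are deliberately brute-force and share no code with the
# implementation paths they check.

library(data.table)

# Build a window_counts object from a plain count vector (or named list of
# vectors, one per chromosome). `len` may truncate the final window.
make_counts <- function(counts, W = 10000, len = NULL, label = "test") {
  if (!is.list(counts)) counts <- list(c1 = counts)
  lens <- if (is.null(len)) vapply(counts, length, 0L) * W else len
  grid <- make_grid(genome_index(names(counts), lens), W)
  win <- data.table::copy(grid$windows)
  win[, count := 0]
  for (ch in names(counts))
    win[chrom == ch, count := as.numeric(counts[[ch]])]
  wc <- list(grid = grid, label = label, windows = win[])
  class(wc) <- "window_counts"
  wc
}

# Brute-force peak-caller oracle on one chromosome: enumerate every segment
# between qualifying windows, test the four predicates directly, then keep
# segments not contained in another valid segment.
oracle_peaks_one <- function(cnt, thr, W, min_size, max_gap, chrom_len) {
  n <- length(cnt)
  ends_bp <- pmin(seq_len(n) * W, chrom_len)
  starts_bp <- (seq_len(n) - 1) * W
  qual <- which(cnt >= thr)
  if (!length(qual)) return(NULL)
  cand <- list()
  for (ai in seq_along(qual)) {
    a <- qual[ai]
    for (bi in ai:length(qual)) {
      b <- qual[bi]
      inner <- if (b > a) cnt[a:b] else cnt[a]
      runs <- rle(inner < thr)
      max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
      if (max_run * W > max_gap) next
      span <- ends_bp[b] - starts_bp[a]
      nq <- sum(cnt[a:b] >= thr)
      if (span < min_size || nq < min_size / W) next
      cand[[length(cand) + 1]] <- c(a = a, b = b, nq = nq)
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(cand)), function(i)
    !any(cand[, "a"] <= cand[i, "a"] & cand[, "b"] >= cand[i, "b"] &
           (cand[, "a"] < cand[i, "a"] | cand[, "b"] > cand[i, "b"])),
    TRUE)
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand[, "a"]), , drop = FALSE]
  data.table::data.table(
    start = starts_bp[cand[, "a"]], end = ends_bp[cand[, "b"]],
    n_windows = cand[, "b"] - cand[, "a"] + 1L,
    n_qualifying_windows = as.integer(cand[, "nq"]),
    n_snps = vapply(seq_len(nrow(cand)), function(i)
      sum(cnt[cand[i, "a"]:cand[i, "b"]]), 0),
    gap_bp = (cand[, "b"] - cand[, "a"] + 1L - cand[, "nq"]) * W)
}

# Oracle wrapper matching call_peaks() output columns for a one-chromosome
# window_counts object.
oracle_call_peaks <- function(counts, params) {
  gi <- counts$grid$index
  parts <- lapply(seq_len(nrow(gi)), function(i) {
    sub <- counts$windows[chrom == gi$chrom[i]][order(window)]
    r <- oracle_peaks_one(sub$count, params$min_snps_per_window,
                          params$window_size, params$min_region_size,
                          params$max_gap, gi$length[i])
    if (!is.null(r)) r[, chrom := gi$chrom[i]]
    r
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out)) {
    data.table::setcolorder(out, c("chrom", "start", "end", "n_windows",
                                   "n_qualifying_windows", "n_snps",
                                   "gap_bp"))
  } else {
    out <- data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(),
      n_windows = integer(), n_qualifying_windows = integer(),
      n_snps = numeric(), gap_bp = numeric())
  }
  out[]
}

# Attribute-free data.frame view of a peak table for oracle comparisons.
peaks_df <- function(x) {
  df <- as.data.frame(as.data.table(x))
  attr(df, "params") <- NULL
  rownames(df) <- NULL
  df
}

# Brute-force array-scan oracle: enumerate every set of min_markers
# consecutive polymorphic positions fitting in `span`, merge by union of
# overlapping/bookended intervals, report outermost positions and counts.
oracle_marker_regions <- function(pos, span, min_markers) {
  pos <- sort(pos)
  m <- length(pos)
  if (m < min_markers) return(NULL)
  ivs <- list()
  for (i in seq_len(m - min_markers + 1)) {
    j <- i + min_markers - 1
    if (pos[j] - pos[i] <= span)
      ivs[[length(ivs) + 1]] <- c(pos[i], pos[j])
  }
  if (!length(ivs)) return(NULL)
  ivs <- do.call(rbind, ivs)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  merged <- list(ivs[1, ])
  for (k in seq_len(nrow(ivs))[-1]) {
    last <- merged[[length(merged)]]
    if (ivs[k, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], ivs[k, 2]))
    } else merged[[length(merged) + 1]] <- ivs[k, ]
  }
  do.call(rbind, lapply(merged, function(iv)
    data.frame(start = iv[1], end = iv[2],
               n_polymorphic = sum(pos >= iv[1] & pos <= iv[2]))))
}

# Random snp_records on one chromosome for set-algebra tests.
random_snps <- function(n, accession = "acc", chrom = "c1", len = 1e6,
                        depth = NULL, alt_fraction = NULL) {
  pos <- sample.int(len, n) - 1
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), "")
  snp_records(accession, rep(chrom, n), pos, ref, alt,
              depth %||% sample(5:40, n, replace = TRUE),
              alt_fraction %||% runif(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hand-written VCF fixture for I/O tests.
write_toy_vcf <- function(path, lines, sample_id = "S1",
                          contigs = c(c1 = 100000)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  writeLines(c(hdr, lines), path)
  path
}
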