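#' Define a comparison-panel accession
#'
#' @param accession_id text label.
#' @param role `"donor"` (a wild species suspected as introgression source)
#'   or `"heirloom"` (an introgression-free domesticated line whose shared
#'   SNPs implicate the reference genome itself).
#' @param snps the accession's [snp_records()] versus the same reference.
#' @return A `panel_accession` list.
#' @export
panel_accession <- function(accession_id, role = c("donor", "heirloom"),
                            snps) {
  role <- match.arg(role)
  p <- list(accession_id = as.character(accession_id), role = role,
            snps = snps)
  class(p) <- "panel_accession"
  p
}

#' Per-window shared-SNP matches between a peak and a comparison panel
#'
#' For every panel accession and every window inside the peak, counts the
#' SNP keys the query shares with that accession in the window; the window
#' "matches" the accession when the count reaches `match_min` (default 10
#' shared SNPs per 10-kb window, the same boundary as the peak rule).
#'
#' @param query the query accession's [snp_records()].
#' @param panel list of [panel_accession()] objects.
#' @param peak one row of a `peak_regions` table (data.frame/list with
#'   `chrom`, `start`, `end`).
#' @param grid the [make_grid()] grid the peak was called on.
#' @param match_min inclusive shared-SNP count for a window match.
#' @return list with `windows` (window starts), and per accession `shared`
#'   (counts per window), `matched` (logical per window), plus `roles`.
#' @export
match_windows_to_panel <- function(query, panel, peak, grid, match_min = 10) {
  if (match_min < 1) param_error("match_min must be >= 1")
  W <- grid$window_size
  win <- grid$windows[chrom == peak$chrom & start >= peak$start &
                        start < peak$end]
  if (nrow(win) == 0)
    coord_error("peak [%s:%g-%g) lies outside the window grid",
                peak$chrom, peak$start, peak$end)
  qk <- snp_keys(query)[chrom == peak$chrom & pos >= peak$start &
                          pos < peak$end]
  ids <- vapply(panel, `[[`, "", "accession_id")
  if (anyDuplicated(ids)) input_error("duplicate panel accession_id")
  res <- lapply(panel, function(acc) {
    sk <- merge(qk, snp_keys(acc$snps), by = c("chrom", "pos", "alt"))
    cnt <- rep(0, nrow(win))
    if (nrow(sk)) {
      tab <- sk[, .N, by = .(window = pos %/% W)]
      idx <- match(tab$window, win$window)
      cnt[idx[!is.na(idx)]] <- tab$N[!is.na(idx)]
    }
    list(shared = cnt, matched = cnt >= match_min)
  })
  names(res) <- ids
  list(windows = win$start, window_size = W, chrom = peak$chrom,
       accessions = res,
       roles = setNames(vapply(panel, `[[`, "", "role"), ids))
}

#' Assign an origin label to a peak from its panel match map
#'
#' A peak is labeled `reference_introgression` when the heirloom's matched-
#' window fraction reaches `majority_fraction` (shared SNPs with an
#' introgression-free heirloom implicate wild sequence in the reference
#' itself, and take precedence over donor evidence at equal support);
#' otherwise `donor:<id>` for the unique donor with the highest matched
#' fraction at or above `majority_fraction`; ties between top donors, or no
#' accession reaching the majority, yield `unknown`. Subsegments — maximal
#' runs of windows sharing a per-window label (heirloom-matched before
#' donor-matched before unlabeled) — tile the peak and expose mixed regions
#' such as donor introgressions with embedded reference-derived fragments.
#'
#' @param peak one peak-region row.
#' @param match_map output of [match_windows_to_panel()].
#' @param majority_fraction matched-window fraction required (default 0.5).
#' @return An `origin_call` list: `label`, `window_match_fractions`,
#'   `matched_windows`, `snp_match_fractions` and `subsegments`.
#' @export
assign_origin <- function(peak, match_map, majority_fraction = 0.5) {
  accs <- match_map$accessions
  if (!length(accs)) contract_error("empty match map")
  n_win <- length(match_map$windows)
  ids <- names(accs)
  roles <- match_map$roles[ids]
  frac <- vapply(accs, function(a) mean(a$matched), 0)
  nmatch <- vapply(accs, function(a) sum(a$matched), 0L)
  tot_shared <- vapply(accs, function(a) sum(a$shared), 0)
  snp_frac <- if (sum(tot_shared) > 0) tot_shared / max(tot_shared) else
    tot_shared

  heir <- ids[roles == "heirloom"]
  don <- ids[roles == "donor"]
  label <- "unknown"
  if (length(heir) && max(frac[heir]) >= majority_fraction) {
    label <- "reference_introgression"
  } else if (length(don)) {
    top <- max(frac[don])
    if (top >= majority_fraction) {
      winners <- sort(don[frac[don] == top])
      if (length(winners) == 1) label <- paste0("donor:", winners)
    }
  }

  # per-window labels: heirloom precedence, then best donor (alphabetical on
  # ties so the result is invariant to panel ordering), else unlabeled
  win_lab <- rep("unlabeled", n_win)
  if (length(don)) {
    dshared <- vapply(sort(don), function(d) accs[[d]]$shared,
                      numeric(n_win))
    dmatch <- vapply(sort(don), function(d) accs[[d]]$matched,
                     logical(n_win))
    dshared <- matrix(dshared, nrow = n_win)
    dmatch <- matrix(dmatch, nrow = n_win)
    any_d <- apply(dmatch, 1, any)
    best <- apply(ifelse(dmatch, dshared, -Inf), 1, which.max)
    win_lab[any_d] <- paste0("donor:", sort(don)[best[any_d]])
  }
  if (length(heir)) {
    hmatch <- Reduce(`|`, lapply(heir, function(h) accs[[h]]$matched))
    win_lab[hmatch] <- "heirloom"
  }
  r <- rle(win_lab)
  ends <- cumsum(r$lengths)
  starts_i <- c(1, head(ends, -1) + 1)
  W <- match_map$window_size
  subsegments <- data.table(
    start = match_map$windows[starts_i],
    end = pmin(match_map$windows[ends] + W, peak$end),
    label = r$values)

  out <- list(label = label,
              window_match_fractions = frac,
              matched_windows = nmatch,
              snp_match_fractions = snp_frac,
              subsegments = subsegments)
  class(out) <- "origin_call"
  out
}

#' Classify every peak of a region table against a panel
#'
#' Convenience wrapper running [match_windows_to_panel()] and
#' [assign_origin()] per peak.
#'
#' @inheritParams match_windows_to_panel
#' @inheritParams assign_origin
#' @param peaks a `peak_regions` table.
#' @return the peaks table with an `origin` label column added, plus an
#'   `origin_calls` attribute (list of `origin_call` objects) and an
#'   `evidence` attribute (long data.table of per-accession fractions).
#' @export
classify_peaks <- function(peaks, query, panel, grid, match_min = 10,
                           majority_fraction = 0.5) {
  peaks <- copy(as.data.table(peaks))
  calls <- vector("list", nrow(peaks))
  ev <- list()
  labs <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    mm <- match_windows_to_panel(query, panel, peaks[i], grid, match_min)
    oc <- assign_origin(peaks[i], mm, majority_fraction)
    calls[[i]] <- oc
    labs[i] <- oc$label
    ev[[i]] <- data.table(chrom = peaks$chrom[i], start = peaks$start[i],
                          end = peaks$end[i],
                          accession_id = names(oc$window_match_fractions),
                          role = unname(mm$roles),
                          window_match_fraction =
                            unname(oc$window_match_fractions),
                          matched_windows = unname(oc$matched_windows))
  }
  peaks[, origin := labs]
  setattr(peaks, "origin_calls", calls)
  setattr(peaks, "evidence",
          if (length(ev)) rbindlist(ev) else data.table())
  setattr(peaks, "class", c("peak_regions", class(peaks)))
  peaks[]
}

#' Delineate introgression breakpoints from donor-unique SNPs
#'
#' Restricts a donor-unique SNP key set (see [unique_donor_snps()]) to the
#' peak interval and reports the first and last positions, 1-based for
#' reporting, with the count of unique SNPs inside; `NULL` when no unique
#' key falls inside the peak.
#'
#' @param peak one peak-region row (`chrom`, `start`, `end`).
#' @param unique_keys data.table of keys (`chrom, pos, alt`), 0-based.
#' @return list `(chrom, first_unique_pos, last_unique_pos, n_unique)` or
#'   `NULL`.
#' @export
delineate_breakpoints <- function(peak, unique_keys) {
  k <- as.data.table(unique_keys)[chrom == peak$chrom & pos >= peak$start &
                                    pos < peak$end]
  if (nrow(k) == 0) return(NULL)
  list(chrom = peak$chrom,
       first_unique_pos = min(k$pos) + 1,
       last_unique_pos = max(k$pos) + 1,
       n_unique = nrow(k))
}
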