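# Builders for a peak plus panel with controlled per-window sharing: donor
# windows get `n_shared` SNPs copied from the query.
build_case <- function(shared_per_window, W = 10000) {
  n_win <- length(shared_per_window[[1]])
  len <- n_win * W
  grid <- make_grid(genome_index("c1", len), W)
  # exactly 15 query SNPs per window at fixed offsets
  pos <- as.vector(outer((0:14) * 100, (seq_len(n_win) - 1) * W, `+`))
  q <- snp_records("q", rep("c1", length(pos)), sort(pos), "C", "A")
  peak <- data.table(chrom = "c1", start = 0, end = len)
  panel_snps <- lapply(shared_per_window, function(spw)
    rbindlist(lapply(seq_len(n_win), function(w)
      q[pos >= (w - 1) * W & pos < w * W][seq_len(spw[w])])))
  list(query = q, peak = peak, grid = grid, panel_snps = panel_snps)
}

test_that("match_windows_to_panel counts shared SNPs per window against match_min", {
  cs <- build_case(list(A = c(12, 9, 12, 0), H = c(0, 0, 12, 0)))
  panel <- list(panel_accession("A", "donor", cs$panel_snps$A),
                panel_accession("H", "heirloom", cs$panel_snps$H))
  mm <- match_windows_to_panel(cs$query, panel, cs$peak, cs$grid,
                               match_min = 10)
  expect_equal(mm$accessions$A$matched, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(mm$accessions$H$matched, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(mm$accessions$A$shared, c(12, 9, 12, 0))
  # a window can match donor and heirloom simultaneously
  expect_true(mm$accessions$A$matched[3] && mm$accessions$H$matched[3])
  # peak outside grid
  off <- data.table(chrom = "c1", start = 1e9, end = 2e9)
  expect_error(match_windows_to_panel(cs$query, panel, off, cs$grid),
               class = "introscan_coord_error")
})

# construct a match map directly (assign_origin contracts on the map itself)
mk_map <- function(matched, roles, shared = NULL, W = 10000) {
  n <- if (length(matched)) length(matched[[1]]) else 0L
  accs <- lapply(names(matched), function(id)
    list(shared = (shared %||% lapply(matched, function(m) m * 12))[[id]],
         matched = as.logical(matched[[id]])))
  names(accs) <- names(matched)
  list(windows = (seq_len(n) - 1) * W, window_size = W, chrom = "c1",
       accessions = accs, roles = setNames(roles, names(matched)))
}

test_that("assign_origin applies heirloom precedence, majority and tie rules", {
  peak <- list(chrom = "c1", start = 0, end = 1e5)
  m <- mk_map(list(H = rep(c(TRUE, FALSE), c(9, 1)),
                   P = rep(c(TRUE, FALSE), c(1, 9))),
              c("heirloom", "donor"))
  expect_equal(assign_origin(peak, m)$label, "reference_introgression")

  m <- mk_map(list(P = rep(c(TRUE, FALSE), c(8, 2)),
                   H = rep(FALSE, 10)), c("donor", "heirloom"))
  expect_equal(assign_origin(peak, m)$label, "donor:P")

  m <- mk_map(list(A = rep(c(TRUE, FALSE), c(6, 4)),
                   B = rep(c(FALSE, TRUE), c(4, 6)),
                   H = rep(FALSE, 10)),
              c("donor", "donor", "heirloom"))
  expect_equal(assign_origin(peak, m)$label, "unknown")   # top-donor tie

  m <- mk_map(list(A = rep(FALSE, 10), H = rep(FALSE, 10)),
              c("donor", "heirloom"))
  expect_equal(assign_origin(peak, m)$label, "unknown")

  # heirloom precedence at equal fractions
  m <- mk_map(list(A = rep(TRUE, 10), H = rep(TRUE, 10)),
              c("donor", "heirloom"))
  expect_equal(assign_origin(peak, m)$label, "reference_introgression")

  expect_error(assign_origin(peak, mk_map(list(), character())),
               class = "introscan_contract_error")
})

test_that("assign_origin is invariant to panel ordering and its subsegments tile the peak", {
  set.seed(83)
  for (trial in 1:25) {
    n <- sample(5:30, 1)
    ids <- c("A", "B", "H")
    roles <- c("donor", "donor", "heirloom")
    matched <- lapply(ids, function(i) runif(n) < runif(1))
    shared <- lapply(seq_along(ids), function(i)
      ifelse(matched[[i]], sample(10:30, n, TRUE), sample(0:9, n, TRUE)))
    names(matched) <- names(shared) <- ids
    peak <- list(chrom = "c1", start = 0, end = n * 10000)
    m1 <- mk_map(matched, roles, shared)
    oc1 <- assign_origin(peak, m1)
    perm <- sample(3)
    m2 <- mk_map(matched[perm], roles[perm], shared[perm])
    oc2 <- assign_origin(peak, m2)
    expect_equal(oc1$label, oc2$label)
    expect_equal(oc1$window_match_fractions[ids],
                 oc2$window_match_fractions[ids])
    expect_equal(oc1$subsegments, oc2$subsegments)

    segs <- oc1$subsegments
    expect_equal(segs$start[1], 0)
    expect_equal(segs$end[nrow(segs)], peak$end)
    if (nrow(segs) > 1)
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
    # per-window label consistency with the map (heirloom precedence)
    for (k in seq_len(nrow(segs))) {
      w <- which(m1$windows >= segs$start[k] & m1$windows < segs$end[k])
      lab <- segs$label[k]
      if (lab == "heirloom") expect_true(all(matched$H[w]))
      else expect_true(all(!matched$H[w]))
      if (startsWith(lab, "donor:"))
        expect_true(all(matched[[sub("donor:", "", lab)]][w]))
      if (lab == "unlabeled")
        expect_true(all(!matched$A[w] & !matched$B[w] & !matched$H[w]))
    }
  }
})

test_that("delineate_breakpoints reports 1-based extremes inside the peak", {
  keys <- data.table(chrom = "c1", pos = c(99, 4999, 60999),
                     alt = c("A", "T", "G"))
  peak <- list(chrom = "c1", start = 0, end = 50000)
  bp <- delineate_breakpoints(peak, keys)
  expect_equal(bp$first_unique_pos, 100)
  expect_equal(bp$last_unique_pos, 5000)
  expect_equal(bp$n_unique, 2)

  expect_null(delineate_breakpoints(list(chrom = "c1", start = 70000,
                                         end = 130000), keys))

  set.seed(89)
  for (trial in 1:10) {
    k <- data.table(chrom = "c1", pos = sample.int(1e6, 1000) - 1,
                    alt = "A")
    s <- sort(sample.int(1e6, 2)) - 1
    peak <- list(chrom = "c1", start = s[1], end = s[2])
    inside <- k$pos[k$pos >= s[1] & k$pos < s[2]]     # linear-scan oracle
    bp <- delineate_breakpoints(peak, k)
    if (length(inside) == 0) expect_null(bp)
    else {
      expect_equal(bp$first_unique_pos, min(inside) + 1)
      expect_equal(bp$last_unique_pos, max(inside) + 1)
      expect_equal(bp$n_unique, length(inside))
      expect_gte(bp$first_unique_pos, peak$start + 1)
      expect_lte(bp$last_unique_pos, peak$end)
    }
  }
})
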