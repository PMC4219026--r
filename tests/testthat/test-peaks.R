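test_that("peak_params enforces its invariants", {
  expect_error(peak_params(max_gap = 50000), class = "introscan_param_error")
  expect_error(peak_params(max_gap = 45000), class = "introscan_param_error")
  expect_error(peak_params(window_size = -1), class = "introscan_param_error")
  p <- peak_params()
  expect_equal(p$min_snps_per_window, 10)
  expect_equal(p$min_region_size, 50000)
  expect_equal(p$max_gap, 40000)
})

test_that("call_peaks reproduces the fixed density/size/gap examples", {
  # minimal qualifying run
  pk <- call_peaks(make_counts(c(12, 15, 11, 10, 13)))
  expect_equal(as.data.frame(pk[, .(start, end, n_qualifying_windows,
                                    gap_bp)]),
               data.frame(start = 0, end = 50000,
                          n_qualifying_windows = 5L, gap_bp = 0))
  # one 40-kb interior gap is tolerated
  pk <- call_peaks(make_counts(c(12, 0, 0, 0, 0, 13, 11, 10, 15)))
  expect_equal(as.data.frame(pk[, .(start, end, gap_bp)]),
               data.frame(start = 0, end = 90000, gap_bp = 40000))
  # a 50-kb gap splits; the 1-window left fragment fails min size
  pk <- call_peaks(make_counts(c(12, 0, 0, 0, 0, 0, 13, 11, 10, 15, 11)))
  expect_equal(as.data.frame(pk[, .(start, end)]),
               data.frame(start = 60000, end = 110000))
  # threshold is inclusive ">= 10", so all-9 counts yield nothing
  expect_equal(nrow(call_peaks(make_counts(rep(9, 60)))), 0)
  # window-size mismatch
  expect_error(call_peaks(make_counts(rep(12, 10), W = 5000)),
               class = "introscan_param_error")
})

test_that("call_peaks equals the brute-force maximal-segment oracle on random vectors", {
  set.seed(53)
  params <- peak_params()
  for (trial in 1:150) {
    n <- sample(20:120, 1)
    cnt <- ifelse(runif(n) < 0.12, rpois(n, 30), rpois(n, 0.4))
    len <- n * 10000 - sample(c(0, 3210), 1)
    wc <- make_counts(cnt, len = len)
    expect_equal(peaks_df(call_peaks(wc, params)),
                 peaks_df(oracle_call_peaks(wc, params)),
                 info = sprintf("trial %d", trial))
  }
})

test_that("raising the threshold never enlarges peaks (monotonicity)", {
  set.seed(59)
  for (trial in 1:20) {
    n <- sample(30:100, 1)
    cnt <- ifelse(runif(n) < 0.2, rpois(n, 25), rpois(n, 2))
    wc <- make_counts(cnt)
    lo <- call_peaks(wc, peak_params(min_snps_per_window = 8))
    hi <- call_peaks(wc, peak_params(min_snps_per_window = 14))
    expect_lte(sum(hi$end - hi$start), sum(lo$end - lo$start))
    expect_lte(sum(hi$n_qualifying_windows), sum(lo$n_qualifying_windows))
    # every high-threshold peak is contained in a low-threshold peak
    for (i in seq_len(nrow(hi)))
      expect_true(any(lo$start <= hi$start[i] & lo$end >= hi$end[i]))
  }
})

test_that("peaks are disjoint, sorted, and idempotent under restriction", {
  set.seed(61)
  for (trial in 1:20) {
    n <- sample(40:120, 1)
    cnt <- ifelse(runif(n) < 0.15, rpois(n, 30), rpois(n, 0.4))
    wc <- make_counts(cnt)
    pk <- call_peaks(wc)
    if (nrow(pk) > 1) {
      expect_true(all(diff(pk$start) > 0))
      expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
    }
    # idempotence: zero out everything outside one peak, recall
    for (i in seq_len(nrow(pk))) {
      cnt2 <- rep(0, n)
      w0 <- pk$start[i] %/% 10000 + 1
      w1 <- (pk$end[i] - 1) %/% 10000 + 1
      cnt2[w0:w1] <- cnt[w0:w1]
      again <- call_peaks(make_counts(cnt2, len = wc$grid$index$length))
      expect_equal(nrow(again), 1)
      expect_equal(peaks_df(again), peaks_df(pk[i]))
    }
  }
})

test_that("nonpeak_window_counts returns exactly the uncovered windows", {
  wc <- make_counts(c(1, 2, 30, 30, 30, 30, 30, 3, 4, 5))
  expect_equal(nonpeak_window_counts(wc, call_peaks(wc)[0]),
               wc$windows$count)
  pk <- call_peaks(wc, peak_params(min_snps_per_window = 10))
  expect_equal(pk$start, 20000)
  expect_equal(nonpeak_window_counts(wc, pk), c(1, 2, 3, 4, 5))
  all_cov <- make_counts(rep(20, 10))
  expect_length(nonpeak_window_counts(all_cov, call_peaks(all_cov)), 0)
})

test_that("calibrate_threshold computes the Student t-test the oracle way", {
  # no window reaches any candidate: identical samples, t = 0, p = 1
  wc <- make_counts(rep(1, 100))
  rows <- calibrate_threshold(wc, candidates = c(3, 5, 10, 15, 20))
  expect_equal(rows$candidate_threshold, c(3, 5, 10, 15, 20))
  expect_equal(rows$t_statistic, rep(0, 5))
  expect_equal(rows$p_value, rep(1, 5))

  # planted excess: 990 background windows + 10 windows of 50
  set.seed(67)
  bg <- rpois(990, 0.4)
  cnt <- c(bg[1:500], rep(50, 10), bg[501:990])
  wc <- make_counts(cnt)
  rows <- calibrate_threshold(wc, candidates = 10)
  expect_false(rows$degenerate)
  expect_gt(rows$genome_mean, rows$nonpeak_mean)
  expect_lt(rows$p_value, 0.05)
  # oracle: direct t-test between the two known samples
  oracle <- t.test(cnt, bg, var.equal = TRUE)
  expect_equal(rows$p_value, oracle$p.value)
  expect_equal(rows$t_statistic, unname(oracle$statistic))

  # excluded chromosomes are removed from both samples
  wc2 <- make_counts(list(c1 = cnt, c2 = rep(40, 20)))
  rows2 <- calibrate_threshold(wc2, candidates = 10,
                               exclude_chroms = "c2")
  expect_equal(rows2$p_value, oracle$p.value)
  expect_equal(rows2$excluded_chromosomes, "c2")

  # degenerate: every window inside a peak
  wc3 <- make_counts(rep(30, 20))
  rows3 <- calibrate_threshold(wc3, candidates = 10)
  expect_true(rows3$degenerate)
  expect_true(is.na(rows3$p_value))
})

test_that("recommend_threshold picks the smallest significant candidate", {
  rows <- data.table::data.table(
    candidate_threshold = c(3, 5, 10, 15, 20),
    genome_mean = 2, nonpeak_mean = c(2, 2, 1, 1, 1),
    t_statistic = 1, p_value = c(0.8, 0.4, 0.01, 0.02, 0.03),
    degenerate = FALSE)
  expect_equal(recommend_threshold(rows), 10L)
  rows$p_value <- 1
  expect_true(is.na(recommend_threshold(rows)))
  one <- rows[3][, p_value := 0.001]
  expect_equal(recommend_threshold(one), 10L)
  rows$degenerate <- TRUE
  expect_warning(out <- recommend_threshold(rows), "degenerate")
  expect_true(is.na(out))
  expect_error(recommend_threshold(rows[0]), class = "introscan_param_error")
  expect_error(recommend_threshold(rows, alpha = 2),
               class = "introscan_param_error")
})

test_that("on homogeneous sub-threshold counts no threshold is recommended", {
  set.seed(71)
  none <- 0L
  for (rep in 1:20) {
    wc <- make_counts(rpois(2000, 0.4))
    rec <- suppressWarnings(recommend_threshold(calibrate_threshold(wc)))
    none <- none + is.na(rec)
  }
  expect_gte(none, 19)
})
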