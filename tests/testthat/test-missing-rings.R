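test_that("apply_missing inserts zeros without touching measurements", {
  s <- ring_series(seq(0.1, 1, by = 0.1), first_year = 2000)
  out <- apply_missing(s, c(3L, 7L))
  expect_length(out$widths, 12L)
  expect_identical(out$widths[c(3, 8)], c(0, 0))
  expect_identical(out$ring_flags[c(3, 8)],
                   rep("missing_inserted", 2))
  # conservation: measured widths unchanged, in order
  expect_identical(out$widths[out$ring_flags == "measured"], s$widths)
  expect_identical(sum(out$ring_flags == "measured"), 10L)
})

test_that("boundary insertions adjust the span correctly", {
  s <- ring_series(rep(0.2, 5), first_year = 2000)
  out <- apply_missing(s, c(1L, 6L))
  expect_length(out$widths, 7L)
  # an insertion before ring 1 moves the first year one back
  expect_identical(out$first_year, 1999L)
  expect_identical(calendar_span(out), c(1999L, 2005L))
  expect_identical(out$ring_flags[c(1, 7)], rep("missing_inserted", 2))
  expect_identical(apply_missing(s, integer(0)), s)
  expect_error(apply_missing(s, c(2L, 2L)), "duplicate")
  expect_error(apply_missing(s, 9L), "1\\.\\.6")
})

test_that("a clean dated series produces an all-lag-zero scan", {
  d <- make_disk_pair(101)
  sc <- segment_lag_scan(d$b, index_series(d$a))
  expect_true(all(sc$best_lag == 0L, na.rm = TRUE))
  expect_false(any(sc$flagged))
})

test_that("one deletion splits the scan into lag 0 before, lag 1 after", {
  d <- make_disk_pair(102)
  bdel <- delete_rings(d$b, 150L)
  sc <- segment_lag_scan(bdel, index_series(d$a))
  full <- sc[sc$end - sc$start + 1L == 50L, ]
  expect_true(all(full$best_lag[full$end < 150] == 0L))
  expect_true(all(full$best_lag[full$start > 150] == 1L))
  expect_true(any(sc$flagged))
})

test_that("a series shorter than one segment is scanned whole with warning", {
  d <- make_disk_pair(103, L = 30L)
  expect_warning(sc <- segment_lag_scan(d$b, index_series(d$a),
                                        segment_len = 50), "whole")
  expect_identical(nrow(sc), 1L)
})

test_that("a series needing no insertions gets an empty hypothesis", {
  d <- make_disk_pair(104)
  mh <- propose_missing(d$b, index_series(d$a), max_missing = 3)
  expect_length(mh$positions, 0L)
  expect_identical(mh$score_after, mh$score_before)
})

test_that("a planted deletion is recovered close to its position", {
  hits <- 0L
  for (seed in 111:120) {
    d <- make_disk_pair(seed)
    set.seed(seed)
    del <- sample(15:285, 1L)
    mh <- propose_missing(delete_rings(d$b, del), index_series(d$a),
                          max_missing = 3)
    if (length(mh$positions) == 1L && abs(mh$positions - del) <= 1L)
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("an accepted hypothesis reproduces its score through slide_date", {
  d <- make_disk_pair(105)
  del <- 140L
  bdel <- delete_rings(d$b, del)
  ref <- index_series(d$a)
  mh <- propose_missing(bdel, ref, max_missing = 3)
  expect_gte(mh$score_after, mh$score_before)
  fixed <- apply_missing(bdel, mh$positions)
  fixed$first_year <- mh$anchored_first_year + sum(mh$positions == 1L)
  res <- slide_date(index_series(fixed), ref, min_overlap = 30)
  expect_identical(res$candidate_first_year[1], fixed$first_year)
  expect_equal(res$tvalue[1], mh$score_after, tolerance = 1e-8)
})

test_that("propose_missing validates its inputs", {
  d <- make_disk_pair(106, L = 80L)
  und <- undate(d$b)
  expect_error(propose_missing(und, index_series(d$a)), "dated")
  expect_error(propose_missing(d$b, index_series(undate(d$a))), "dated")
  expect_error(propose_missing(d$b, index_series(d$a), max_missing = -1),
               ">= 0")
})
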