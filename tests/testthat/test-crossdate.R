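test_that("GLK scores the hand-enumerated sign example", {
  # difference signs a = +,+,-,+ vs b = +,-,-,+ : agree, disagree, agree,
  # agree -> scores 1,0,1,1 -> mean 0.75
  a <- indexed_series(cumsum(c(0, 1, 1, -1, 1)))
  b <- indexed_series(cumsum(c(0, 1, -1, -1, 1)))
  expect_equal(glk(a, b, offset = 0), 0.75)
})

test_that("GLK is 1 against itself, 0 against the inverted series", {
  set.seed(3)
  x <- stats::rnorm(40)
  a <- indexed_series(x)
  expect_equal(glk(a, a, offset = 0), 1)
  expect_equal(glk(a, indexed_series(-x + 100), offset = 0), 0)
})

test_that("GLK stays in [0,1] and is symmetric under offset reversal", {
  set.seed(9)
  for (i in 1:15) {
    a <- indexed_series(stats::rnorm(30))
    b <- indexed_series(stats::rnorm(25))
    k <- sample(-10:10, 1)
    g1 <- glk(a, b, offset = k)
    g2 <- glk(b, a, offset = -k)
    if (!is.na(g1)) {
      expect_gte(g1, 0); expect_lte(g1, 1)
      expect_equal(g1, g2)
    }
  }
})

test_that("ties in either difference score one half", {
  a <- indexed_series(c(1, 1, 2))   # diffs: 0, +
  b <- indexed_series(c(1, 2, 3))   # diffs: +, +
  expect_equal(glk(a, b, offset = 0), 0.75)  # (0.5 + 1) / 2
})

test_that("overlap_corr returns r with its overlap and guards degeneracy", {
  set.seed(5)
  a <- indexed_series(stats::rnorm(100), first_year = 1900)
  self <- overlap_corr(a, a, min_overlap = 50)
  expect_equal(self$r, 1)
  expect_identical(self$n, 100L)
  # insufficient overlap is an undefined result, not a number
  short <- overlap_corr(a, a, offset = 80, min_overlap = 50)
  expect_true(is.na(short$r))
  expect_identical(short$n, 20L)
  # zero variance window
  cst <- indexed_series(rep(1, 100), first_year = 1900)
  expect_true(is.na(overlap_corr(cst, a, min_overlap = 50)$r))
})

test_that("the t-value follows the textbook transform and its monotonicity", {
  expect_equal(bp_tvalue(0.5, 100), 0.5 * sqrt(98) / sqrt(0.75))
  expect_equal(round(bp_tvalue(0.5, 100), 3), 5.715)
  expect_identical(bp_tvalue(0, 50), 0)
  expect_gt(bp_tvalue(0.6, 100), bp_tvalue(0.4, 100))
  expect_gt(bp_tvalue(0.4, 200), bp_tvalue(0.4, 100))
  expect_lt(bp_tvalue(-0.5, 100), 0)
  expect_error(bp_tvalue(0.5, 2), "n > 2")
  expect_warning(t1 <- bp_tvalue(1, 50), "sentinel")
  expect_identical(t1, 1e6)
})

test_that("slide_date recovers an exact slice at rank 1 with r = 1", {
  set.seed(21)
  ref <- indexed_series(stats::rnorm(800), first_year = 1100)
  slice <- indexed_series(ref$index[301:600])
  res <- slide_date(slice, ref, min_overlap = 50)
  expect_identical(res$candidate_first_year[1], 1400L)
  expect_equal(res$corr[1], 1)
  expect_equal(res$glk[1], 1)
  expect_true(res$significant[1])
})

test_that("slide_date is translation consistent", {
  set.seed(22)
  ref <- indexed_series(stats::rnorm(300), first_year = 1500)
  x <- indexed_series(stats::rnorm(120))
  r1 <- slide_date(x, ref, min_overlap = 60)
  ref2 <- ref; ref2$first_year <- ref$first_year + 37L
  r2 <- slide_date(x, ref2, min_overlap = 60)
  expect_identical(r2$candidate_first_year, r1$candidate_first_year + 37L)
  expect_equal(r2$tvalue, r1$tvalue)
  expect_equal(r2$glk, r1$glk)
})

test_that("a dated series slid against itself picks offset zero", {
  set.seed(23)
  a <- indexed_series(stats::rnorm(200), first_year = 1700)
  res <- slide_date(a, a, min_overlap = 50)
  expect_identical(res$candidate_first_year[1], 1700L)
  expect_equal(res$corr[1], 1)
})

test_that("a reference shorter than the minimum overlap yields empty + status", {
  ref <- indexed_series(stats::rnorm(30), first_year = 2000)
  x <- indexed_series(stats::rnorm(100))
  res <- slide_date(x, ref, min_overlap = 50)
  expect_identical(nrow(res), 0L)
  expect_match(attr(res, "status"), "minimum overlap")
})

test_that("ranking is by t, then GLK, then overlap, deterministic", {
  set.seed(24)
  ref <- indexed_series(stats::rnorm(400), first_year = 1000)
  x <- indexed_series(stats::rnorm(150))
  res <- slide_date(x, ref, min_overlap = 60)
  expect_identical(res$rank, seq_len(nrow(res)))
  o <- order(-res$tvalue, -res$glk, -res$overlap_n,
             abs(res$candidate_first_year), na.last = TRUE)
  expect_identical(o, seq_len(nrow(res)))
})
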