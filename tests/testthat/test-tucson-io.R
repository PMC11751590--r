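test_that("a hand-decoded decadal block reads back correctly", {
  lines <- c("TEST0001 1994   100   120    90    85    60    40",
             "TEST0001 2000    55    70     0    95   110    33   999")
  s <- read_tucson(lines)
  expect_length(s, 1L)
  s <- s[[1L]]
  expect_identical(s$series_id, "TEST0001")
  expect_identical(s$first_year, 1994L)
  expect_length(s$widths, 12L)
  # hundredths dialect: integers / 100
  expect_equal(s$widths[1:3], c(1.00, 1.20, 0.90))
  # value 0 at position 9 is a missing ring
  expect_identical(s$ring_flags[9], "missing_inserted")
  expect_identical(s$widths[9], 0)
})

test_that("the -9999 stop marker selects the thousandths dialect", {
  lines <- c("THOU0001 1998   123   456",
             "THOU0001 2000   789 -9999")
  s <- read_tucson(lines)[[1L]]
  expect_equal(s$widths, c(0.123, 0.456, 0.789))
})

test_that("parse errors name the problem", {
  # broken decade arithmetic (gap)
  expect_error(read_tucson(c("AAAA0001 1990 10 20 30 40 50 60 70 80 90 11",
                             "AAAA0001 2010 10 999")), "decade arithmetic")
  # missing stop marker
  expect_error(read_tucson(c("AAAA0001 1990 10 20 30")), "stop marker")
  # a site header of up to 3 lines is tolerated, more unparseable lines not
  hdr <- c("SITE Somewhere 68N 19E", "SITE Juniperus communis",
           "SITE measured 2020", "AAAA0001 2000 10 20 30 999")
  expect_length(read_tucson(hdr), 1L)
})

test_that("write_tucson refuses undated series and id collisions", {
  expect_error(write_tucson(ring_series(c(0.1, 0.2))), "undated")
  a <- ring_series(rep(0.1, 3), first_year = 2000, series_id = "LONGNAME01")
  b <- ring_series(rep(0.1, 3), first_year = 2000, series_id = "LONGNAME02")
  expect_error(write_tucson(list(a, b)), "collide")
})

test_that("sub-quantum widths are floored to one quantum, never zero", {
  s <- ring_series(c(0.005, 0.5), first_year = 2000, series_id = "TINY")
  back <- read_tucson(write_tucson(s))[[1L]]
  expect_identical(back$ring_flags, c("measured", "measured"))
  expect_identical(back$widths[1], 0.01)
})

test_that("Tucson round-trip is the identity up to one quantum", {
  for (seed in 1:20) {
    s <- random_series(seed)
    s$first_year <- sample(700:2000, 1L)
    for (units in c("hundredths_mm", "thousandths_mm")) {
      d <- tucson_dialect(units)
      back <- read_tucson(write_tucson(s, dialect = d))[[1L]]
      expect_identical(back$first_year, s$first_year)
      expect_identical(back$ring_flags, s$ring_flags)
      expect_length(back$widths, length(s$widths))   # no ring dropped
      expect_lte(max(abs(back$widths - s$widths)), 0.5 / d$scale + 1e-12)
    }
  }
})

test_that("long-format tables round-trip with metadata and flags", {
  s <- ring_series(c(0.4, 0, 0.6), first_year = 2001, series_id = "L1",
                   sample_id = "SAMP", site_id = "TUNDRA1", status = "living",
                   ring_flags = c("measured", "missing_inserted", "measured"))
  back <- read_long_table(write_long_table(s))[[1L]]
  expect_identical(back$widths, s$widths)
  expect_identical(back$ring_flags, s$ring_flags)
  expect_identical(back$first_year, 2001L)
  expect_identical(back$site_id, "TUNDRA1")
  expect_identical(back$status, "living")
  # undated series round-trip on ring index
  u <- ring_series(c(0.1, 0.2, 0.3), series_id = "U1")
  ub <- read_long_table(write_long_table(u))[[1L]]
  expect_true(is.na(ub$first_year))
  expect_identical(ub$widths, u$widths)
})

test_that("long-table validation rejects duplicate and broken year runs", {
  bad_dup <- c("series_id,year,width_mm", "A,2000,0.1", "A,2000,0.2")
  expect_error(read_long_table(bad_dup), "duplicate")
  bad_ord <- c("series_id,year,width_mm", "A,2001,0.1", "A,2000,0.2")
  expect_error(read_long_table(bad_ord), "increasing")
  bad_gap <- c("series_id,year,width_mm", "A,2000,0.1", "A,2002,0.2")
  expect_error(read_long_table(bad_gap), "consecutive")
})
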