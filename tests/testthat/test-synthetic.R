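test_that("generation is fully reproducible from the seed", {
  cfg <- generator_config(n_samples = 4, seed = 301,
                          length_range = c(150, 400))
  g1 <- generate_site(cfg)
  g2 <- generate_site(cfg)
  expect_identical(g1$series, g2$series)
  expect_identical(g1$truth$missing, g2$truth$missing)
  expect_identical(g1$truth$climate$index, g2$truth$climate$index)
})

test_that("the realized missing fraction hits the target rate", {
  cfg <- generator_config(n_samples = 1, radii_per_sample = c(1, 1),
                          length_range = c(1000, 1000), wedging_rate = 0,
                          prop_living = 1, seed = 302)
  g <- generate_site(cfg)
  realized <- g$truth$series$n_missing / g$truth$series$n_true
  expect_lte(abs(realized - cfg$missing_rate), 0.01)
  # deletions are the only source of shortened series
  expect_identical(g$truth$series$n_emitted + g$truth$series$n_missing,
                   g$truth$series$n_true)
})

test_that("emitted widths are strictly positive measured rings", {
  g <- generate_site(generator_config(n_samples = 5, seed = 303,
                                      length_range = c(150, 600)))
  for (s in g$series) {
    expect_true(all(s$widths > 0))
    expect_true(all(s$ring_flags == "measured"))
  }
})

test_that("shared-signal limits bracket the pairwise correlation", {
  cfg1 <- generator_config(n_samples = 2, radii_per_sample = c(1, 1),
                           length_range = c(600, 600), signal_share = 1,
                           missing_rate = 0, wedging_rate = 0,
                           radius_noise_sd = 0, prop_living = 1, seed = 304)
  g1 <- generate_site(cfg1)
  idx <- lapply(g1$series, index_series)
  expect_gt(overlap_corr(idx[[1]], idx[[2]])$r, 0.95)
  cfg0 <- generator_config(n_samples = 10, radii_per_sample = c(1, 1),
                           length_range = c(500, 500), signal_share = 0,
                           missing_rate = 0, wedging_rate = 0,
                           prop_living = 1, seed = 305)
  g0 <- generate_site(cfg0)
  expect_lt(abs(rbar_eps(lapply(g0$series, index_series))$rbar), 0.05)
})

test_that("realized coherence rises monotonically with the signal share", {
  rb <- vapply(seq(0.1, 0.9, by = 0.2), function(a) {
    cfg <- generator_config(n_samples = 8, radii_per_sample = c(1, 1),
                            length_range = c(400, 400), signal_share = a,
                            missing_rate = 0, wedging_rate = 0,
                            prop_living = 1, seed = 7)
    g <- generate_site(cfg)
    rbar_eps(lapply(g$series, index_series))$rbar
  }, numeric(1))
  expect_true(all(diff(rb) > 0))
})

test_that("the truth table undoes every deletion it records", {
  g <- generate_site(generator_config(n_samples = 4, seed = 306,
                                      length_range = c(150, 500)))
  for (i in seq_along(g$series)) {
    s <- g$series[[i]]
    ti <- g$truth$series[i, ]
    mi <- g$truth$missing[g$truth$missing$series_id == s$series_id, ]
    expect_identical(length(s$widths) + nrow(mi), ti$n_true)
    if (nrow(mi)) {
      restored <- apply_missing(s, mi$insert_at)
      expect_identical(length(restored$widths), ti$n_true)
      expect_identical(which(restored$ring_flags == "missing_inserted"),
                       sort(mi$position))
    }
  }
})

test_that("an impossible missing-rate configuration is refused", {
  cfg <- generator_config(n_samples = 1, radii_per_sample = c(1, 1),
                          length_range = c(300, 300), missing_rate = 0,
                          measurement_floor = 0.2, trend_A = 0.1,
                          trend_B = 0.05, sigma = 0.5,
                          prop_living = 1, seed = 307)
  expect_error(generate_site(cfg), "impossible config")
})

test_that("exported fixtures are byte-identical and round-trip", {
  g <- generate_site(generator_config(n_samples = 3, seed = 308,
                                      length_range = c(150, 300)))
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  p1 <- export_fixture(g$series, g$truth, d1)
  p2 <- export_fixture(g$series, g$truth, d2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  back <- read_tucson(p1["rwl"])
  expect_length(back, length(g$series))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$first_year, g$series[[i]]$first_year)
    expect_lte(max(abs(back[[i]]$widths - g$series[[i]]$widths)), 0.005 + 1e-12)
  }
})
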