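test_that("identical series collapse to themselves at full depth", {
  set.seed(31)
  x <- stats::rnorm(60, 1, 0.2)
  idx <- lapply(1:5, function(i)
    indexed_series(x, first_year = 1900, source_id = paste0("s", i)))
  ch <- build_chronology(idx)
  expect_identical(ch$first_year, 1900L)
  expect_equal(ch$values, x)
  expect_true(all(ch$depth == 5L))
  expect_equal(ch$rbar, 1)
})

test_that("the biweight mean resists a single outlier year", {
  base <- lapply(1:5, function(i)
    indexed_series(rep(1, 50), first_year = 2000, source_id = paste0("s", i)))
  out <- indexed_series(c(rep(1, 24), 5, rep(1, 25)), first_year = 2000,
                        source_id = "outlier")
  robust <- build_chronology(c(base, list(out)), robust = TRUE)
  plain <- build_chronology(c(base, list(out)), robust = FALSE)
  expect_lt(abs(robust$values[25] - 1), abs(plain$values[25] - 1))
  expect_equal(plain$values[25], (5 + 5) / 6)
})

test_that("a single series passes through at depth one", {
  a <- indexed_series(stats::rnorm(40), first_year = 1850)
  ch <- build_chronology(list(a))
  expect_equal(ch$values, a$index)
  expect_true(all(ch$depth == 1L))
  expect_true(is.na(ch$rbar))
})

test_that("duplicating every series changes depth but not values", {
  set.seed(33)
  # common span so the depth-4 robust/mean switch is on the same side
  # before and after duplication
  idx <- lapply(1:4, function(i)
    indexed_series(stats::rnorm(80, 1, 0.3), first_year = 1800,
                   source_id = paste0("s", i)))
  ch1 <- build_chronology(idx)
  ch2 <- build_chronology(c(idx, idx))
  expect_equal(ch2$values, ch1$values)
  expect_identical(ch2$depth, 2L * ch1$depth)
})

test_that("leave-one-out perturbation is bounded at realistic depth", {
  cfg <- generator_config(n_samples = 12, radii_per_sample = c(1, 1),
                          length_range = c(300, 300), missing_rate = 0,
                          wedging_rate = 0, prop_living = 1, seed = 34)
  g <- generate_site(cfg)
  idx <- lapply(g$series, index_series)
  full <- build_chronology(idx)
  loo <- build_chronology(idx[-1])
  common <- seq_along(loo$values)
  rms <- sqrt(mean((full$values[common] - loo$values[common])^2))
  expect_lt(rms, 3 / sqrt(12))
})

test_that("rbar and EPS behave at the two ends of coherence", {
  set.seed(35)
  x <- stats::rnorm(120)
  same <- lapply(1:4, function(i)
    indexed_series(x, first_year = 1900, source_id = paste0("s", i)))
  r1 <- rbar_eps(same)
  expect_equal(r1$rbar, 1)
  expect_equal(r1$eps, 1)
  noise <- lapply(1:10, function(i)
    indexed_series(stats::rnorm(500), first_year = 1500,
                   source_id = paste0("n", i)))
  r0 <- rbar_eps(noise)
  expect_lt(abs(r0$rbar), 0.05)
})

test_that("rbar recovers the generator's signal share", {
  # with equal AR(1) coefficients and no radius noise, the difference
  # indices of two series share exactly a fraction a of their variance
  for (a in c(0.2, 0.8)) {
    cfg <- generator_config(n_samples = 10, radii_per_sample = c(1, 1),
                            length_range = c(500, 500), signal_share = a,
                            climate_ar1 = 0.5, noise_ar1 = 0.5,
                            radius_noise_sd = 0, missing_rate = 0,
                            wedging_rate = 0, prop_living = 1,
                            seed = 36 + round(10 * a))
    g <- generate_site(cfg)
    idx <- lapply(g$series, index_series, method = "log_diff")
    expect_lt(abs(rbar_eps(idx)$rbar - a), 0.06)
  }
})

test_that("chronology construction rejects bad input", {
  expect_error(build_chronology(list()), "at least one")
  und <- indexed_series(stats::rnorm(30))
  expect_error(build_chronology(list(und)), "dated")
  expect_error(rbar_eps(list(und)), "at least two")
  two <- list(indexed_series(stats::rnorm(40), first_year = 1900),
              indexed_series(stats::rnorm(40), first_year = 1980))
  r <- rbar_eps(two)
  expect_true(is.na(r$rbar))
  expect_match(r$status, "overlap")
})
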