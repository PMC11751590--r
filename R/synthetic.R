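#' Configuration for the synthetic juniper ring-width generator
#'
#' The generator emulates the statistical structure of slow-growing tundra
#' juniper ring series: a shared site-level AR(1) climate signal, individual
#' AR(1) noise, lognormal multiplicative variability around a declining
#' negative-exponential age trend, a measurement floor below which rings go
#' undetected, extra locally-absent rings at a target rate, and one to four
#' radii per disk with radius-specific wedging deletions.
#'
#' Width model for ring `t` (cambial age, years) of sample `i`:
#' `width = (A * exp(-t / tau) + B) * exp(sigma * z)`, with
#' `z = sqrt(a) * C + sqrt(1 - a) * e`, where `C` is the standardized site
#' climate AR(1) and `e` the standardized individual AR(1). Under this model
#' the expected inter-series index correlation is about `a`, the
#' signal share.
#'
#' @param n_samples Number of sampled individuals (disks).
#' @param radii_per_sample Inclusive range of radii measured per disk,
#'   within 1-4.
#' @param length_range Inclusive range of true series lengths in years;
#'   default 150-1700, spanning centuries-old shrubs up to the oldest known.
#' @param signal_share Fraction `a` in [0,1] of index variance shared across
#'   the site (default 0.5).
#' @param climate_ar1,noise_ar1 AR(1) coefficients of the shared climate
#'   signal (default 0.5) and the individual noise (default 0.3).
#' @param sigma Lognormal sigma of the multiplicative width variability
#'   (default 0.3).
#' @param trend_A,trend_tau,trend_B Age-trend parameters: initial extra
#'   width `A` (mm, default 0.8), e-folding time `tau` (years, default 100),
#'   asymptotic width `B` (mm, default 0.05).
#' @param missing_rate Target realized fraction of missing (deleted) rings
#'   per series, default 0.03 — the order observed in extremely old junipers
#'   (tens of missing rings per millennium).
#' @param measurement_floor Width in mm below which a ring goes undetected
#'   (default 0.01).
#' @param wedging_rate Extra per-radius deletion rate from wedging sectors
#'   (default 0.01).
#' @param radius_noise_sd Lognormal sd of radius-to-radius width variation
#'   within a disk (default 0.1). Radii of one disk measure the same
#'   anatomical rings, so this variation is modelled as a smooth AR(1)
#'   eccentricity path (coefficient 0.9), not per-ring white noise.
#' @param prop_living Probability a sample is living (ends at `end_year`),
#'   default 0.6; dead samples end up to `dead_span` years earlier.
#' @param end_year Sampling year (default 2020).
#' @param dead_span Maximum years a dead sample's outermost ring predates
#'   `end_year` (default 300).
#' @param site_id Site identifier for the emitted series.
#' @param seed Integer seed; one seed drives every stream, so output is
#'   fully reproducible.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 20L, radii_per_sample = c(1L, 4L),
                             length_range = c(150L, 1700L),
                             signal_share = 0.5, climate_ar1 = 0.5,
                             noise_ar1 = 0.3, sigma = 0.3,
                             trend_A = 0.8, trend_tau = 100, trend_B = 0.05,
                             missing_rate = 0.03, measurement_floor = 0.01,
                             wedging_rate = 0.01, radius_noise_sd = 0.1,
                             prop_living = 0.6, end_year = 2020L,
                             dead_span = 300L, site_id = "SYN1", seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              radii_per_sample = as.integer(radii_per_sample),
              length_range = as.integer(length_range),
              signal_share = signal_share, climate_ar1 = climate_ar1,
              noise_ar1 = noise_ar1, sigma = sigma,
              trend_A = trend_A, trend_tau = trend_tau, trend_B = trend_B,
              missing_rate = missing_rate,
              measurement_floor = measurement_floor,
              wedging_rate = wedging_rate, radius_noise_sd = radius_noise_sd,
              prop_living = prop_living, end_year = as.integer(end_year),
              dead_span = as.integer(dead_span),
              site_id = site_id, seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1L,
            all(cfg$radii_per_sample >= 1L & cfg$radii_per_sample <= 4L),
            cfg$length_range[1] >= 10L,
            cfg$signal_share >= 0, cfg$signal_share <= 1,
            abs(cfg$climate_ar1) < 1, abs(cfg$noise_ar1) < 1,
            cfg$sigma >= 0, cfg$trend_A > 0, cfg$trend_tau > 0, cfg$trend_B > 0,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$wedging_rate >= 0, cfg$wedging_rate <= 1,
            cfg$prop_living >= 0, cfg$prop_living <= 1)
  class(cfg) <- "generator_config"
  cfg
}

# Keep only the first member of each run of consecutive integers.
drop_adjacent <- function(x) {
  if (length(x) < 2L) return(x)
  x[c(TRUE, diff(x) > 1L)]
}

# Standardized (unit-variance, stationary) AR(1) path of length n.
ar1_path <- function(n, phi) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1L, sd = sqrt(1 - phi^2))
    for (t in 2:n) x[t] <- phi * x[t - 1L] + innov[t - 1L]
  }
  x
}

#' Generate a synthetic site with known truth
#'
#' Draws a population of juniper-like ring-width series under
#' [generator_config()] and returns both the emitted (observed) series and a
#' `synthetic_truth` object sufficient to score any recovery experiment
#' without re-running the generator. Missing rings are *deleted* from the
#' emitted series — the detector faces the real problem of a silent one-year
#' shift, not a visible zero. Deletions are confined to interior rings (the
#' true first year is exact) and are single rings, never consecutive runs. Floor-induced deletions (width below
#' `measurement_floor`) are topped up by exact random draws so the realized
#' per-series missing fraction equals `round(missing_rate * length) /
#' length`.
#'
#' @param cfg A [generator_config()].
#' @return A list with `series` (list of dated `ring_series`, one per
#'   radius) and `truth` (class `synthetic_truth`): `series` table (one row
#'   per emitted radius: ids, true first/last year, ring counts, status),
#'   `missing` table (one row per deleted ring: series id, position in the
#'   complete ring sequence, calendar year, and `insert_at`, the insert
#'   position in the emitted series that undoes the deletion), and `climate`
#'   (the latent site signal as a dated `indexed_series`).
#' @export
generate_site <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  lens <- sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L, n,
                     replace = TRUE) + cfg$length_range[1] - 1L
  living <- stats::runif(n) < cfg$prop_living
  last_yr <- ifelse(living, cfg$end_year,
                    cfg$end_year - sample.int(cfg$dead_span + 1L, n,
                                              replace = TRUE) + 1L)
  first_yr <- last_yr - lens + 1L
  clim_y0 <- min(first_yr)
  clim <- ar1_path(cfg$end_year - clim_y0 + 1L, cfg$climate_ar1)

  series <- list()
  truth_series <- list()
  truth_missing <- list()
  for (i in seq_len(n)) {
    L <- lens[i]
    yrs <- first_yr[i]:last_yr[i]
    C <- clim[yrs - clim_y0 + 1L]
    e <- ar1_path(L, cfg$noise_ar1)
    z <- sqrt(cfg$signal_share) * C + sqrt(1 - cfg$signal_share) * e
    t_age <- seq_len(L) - 1L
    trend <- cfg$trend_A * exp(-t_age / cfg$trend_tau) + cfg$trend_B
    disk_w <- trend * exp(cfg$sigma * z)

    interior <- 2:(L - 1L)
    floor_miss <- interior[disk_w[interior] < cfg$measurement_floor]
    target <- round(cfg$missing_rate * L)
    if (length(floor_miss) > target)
      stop(sprintf(paste("impossible config: measurement floor alone deletes %d",
                         "rings of sample %d but missing_rate %.3f allows only %d;",
                         "raise missing_rate or lower the floor"),
                   length(floor_miss), i, cfg$missing_rate, target), call. = FALSE)
    pool <- setdiff(interior, floor_miss)
    shared_pool <- pool[sample.int(length(pool))]  # shared top-up order

    k <- if (cfg$radii_per_sample[1] == cfg$radii_per_sample[2])
      cfg$radii_per_sample[1]
    else sample(cfg$radii_per_sample[1]:cfg$radii_per_sample[2], 1L)
    sample_id <- sprintf("S%03d", i)
    for (r in seq_len(k)) {
      # radius-to-radius differences are growth eccentricity: smooth in time
      # (AR(1), phi 0.9), so radii agree closely at the year-to-year scale
      w_r <- disk_w * exp(cfg$radius_noise_sd * ar1_path(L, 0.9))
      wedge <- interior[stats::runif(length(interior)) < cfg$wedging_rate]
      base <- drop_adjacent(sort(union(floor_miss, wedge)))
      # top up from the shared pool so the realized per-radius missing
      # fraction hits the target exactly (radii share most deletions);
      # deletions are kept non-adjacent -- single missing rings, no runs
      need <- target - length(base)
      topup <- integer(0)
      if (need > 0L) {
        for (cand in shared_pool) {
          if (length(topup) >= need) break
          sel <- c(base, topup)
          if (!(cand %in% sel) && !((cand - 1L) %in% sel) &&
              !((cand + 1L) %in% sel)) topup <- c(topup, cand)
        }
      }
      miss_r <- sort(c(base, topup))
      keep <- setdiff(seq_len(L), miss_r)
      sid <- sprintf("S%03dR%d", i, r)
      series[[length(series) + 1L]] <-
        ring_series(w_r[keep], first_year = first_yr[i],
                    series_id = sid, sample_id = sample_id,
                    site_id = cfg$site_id, radius_no = r,
                    status = if (living[i]) "living" else "dead")
      truth_series[[length(truth_series) + 1L]] <-
        data.frame(series_id = sid, sample_id = sample_id,
                   site_id = cfg$site_id, radius_no = r,
                   status = if (living[i]) "living" else "dead",
                   true_first_year = first_yr[i],
                   true_last_year = last_yr[i],
                   n_true = L, n_emitted = length(keep),
                   n_missing = length(miss_r))
      if (length(miss_r))
        truth_missing[[length(truth_missing) + 1L]] <-
          data.frame(series_id = sid,
                     position = miss_r,
                     year = yrs[miss_r],
                     insert_at = vapply(miss_r, function(p)
                       sum(keep < p) + 1L, integer(1)))
    }
  }
  truth <- structure(
    list(series = do.call(rbind, truth_series),
         missing = if (length(truth_missing)) do.call(rbind, truth_missing)
         else data.frame(series_id = character(), position = integer(),
                         year = integer(), insert_at = integer()),
         climate = indexed_series(clim, first_year = clim_y0,
                                  source_id = paste0(cfg$site_id, "_climate")),
         config = cfg),
    class = "synthetic_truth")
  list(series = series, truth = truth)
}

#' Latent climate master of a synthetic site
#'
#' The generator's shared site signal as a dated `indexed_series`, usable
#' directly as the dating reference in recovery experiments.
#' @param truth A `synthetic_truth`.
#' @return A dated `indexed_series`.
#' @export
truth_master <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth$climate
}

#' Export a generated site as plain-text fixtures
#'
#' Writes the series as a Tucson .rwl file plus the truth tables as CSV.
#' Output is byte-identical for identical inputs, so fixtures regenerate
#' deterministically from a seed.
#'
#' @param series List of dated `ring_series`.
#' @param truth The matching `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_fixture <- function(series, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(rwl = file.path(dir, "series.rwl"),
             series = file.path(dir, "truth_series.csv"),
             missing = file.path(dir, "truth_missing.csv"))
  write_tucson(series, paths["rwl"])
  utils::write.csv(truth$series, paths["series"], row.names = FALSE)
  utils::write.csv(truth$missing, paths["missing"], row.names = FALSE)
  invisible(paths)
}
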