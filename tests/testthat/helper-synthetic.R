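# Shared fixtures: all synthetic, generated in code at test time.

# Two complete radii of one disk (no deletions), length L, strong shared
# signal -- the setting for controlled missing-ring experiments.
make_disk_pair <- function(seed, L = 300L) {
  cfg <- generator_config(n_samples = 1L, radii_per_sample = c(2L, 2L),
                          length_range = c(L, L), missing_rate = 0,
                          wedging_rate = 0, prop_living = 1, seed = seed)
  g <- generate_site(cfg)
  list(a = g$series[[1L]], b = g$series[[2L]], truth = g$truth)
}

# Delete rings (1-based positions of the complete series) from a series.
delete_rings <- function(series, del) {
  ring_series(series$widths[-del], first_year = series$first_year,
              series_id = series$series_id, sample_id = series$sample_id,
              site_id = series$site_id, status = series$status)
}

# Insert-before positions (in the emitted series) that undo deletions `del`
# made in a complete series of length L.
true_insert_at <- function(L, del) {
  kept <- setdiff(seq_len(L), del)
  vapply(del, function(p) sum(kept < p) + 1L, integer(1L))
}

# A random dated ring series with a few missing rings, for round-trip
# property tests.
random_series <- function(seed, id = "RAND0001") {
  set.seed(seed)
  L <- sample(15:120, 1L)
  w <- round(stats::runif(L, 0.02, 2.5), 3)
  fl <- rep("measured", L)
  nmiss <- sample(0:3, 1L)
  if (nmiss > 0L) {
    at <- sample(seq_len(L), nmiss)
    w[at] <- 0
    fl[at] <- "missing_inserted"
  }
  ring_series(w, first_year = sample(500:1990, 1L), series_id = id,
              ring_flags = fl)
}
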