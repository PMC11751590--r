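---
title: "Cross-dating slow-growing shrub ring series: models, statistics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dating slow-growing shrub ring series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodate)
```

## The problem

Prostrate junipers and similar tundra shrubs reach ages of many centuries
while adding rings a few hundredths of a millimetre wide. Their age cannot be
read off by counting rings: asymmetric cambial activity routinely produces
*locally absent* ("missing") rings — years in which the measured radius
records no ring at all — and every missing ring silently shifts all later
rings one year off the calendar. Reliable age determination therefore rests
on *cross-dating*: matching the year-to-year width pattern of a series
against independently dated material until every ring can be assigned its
exact calendar year, and inserting the statistically required missing rings
along the way.

`dendrodate` implements that workflow end to end: Tucson/long-table I/O,
high-pass indexing, the three classical dating statistics
(Gleichläufigkeit, overlap correlation, Baillie–Pilcher t), sliding calendar
placement, segment-based missing-ring detection, robust mean chronologies
with rbar/EPS diagnostics, a per-disk-to-per-site age pipeline, and a
synthetic generator with known ground truth that makes every stage testable
at desk scale. The exported functions are the interface; everything shown
here runs in an ordinary R session.

## Indexing

Raw widths mix the dating signal with a strong age trend and
individual-vigor differences, so all statistics operate on dimensionless
high-pass indices (`index_series()`):

* `moving_ratio` (default): width divided by a centred moving average over
  `window` years (default 5, odd so the window is centred). The classical
  choice preceding t-value dating. The `(window-1)/2` edge positions are
  invalid. Missing rings are excluded from the moving average rather than
  replaced by a token width: a token width in the window biases the
  neighbours' index low and, in planted-deletion experiments, mis-localized
  insertions by one to three rings.
* `log_diff`: first differences of log widths; position 1 invalid, and both
  differences touching a missing ring invalid. Missing rings enter the log
  as `zero_replacement` (default 0.005 mm, half of the smallest width
  expressible at 0.01 mm resolution).

Both methods are exactly scale invariant, so measurement units cancel.
Invalid positions are excluded from every downstream statistic, never
imputed — series ends are where dating is weakest and fabricated agreement
there would be the most damaging.

## Dating statistics and sliding placement

For two aligned series, `glk()` is the mean sign agreement of first
differences (ties score ½; 0.5 is chance), `overlap_corr()` the Pearson
correlation over the jointly valid overlap, and `bp_tvalue()` the transform
`t = r * sqrt(n - 2) / sqrt(1 - r^2)` — a t statistic on `n - 2` degrees of
freedom that rewards both agreement and overlap length. `slide_date()`
scans every candidate placement of a series along a dated reference
(minimum overlap 50 years by default), ranks candidates by t (ties: GLK,
then overlap, then smaller |first year|), and flags as *significant* those
with `t >= 3.5`, `GLK >= 0.60` and positive correlation. The thresholds are
conventional screening values, configurable and echoed in the output;
negative-correlation matches are never significant, because an inverted
match is physically meaningless for same-hemisphere ring series. Ranking
uses t rather than GLK or r alone because t integrates overlap length; GLK
acts as a confirmatory gate.

```{r slide-example}
cfg <- generator_config(n_samples = 2, radii_per_sample = c(1, 1),
                        length_range = c(300, 300), missing_rate = 0,
                        wedging_rate = 0, prop_living = 1, seed = 42)
g <- generate_site(cfg)
master <- truth_master(g$truth)
res <- slide_date(index_series(undate(g$series[[1]])), master)
head(as.data.frame(res), 3)
g$truth$series$true_first_year[1]
```

## Missing-ring detection

A missing ring manifests as a one-year lag shift of everything after it.
`segment_lag_scan()` (COFECHA-style verification) cuts a provisionally
dated series into overlapping segments (default 50 years every 25, plus
half- and quarter-length tail segments so late boundaries are not hidden
inside a mixed segment) and correlates each segment with the reference at
every lag within ±3. A segment is flagged when its best lag is nonzero by a
margin that is the larger of 0.10 and about 1.5 standard errors of a
correlation at that overlap — short or sparse segments cannot flag on
sampling noise.

`propose_missing()` turns flags into insertions greedily:

1. If the innermost segment prefers a *negative* lag, the provisional date
   locked onto the bulk of the series across an early deletion; the series
   is re-anchored so the innermost rings define lag 0.
2. The earliest flagged positive-lag segment brackets the next boundary
   (from the last lag-0 segment to the flagged segment's end). Every
   insertion position in the bracket is scored by a *local* t on first
   differences of the index: differencing makes a one-ring shift
   anticorrelate, so the boundary is localized sharply, while the window
   restriction keeps pending later deletions from masking the comparison.
3. A lag jump of two or more (clearly beating lag 1) triggers a pair scan,
   since no single insertion can restore such a window.
4. Each accepted insertion advances a left-to-right cursor — every lag
   transition is corrected once — and the loop stops at `max_missing`, when
   nothing is flagged, or when the local gain drops below `min_improve`
   (default 0.05 t units). The final hypothesis is the prefix of insertions
   maximizing the whole-series t, so an accepted hypothesis never scores
   below the uncorrected series.

The detector is purely statistical: no climatic assumption is made about
where junipers drop rings. `exhaustive_missing()` evaluates every single
insertion and every pair — exact but quadratic — and serves as the
verification oracle for the greedy search on short series. At series ends
the objective is weakly identified (an insertion in the outermost few rings
realigns almost nothing), so oracle comparisons are run with interior
deletions and a common acceptance epsilon of 1 t unit; with the default
0.05 epsilon the exhaustive maximizer will happily buy a 0.2–0.5 t
end-of-series artifact that no detector could distinguish from noise.

## Chronologies

`build_chronology()` collates dated indexed series into a year-indexed
robust mean: Tukey's biweight (tuning constant 9, one-step, median/MAD
start) wherever at least four series contribute, the arithmetic mean below
that depth. Chronologies are always built on indices, never raw widths —
age-trend and vigor differences between shrubs would otherwise dominate.
`rbar_eps()` reports the mean pairwise inter-series correlation over a
stated window and the expressed population signal
`EPS = n rbar / (n rbar + (1 - rbar))`.

## The age pipeline

`merge_radii()` reconciles the one to four radii measured per disk:
the longest radius anchors, the others are slid over candidate offsets and
must pass the significance screen (an irreconcilable radius is an error
listing the best candidates — operator decision, never a silent guess);
missing rings are proposed per radius against the anchor; and the sample
series is the per-year mean of vigor-scaled widths (each radius divided by
its mean measured width, rescaled by the grand mean). Scaling first makes
the merge an average of relative variation — the width-domain equivalent of
averaging ratio indices — while still producing a series in mm that the
rest of the pipeline (insertion, export, ring counts) can consume. Years
covered by no measured ring of any radius become width-0 missing rings, so
the sample ring count is the span of the union of aligned radii.

`date_and_report()` dates a sample against a chronology *provisionally*:
the top-ranked placements are tried even when not yet significant, missing
rings are proposed and inserted, the corrected series is re-slid, and only
then is significance required — a series still carrying missing rings
often cannot reach significance at any uncorrected placement. For living
samples the sampling date pins the outermost ring (`bark_year`): a dated
series ending short of the bark year has its deficit inserted at the
best-supported positions in the outer segment, which is exactly the region
where lag statistics are blind. The report's age is
`n_measured + n_missing` at the sampling point; no pith offset or missing
inner part is ever added (an optional informational range can be carried,
never applied), and the fixed caveat states that the true age exceeds the
reported age. Undatable samples are first-class results: counted in
`site_summary()`, excluded from maxima, never silently dropped.
`site_summary()` reports per site only the maximum age, the number of
individuals and the living/dead percentages — sampling targets the
oldest-looking individuals, so no population age structure is inferred.

`scan_indexing_methods()` recomputes GLK/r/t for a dated sample under both
indexing methods (ratio windows 5, 7, 9; log-diff) and two comparison
windows (the first 320 rings vs the full overlap), the tool for
reconciling published dating statistics whose exact standardization is
unstated.

## The synthetic generator

`generate_site()` draws juniper-like populations with known truth. Width of
ring `t` (cambial age) in sample `i`:

\[ w_{it} = \big(A e^{-t/\tau} + B\big)\, e^{\sigma z_{it}}, \qquad
   z_{it} = \sqrt{a}\, C_t + \sqrt{1-a}\, e_{it}, \]

with `C` a standardized AR(1) site climate signal (coefficient 0.5),
`e` standardized individual AR(1) noise (0.3), lognormal sigma 0.3, age
trend A = 0.8 mm, tau = 100 yr, B = 0.05 mm, lengths 150–1700 yr, sampling
year 2020, about 60 % living samples (dead ones end up to 300 years
earlier). These defaults were chosen once as a plausible desk-scale
emulation of extremely slow-growing tundra junipers. A ring goes missing
when its width falls below the 0.01 mm measurement floor, topped up by
uniform draws so the realized per-series rate equals
`round(missing_rate * L) / L` (target 0.03 — the order of 35 missing in
1176 rings). Missing rings are *deleted* from the emitted series, so the
detector faces a real silent shift; deletions are interior and
non-adjacent (single missing rings, no runs — the run-length hook is fixed
at 1), and the truth table records, for every deletion, its position, year
and the emitted-coordinate insertion that undoes it. Radii of one disk
share the disk's widths times a smooth AR(1) (coefficient 0.9) lognormal
eccentricity path — radii measure the same anatomical rings, so their
differences are low-frequency — plus radius-specific wedging deletions.
One seed drives every stream; fixtures regenerate byte-identically.

What the generator does *not* emulate: false rings, run-length missing-ring
clustering, disturbance and herbivory, spatial site structure, and any
mechanistic climate–growth relation. Passing recovery tests therefore shows
the statistical machinery is sound under the stated process, not that real
juniper data meet these assumptions.

Under the defaults, high-pass filtering attenuates the AR(1) climate more
than the individual noise, so realized rbar sits below the signal share
`a` while increasing monotonically with it. With log-difference indices,
equal AR(1) coefficients and no radius noise the attenuations cancel and
the expected pairwise correlation is exactly `a` — the configuration used
for the parameter-recovery test.

## Validation results the test suite computes

* Statistic oracles: GLK against exhaustive sign-pattern enumeration
  (exact), `bp_tvalue` against the closed form (1e-12) and `cor.test`'s
  statistic, `overlap_corr` against a naive two-pass Pearson.
* Dating: 100 seeded 300-ring series at signal share 0.5 slid against
  their true master — rank-1 at the true year in at least 95; 100
  signal-free series — at most 5 spuriously significant at t ≥ 3.5.
* Missing rings (within-disk, the hierarchy's first stage): one deleted
  ring localized within ±1 in ≥ 90 of 100 replicates; three deletions
  ≥ 80 % of deletions; zero-deletion false-positive proposals 0 of 100.
  Greedy matches the exhaustive ≤2-insertion oracle on 20 length-120
  instances (≥ 19 structurally identical, any gap < 3 t from the oracle's
  end artifact).
* End to end: 20 disks (1–4 radii, a few deleted rings each, lengths
  200–400 for desk-scale runtime) merged, dated and corrected against the
  master; 18 of 20 receive the exact true first year and total age at the
  suite's fixed seed. Across seeds the rate averages ~85 %: the residual
  failures are deletions in the innermost ~10 rings (no anchor exists on
  the pith side) and in the outermost ~10 rings of *dead* samples (no bark
  anchor), both information-limited, plus rare over-insertions against a
  noisy master.

## Numerical choices and limitations

* Quantization: Tucson output floors any positive width to one quantum —
  0 is semantically "missing ring" in that format and must never be
  fabricated by rounding.
* Degenerate inputs: zero-variance windows, overlaps below the minimum and
  empty candidate sets return typed undefined results (`NA` plus a status),
  not numbers. `|r| >= 1` maps to a documented ±1e6 sentinel with warning.
* Ties everywhere break deterministically (earlier position, smaller |lag|,
  smaller |candidate year|), so every result is reproducible bit for bit
  from the inputs and seed.
* Against a site-level master of per-ring correlation ~0.45, exact
  (±1-ring) localization of a missing ring is impossible in principle —
  the maximum-likelihood argmax itself is right only about half the time —
  which is why precise localization belongs to the within-individual
  comparison and only the *count* of missing rings is needed from the
  master stage.
* The pith side of every series is unanchored by design: reported ages are
  ring counts at the sampling point and systematically underestimate the
  true age of the individual.
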