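#' Insert missing rings into a series
#'
#' Inserts a width-0, `missing_inserted` ring before each given (1-based)
#' original ring index; `length(widths) + 1` appends after the last ring.
#' Measured widths are never altered — only zeros are added. For a dated
#' series, an insertion before ring 1 moves `first_year` one year earlier;
#' all other insertions extend the series end, so the calendar span widens by
#' exactly the number of inserted rings.
#'
#' @param series A `ring_series`.
#' @param positions Integer vector of distinct insertion positions in
#'   `1..length(widths)+1`.
#' @return The lengthened `ring_series`; `n_measured` is unchanged.
#' @export
apply_missing <- function(series, positions) {
  stopifnot(inherits(series, "ring_series"))
  if (!length(positions)) return(series)
  positions <- as.integer(positions)
  L <- length(series$widths)
  if (anyDuplicated(positions))
    stop("duplicate insertion positions", call. = FALSE)
  if (any(positions < 1L | positions > L + 1L))
    stop("insertion positions must lie in 1..", L + 1L, call. = FALSE)
  w <- series$widths
  f <- series$ring_flags
  for (p in sort(positions, decreasing = TRUE)) {
    w <- append(w, 0, after = p - 1L)
    f <- append(f, "missing_inserted", after = p - 1L)
  }
  out <- series
  out$widths <- w
  out$ring_flags <- f
  if (is_dated(out) && any(positions == 1L))
    out$first_year <- out$first_year - sum(positions == 1L)
  out
}

# t-value of a dated series against a dated reference index at its own
# placement; -Inf when undefined so it can be maximized over.
whole_series_t <- function(series, ref_idx, min_overlap = 30L, ...) {
  xi <- index_series(series, ...)
  oc <- overlap_corr(xi, ref_idx, min_overlap = min_overlap)
  if (is.na(oc$r) || oc$n <= 2L) return(-Inf)
  if (abs(oc$r) >= 1) return(sign(oc$r) * 1e6)
  oc$r * sqrt(oc$n - 2) / sqrt(1 - oc$r^2)
}

#' Segment-wise lag scan against a reference
#'
#' COFECHA-style verification of a provisionally dated series: the series is
#' cut into overlapping segments, each segment is correlated with the dated
#' reference at every lag in `-max_lag..max_lag`, and segments whose best lag
#' is nonzero by a clear margin are flagged. A missing ring makes all
#' segments after it prefer lag +1 while earlier segments stay at lag 0, so
#' the first flagged segment brackets the missing-ring position.
#'
#' @param series Provisionally dated `ring_series` (or `indexed_series`).
#' @param reference Dated `indexed_series` or `chronology`.
#' @param segment_len,step Segment length and spacing in years (defaults 50
#'   and 25). A series shorter than one segment is scanned as a single
#'   whole-series segment, with a warning.
#' @param max_lag Maximum |lag| scanned (default 3).
#' @param margin A segment is flagged only when its best-lag correlation
#'   exceeds the lag-0 correlation by at least this much (default 0.10);
#'   the effective margin never drops below about 1.5 standard errors of a
#'   correlation at the segment's overlap, so short segments do not flag on
#'   sampling noise.
#' @param ... Indexing arguments passed on when `series` is a `ring_series`.
#' @return A data.frame, one row per segment: `segment`, `start`, `end`
#'   (ring positions), `best_lag`, `r_best`, `r_lag0`, `flagged`; the full
#'   lag-correlation matrix is in attribute `lag_corr`.
#' @export
segment_lag_scan <- function(series, reference, segment_len = 50L, step = 25L,
                             max_lag = 3L, margin = 0.10, ...) {
  xi <- if (inherits(series, "indexed_series")) series else index_series(series, ...)
  if (is.na(xi$first_year))
    stop("series must be provisionally dated for a lag scan", call. = FALSE)
  ri <- as_index(reference)
  if (is.na(ri$first_year)) stop("reference must be dated", call. = FALSE)
  L <- length(xi$index)
  if (L < segment_len) {
    warning("series shorter than one segment; scanning it whole")
    starts <- 1L
    ends <- L
  } else {
    starts <- seq.int(1L, L - segment_len + 1L, by = step)
    if (starts[length(starts)] != L - segment_len + 1L)
      starts <- c(starts, L - segment_len + 1L)
    ends <- starts + segment_len - 1L
    # a boundary in the last half segment never dominates a full segment;
    # half- and quarter-length tail segments close that blind spot
    half <- segment_len %/% 2L
    quarter <- max(12L, segment_len %/% 4L)
    starts <- c(starts, L - half + 1L, L - quarter + 1L)
    ends <- c(ends, L, L)
  }
  lags <- (-max_lag):max_lag
  off0 <- xi$first_year - ri$first_year
  lag_corr <- matrix(NA_real_, nrow = length(starts), ncol = length(lags),
                     dimnames = list(NULL, paste0("lag", lags)))
  rows <- data.frame(segment = seq_along(starts), start = starts,
                     end = ends,
                     best_lag = NA_integer_, r_best = NA_real_,
                     r_lag0 = NA_real_, flagged = FALSE)
  for (si in seq_along(starts)) {
    s <- starts[si]; e <- ends[si]
    min_seg <- max(10L, (e - s + 1L) %/% 2L)
    n0 <- NA_integer_
    for (li in seq_along(lags)) {
      al <- align_pair(xi$index[s:e], xi$valid[s:e], ri$index, ri$valid,
                       off0 + s - 1L + lags[li])
      if (is.null(al) || sum(al$valid) < min_seg) next
      x <- al$x[al$valid]; y <- al$y[al$valid]
      if (lags[li] == 0L) n0 <- length(x)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      lag_corr[si, li] <- stats::cor(x, y)
    }
    rr <- lag_corr[si, ]
    if (all(is.na(rr))) next
    pref <- order(abs(lags), lags)       # prefer lag 0, then small |lag|
    best <- pref[which.max(rr[pref])]
    rows$best_lag[si] <- lags[best]
    rows$r_best[si] <- rr[best]
    rows$r_lag0[si] <- rr[lags == 0L]
    # the margin never drops below ~1.5 standard errors of a correlation at
    # this overlap, so short or sparse segments do not flag on r noise
    margin_eff <- max(margin, 1.5 / sqrt(max(if (is.na(n0)) min_seg else n0, 7L) - 3))
    rows$flagged[si] <- lags[best] != 0L &&
      (is.na(rows$r_lag0[si]) || rows$r_best[si] - rows$r_lag0[si] >= margin_eff)
  }
  attr(rows, "lag_corr") <- lag_corr
  rows
}

#' Propose missing-ring insertions for a dated series
#'
#' Greedy detection of locally absent rings: while the segment lag scan
#' flags a positive-lag transition, every insertion position inside the
#' earliest flagged segment is tried, the insertion that maximizes the
#' whole-series t-value against the reference is kept (ties broken toward
#' the earlier position), and the scan repeats — up to `max_missing`
#' insertions, stopping as soon as the best insertion improves t by less
#' than `min_improve`. The search is purely statistical: no climatic
#' assumption is made about where junipers drop rings.
#'
#' @param series Provisionally dated `ring_series`.
#' @param reference Dated `indexed_series` or `chronology`.
#' @param max_missing Maximum number of insertions (default 5).
#' @param min_improve Minimum t-value gain to accept an insertion
#'   (default 0.05).
#' @param min_overlap Minimum overlap for the whole-series t (default 30).
#' @param segment_len,step,max_lag,margin Passed to [segment_lag_scan()].
#' @param ... Indexing arguments (method, window) used throughout.
#' @return An object of class `missing_hypothesis`: `positions` (insertion
#'   positions in the coordinates of the input series, for
#'   [apply_missing()]), `anchored_first_year` (the calendar anchoring of
#'   the corrected series' first ring; differs from the input's when the
#'   provisional date had locked onto the bulk of the series across an
#'   early deletion), `score_before`, `score_after` (whole-series
#'   t-values), `segments` (the final lag-scan table) and `audit` (one row
#'   per accepted insertion; `audit_all` also keeps insertions dropped by
#'   the final best-prefix selection).
#' @export
propose_missing <- function(series, reference, max_missing = 5L,
                            min_improve = 0.05, min_overlap = 30L,
                            segment_len = 50L, step = 25L, max_lag = 3L,
                            margin = 0.10, ...) {
  stopifnot(inherits(series, "ring_series"))
  if (!is_dated(series))
    stop("series must be provisionally dated (run slide_date first)", call. = FALSE)
  ri <- as_index(reference)
  if (is.na(ri$first_year)) stop("reference must be dated", call. = FALSE)
  max_missing <- as.integer(max_missing)
  if (max_missing < 0L) stop("'max_missing' must be >= 0", call. = FALSE)

  cur <- series
  orig_map <- seq_len(length(series$widths))   # NA marks inserted rings
  accepted <- integer(0)
  audit <- list()
  score_before <- whole_series_t(cur, ri, min_overlap = min_overlap, ...)
  score <- score_before
  diag <- segment_lag_scan(cur, ri, segment_len = segment_len, step = step,
                           max_lag = max_lag, margin = margin, ...)
  # when the provisional date locked onto the bulk of a series whose early
  # rings precede a deletion, the first segments sit at a negative lag;
  # re-anchor the working copy so the innermost dated segment defines lag 0
  # and the deletions appear as the usual positive-lag transitions
  # a positive innermost lag means a deletion inside that segment
  # (insertion territory); only a negative lag indicates bulk-locking.
  # The innermost (shortest first) segments are examined with a margin
  # scaled to their own sampling noise.
  heads <- diag[diag$start == 1L & !is.na(diag$best_lag), , drop = FALSE]
  heads <- heads[order(heads$end), , drop = FALSE]
  for (hi in seq_len(nrow(heads))) {
    f1 <- heads[hi, ]
    m_eff <- max(margin, 1.5 / sqrt(max(f1$end - f1$start + 1L, 7L) - 3))
    if (f1$best_lag < 0L &&
        (is.na(f1$r_lag0) || f1$r_best - f1$r_lag0 >= m_eff)) {
      cur$first_year <- cur$first_year + f1$best_lag
      score <- whole_series_t(cur, ri, min_overlap = min_overlap, ...)
      score_before <- score
      diag <- segment_lag_scan(cur, ri, segment_len = segment_len, step = step,
                               max_lag = max_lag, margin = margin, ...)
      break
    }
  }
  cursor <- 0L   # rightmost insertion so far: each transition is fixed once
  while (length(accepted) < max_missing) {
    fl <- diag[diag$flagged & !is.na(diag$best_lag) & diag$best_lag > 0L &
                 diag$end > cursor, , drop = FALSE]
    if (!nrow(fl)) break
    seg <- fl[which.min(fl$start), ]
    # the transition lies between the last lag-0 segment and the first
    # shifted one; mixed segments in between never flag, so bracket from
    # the lag-0 side (fall back to one segment length upstream)
    zero_before <- diag[!is.na(diag$best_lag) & diag$best_lag == 0L &
                          diag$start < seg$start, , drop = FALSE]
    lo <- if (nrow(zero_before)) max(zero_before$start)
    else max(1L, seg$start - segment_len)
    lo <- max(lo, cursor + 1L)
    if (lo > seg$end) break
    cands <- lo:seg$end
    # localize on first differences of the index over the local window:
    # differencing makes a one-ring shift anticorrelate, so the boundary
    # position is discriminated sharply, while candidates only differ
    # inside the window
    hi <- seg$end
    cur_xi <- index_series(cur, ...)
    tloc_null <- local_diff_t(cur_xi, ri, lo, min(length(cur_xi$index), hi + 1L))
    tloc <- vapply(cands, function(p) {
      trial <- apply_missing(cur, p)
      xi <- index_series(trial, ...)
      local_diff_t(xi, ri, lo, min(length(xi$index), hi + 1L))
    }, numeric(1))
    ord <- order(-tloc, cands)
    picked <- NA_integer_
    for (o in ord) {
      p <- cands[o]
      op <- orig_position(orig_map, p)
      if (!(op %in% accepted)) { picked <- o; break }
    }
    if (is.na(picked) || !is.finite(tloc[picked])) break
    ins <- cands[picked]
    t_ins <- tloc[picked]
    # a lag jump of two or more means a second deletion close by: a lone
    # insertion cannot restore the window, so scan insertion pairs too --
    # but only when the lag-2 preference also clearly beats lag 1, so a
    # noisy short segment cannot buy two insertions on one weak flag
    lagmat <- attr(diag, "lag_corr")
    r_lag1 <- if (!is.null(lagmat)) lagmat[seg$segment, "lag1"] else NA_real_
    margin_pair <- max(margin,
                       1.5 / sqrt(max(seg$end - seg$start + 1L, 7L) - 3))
    pair_ok <- seg$best_lag >= 2L &&
      (is.na(r_lag1) || seg$r_best - r_lag1 >= margin_pair)
    if (pair_ok && length(accepted) + 2L <= max_missing) {
      best_pair <- NULL; t_pair <- -Inf
      for (ai in seq_along(cands)[-length(cands)]) {
        for (bi in (ai + 1L):length(cands)) {
          trial <- apply_missing(cur, c(cands[ai], cands[bi]))
          xi <- index_series(trial, ...)
          tp <- local_diff_t(xi, ri, lo, min(length(xi$index), hi + 2L))
          if (tp > t_pair) { t_pair <- tp; best_pair <- c(cands[ai], cands[bi]) }
        }
      }
      if (is.finite(t_pair) && t_pair - t_ins >= min_improve) {
        ins <- best_pair
        t_ins <- t_pair
      }
    }
    # accept on the local evidence: with further deletions still pending,
    # the whole-series t can dip transiently even for a correct insertion
    if (is.finite(tloc_null) && t_ins - tloc_null < min_improve) break
    ops <- integer(0)
    for (p in sort(ins)) ops <- c(ops, orig_position(orig_map, p))
    if (anyDuplicated(ops) || any(ops %in% accepted)) break
    accepted <- c(accepted, ops)
    cur <- apply_missing(cur, ins)
    for (p in sort(ins, decreasing = TRUE))
      orig_map <- append(orig_map, NA_integer_, after = p - 1L)
    cursor <- max(ins)
    t_new <- whole_series_t(cur, ri, min_overlap = min_overlap, ...)
    ins_sorted <- sort(ins)
    for (j in seq_along(ins_sorted))
      audit[[length(audit) + 1L]] <-
        data.frame(iteration = length(audit) + 1L, segment = seg$segment,
                   position_current = ins_sorted[j],
                   position_original = ops[j],
                   t_before = score, t_after = t_new)
    score <- t_new
    diag <- segment_lag_scan(cur, ri, segment_len = segment_len, step = step,
                             max_lag = max_lag, margin = margin, ...)
  }
  # keep the prefix of insertions that maximizes the whole-series t, so an
  # accepted hypothesis never scores below the uncorrected series
  traj <- c(score_before,
            if (length(audit)) vapply(audit, `[[`, numeric(1), "t_after"))
  best_k <- max(which(traj == max(traj))) - 1L
  keep <- if (best_k > 0L) accepted[seq_len(best_k)] else integer(0)
  structure(list(positions = sort(keep),
                 anchored_first_year = cur$first_year,
                 score_before = score_before, score_after = traj[best_k + 1L],
                 segments = diag,
                 audit = if (best_k > 0L)
                   do.call(rbind, audit[seq_len(best_k)]) else data.frame(),
                 audit_all = if (length(audit)) do.call(rbind, audit)
                 else data.frame()),
            class = "missing_hypothesis")
}

# Correlation t of first differences of two aligned indexed series,
# restricted to positions lo..hi of `xi`. Differenced indices anticorrelate
# under a one-ring shift, which is what localizes an insertion boundary.
local_diff_t <- function(xi, ri, lo, hi) {
  off <- xi$first_year - ri$first_year
  al <- align_pair(xi$index, xi$valid, ri$index, ri$valid, off)
  if (is.null(al) || length(al$x) < 3L) return(-Inf)
  inwin <- al$ia >= lo & al$ia <= hi
  ok <- al$valid[-length(al$valid)] & al$valid[-1L] &
    inwin[-length(inwin)] & inwin[-1L]
  if (sum(ok) < 10L) return(-Inf)
  dx <- diff(al$x)[ok]; dy <- diff(al$y)[ok]
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0) return(-Inf)
  r <- stats::cor(dx, dy)
  n <- sum(ok)
  if (abs(r) >= 1) return(sign(r) * 1e6)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

# Original-series insertion coordinate for an insert-before position in the
# current (already lengthened) series: the next surviving measured ring.
orig_position <- function(orig_map, p) {
  tail_ids <- orig_map[seq.int(p, length(orig_map))]
  tail_ids <- tail_ids[!is.na(tail_ids)]
  if (length(tail_ids)) tail_ids[1] else max(orig_map, na.rm = TRUE) + 1L
}

#' @export
print.missing_hypothesis <- function(x, ...) {
  cat(sprintf("<missing_hypothesis> %d insertion(s); t %.2f -> %.2f\n",
              length(x$positions), x$score_before, x$score_after))
  if (length(x$positions))
    cat("  positions:", paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive missing-ring search (slow verification mode)
#'
#' Evaluates every combination of up to `max_missing` (at most 2)
#' simultaneous insertions and keeps the combination maximizing the
#' whole-series t-value, accepting one more insertion only while it gains at
#' least `min_improve` in t over the best smaller combination. Exact but
#' quadratic in series length; intended as the verification oracle for the
#' greedy [propose_missing()] on short series.
#'
#' @inheritParams propose_missing
#' @return A `missing_hypothesis` (with an empty segment table).
#' @export
exhaustive_missing <- function(series, reference, max_missing = 2L,
                               min_improve = 0.05, min_overlap = 30L, ...) {
  stopifnot(inherits(series, "ring_series"), max_missing <= 2L)
  if (!is_dated(series)) stop("series must be provisionally dated", call. = FALSE)
  ri <- as_index(reference)
  L <- length(series$widths)
  score0 <- whole_series_t(series, ri, min_overlap = min_overlap, ...)
  best <- list(positions = integer(0), t = score0)
  if (max_missing >= 1L) {
    t1 <- vapply(seq_len(L + 1L), function(p)
      whole_series_t(apply_missing(series, p), ri, min_overlap = min_overlap, ...),
      numeric(1))
    p1 <- which.max(t1)
    if (is.finite(t1[p1]) && t1[p1] - best$t >= min_improve)
      best <- list(positions = p1, t = t1[p1])
  }
  if (max_missing >= 2L && length(best$positions) == 1L) {
    best2 <- list(positions = integer(0), t = -Inf)
    for (a in seq_len(L)) {
      for (b in (a + 1L):(L + 1L)) {
        t2 <- whole_series_t(apply_missing(series, c(a, b)), ri,
                             min_overlap = min_overlap, ...)
        if (t2 > best2$t) best2 <- list(positions = c(a, b), t = t2)
      }
    }
    if (is.finite(best2$t) && best2$t - best$t >= min_improve) best <- best2
  }
  structure(list(positions = sort(best$positions),
                 score_before = score0, score_after = best$t,
                 segments = data.frame(), audit = data.frame()),
            class = "missing_hypothesis")
}
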