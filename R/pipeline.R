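#' Merge the measured radii of one disk into a sample series
#'
#' First stage of the hierarchical dating workflow: radii from the same disk
#' are cross-dated against each other (sliding over candidate offsets;
#' missing-ring insertions are proposed per radius against the anchor
#' radius), then combined into one sample series. Radii that cannot be
#' reconciled above the significance thresholds raise an error listing the
#' best candidates — reconciliation is an operator decision, never a silent
#' guess.
#'
#' The longest radius anchors the alignment. Because radii of one shrub
#' differ in vigor, each radius is scaled by its mean measured width before
#' averaging and the result is rescaled by the grand mean, i.e. the merge
#' averages relative (index-like) variation, not raw millimetres. Years
#' covered by no measured ring of any radius (wedging on all radii, or
#' inserted missing rings) become width-0 `missing_inserted` rings, so the
#' sample ring count equals the span of the union of the aligned radii.
#'
#' @param radii List of 1-4 `ring_series` sharing a `sample_id`.
#' @param min_overlap Minimum pairwise overlap for the radius-to-radius
#'   slide (capped at half the shorter radius).
#' @param accept_t,accept_glk Significance thresholds for accepting a
#'   radius alignment.
#' @param detect_missing Logical: propose missing rings per radius against
#'   the anchor (default TRUE).
#' @param max_missing Maximum insertions per radius (default 3).
#' @param ... Indexing arguments (method, window).
#' @return A `ring_series` for the sample (dated if the anchor radius is
#'   dated), with attribute `radius_audit` recording per-radius offsets,
#'   statistics and insertions.
#' @export
merge_radii <- function(radii, min_overlap = 30L, accept_t = 3.5,
                        accept_glk = 0.60, detect_missing = TRUE,
                        max_missing = 3L, ...) {
  if (inherits(radii, "ring_series")) radii <- list(radii)
  nr <- length(radii)
  if (nr < 1L || nr > 4L)
    stop("a disk carries 1 to 4 measured radii", call. = FALSE)
  if (length(unique(vapply(radii, `[[`, character(1), "sample_id"))) != 1L)
    stop("all radii must share one sample_id", call. = FALSE)
  if (nr == 1L) {
    out <- radii[[1L]]
    attr(out, "radius_audit") <-
      data.frame(series_id = out$series_id, offset = 0L,
                 tvalue = NA_real_, glk = NA_real_, n_inserted = 0L)
    return(out)
  }
  lens <- vapply(radii, function(s) length(s$widths), integer(1))
  anchor_i <- which.max(lens)
  anchor <- radii[[anchor_i]]
  pseudo <- !is_dated(anchor)
  if (pseudo) anchor$first_year <- 0L   # internal relative calendar
  anchor_idx <- index_series(anchor, ...)

  audit <- data.frame(series_id = anchor$series_id, offset = 0L,
                      tvalue = NA_real_, glk = NA_real_, n_inserted = 0L)
  aligned <- list(anchor)
  for (j in setdiff(seq_len(nr), anchor_i)) {
    r <- radii[[j]]
    mo <- max(10L, min(min_overlap, length(r$widths) %/% 2L))
    cand <- slide_date(index_series(r, ...), anchor_idx, min_overlap = mo,
                       accept_t = accept_t, accept_glk = accept_glk)
    if (!nrow(cand) || !cand$significant[1L]) {
      top <- utils::head(as.data.frame(cand), 3L)
      stop("radius '", r$series_id, "' cannot be reconciled with '",
           anchor$series_id, "' above t=", accept_t, ", GLK=", accept_glk,
           "; best candidates:\n",
           paste(utils::capture.output(print(top, digits = 3)), collapse = "\n"),
           call. = FALSE)
    }
    r$first_year <- cand$candidate_first_year[1L]
    n_ins <- 0L
    if (detect_missing) {
      mh <- propose_missing(r, anchor_idx, max_missing = max_missing, ...)
      if (length(mh$positions)) {
        r <- apply_missing(r, mh$positions)
        n_ins <- length(mh$positions)
      }
      r$first_year <- mh$anchored_first_year + sum(mh$positions == 1L)
    }
    aligned[[length(aligned) + 1L]] <- r
    audit <- rbind(audit,
                   data.frame(series_id = r$series_id,
                              offset = cand$candidate_first_year[1L] -
                                anchor$first_year,
                              tvalue = cand$tvalue[1L], glk = cand$glk[1L],
                              n_inserted = n_ins))
  }

  fy <- vapply(aligned, `[[`, integer(1), "first_year")
  ly <- fy + vapply(aligned, function(s) length(s$widths), integer(1)) - 1L
  y0 <- min(fy); y1 <- max(ly)
  nyr <- y1 - y0 + 1L
  contrib <- matrix(NA_real_, nrow = nyr, ncol = length(aligned))
  scales <- vapply(aligned, function(s) mean(s$widths[s$ring_flags == "measured"]),
                   numeric(1))
  for (j in seq_along(aligned)) {
    s <- aligned[[j]]
    meas <- s$ring_flags == "measured"
    rows <- (fy[j] - y0 + 1L):(ly[j] - y0 + 1L)
    v <- s$widths / scales[j]
    v[!meas] <- NA_real_
    contrib[rows, j] <- v
  }
  relw <- rowMeans(contrib, na.rm = TRUE)
  has_meas <- !is.nan(relw)
  widths <- ifelse(has_meas, relw * mean(scales), 0)
  flags <- ifelse(has_meas, "measured", "missing_inserted")
  out <- ring_series(widths,
                     first_year = if (pseudo) NA else y0,
                     series_id = anchor$sample_id,
                     sample_id = anchor$sample_id,
                     site_id = anchor$site_id, radius_no = 1L,
                     status = anchor$status, ring_flags = flags)
  attr(out, "radius_audit") <- audit
  out
}

#' Date a sample against a reference chronology and report its age
#'
#' The per-sample dating workflow: slide the sample along the reference and
#' take the best significant placement; propose and insert missing rings;
#' re-date the corrected series; and issue an [age_report()]. The reported
#' age is the cross-dated ring count (measured plus inserted missing rings)
#' at the sampling point — no pith offset or missing inner part is ever
#' added, and the report's caveat says so. A sample with no significant
#' placement is returned undated, with no age claimed: undatable samples
#' are first-class outcomes.
#'
#' @param sample A `ring_series` (typically from [merge_radii()]).
#' @param reference A dated `chronology` or `indexed_series`.
#' @param min_overlap,accept_t,accept_glk Sliding and screening settings
#'   (see [slide_date()]).
#' @param max_missing Maximum missing-ring insertions (default 5).
#' @param offset_range Optional candidate first-year bounds; dead samples
#'   may date earlier than the living span, so the default scans the full
#'   reference.
#' @param bark_year Optional calendar year of the outermost (bark) ring,
#'   known for living samples from the sampling date. Missing rings in the
#'   outermost few rings leave too short a misaligned tail to be detected
#'   statistically; the bark edge pins them: if the dated series ends
#'   short of `bark_year`, the deficit is inserted in the outer segment at
#'   the positions best supported by the local match.
#' @param pith_offset_range Optional informational range of unsampled inner
#'   years carried on the report, never added to the age.
#' @param ... Indexing arguments.
#' @return A list: `series` (the dated, missing-ring-corrected
#'   `ring_series`, or the input if undatable), `report` (an `age_report`),
#'   and `candidates` (the final `crossdate_table`).
#' @export
date_and_report <- function(sample, reference, min_overlap = 50L,
                            accept_t = 3.5, accept_glk = 0.60,
                            max_missing = 5L, offset_range = NULL,
                            bark_year = NULL, pith_offset_range = NULL, ...) {
  stopifnot(inherits(sample, "ring_series"))
  ri <- as_index(reference)
  cand <- slide_date(index_series(sample, ...), ri, min_overlap = min_overlap,
                     offset_range = offset_range,
                     accept_t = accept_t, accept_glk = accept_glk)
  n_meas <- sum(sample$ring_flags == "measured")
  # provisional dating: a series still carrying missing rings may not reach
  # significance at any placement, so the top-ranked placements are tried
  # provisionally, corrected, and only then screened. A placement counts
  # only if the corrected series is significant at its re-slid position.
  n_try <- min(3L, nrow(cand))
  best <- NULL
  for (k in seq_len(n_try)) {
    if (is.na(cand$tvalue[k]) || cand$tvalue[k] <= 0) next
    trial <- sample
    trial$first_year <- cand$candidate_first_year[k]
    mh <- propose_missing(trial, ri, max_missing = max_missing,
                          min_overlap = min(min_overlap, 30L), ...)
    trial <- apply_missing(trial, mh$positions)
    trial$first_year <- mh$anchored_first_year +
      sum(mh$positions == 1L)        # apply_missing already shifted those
    re <- slide_date(index_series(trial, ...), ri, min_overlap = min_overlap,
                     offset_range = offset_range,
                     accept_t = accept_t, accept_glk = accept_glk)
    if (nrow(re) && re$significant[1L] &&
        (is.null(best) || re$tvalue[1L] > best$tvalue)) {
      trial$first_year <- re$candidate_first_year[1L]
      best <- list(series = trial, cand = re, tvalue = re$tvalue[1L])
    }
    # an already-significant uncorrected placement needs no further tries
    if (!is.null(best) && k == 1L && cand$significant[1L] &&
        !length(mh$positions)) break
  }
  if (is.null(best)) {
    rep <- age_report(sample$sample_id, n_meas,
                      sum(sample$ring_flags == "missing_inserted"),
                      first_year = NA, site_id = sample$site_id,
                      status = sample$status, dated = FALSE,
                      pith_offset_range = pith_offset_range)
    return(list(series = sample, report = rep, candidates = cand))
  }
  dated <- best$series
  cand <- best$cand
  if (!is.null(bark_year)) {
    deficit <- bark_year - (dated$first_year + length(dated$widths) - 1L)
    deficit <- max(0L, min(deficit, 5L))
    while (deficit > 0L) {
      L <- length(dated$widths)
      xi0 <- index_series(dated, ...)
      lo <- max(1L, L - 49L)
      cands <- setdiff(lo:L, which(dated$ring_flags == "missing_inserted"))
      tloc <- vapply(cands, function(p) {
        xi <- index_series(apply_missing(dated, p), ...)
        local_diff_t(xi, ri, lo, length(xi$index))
      }, numeric(1))
      p <- cands[order(-tloc, cands)[1L]]
      dated <- apply_missing(dated, p)
      deficit <- deficit - 1L
    }
  }
  rep <- age_report(dated$sample_id,
                    sum(dated$ring_flags == "measured"),
                    sum(dated$ring_flags == "missing_inserted"),
                    first_year = dated$first_year,
                    site_id = dated$site_id, status = dated$status,
                    dated = TRUE, pith_offset_range = pith_offset_range)
  list(series = dated, report = rep, candidates = cand)
}

#' Summarise age reports by site
#'
#' Per-site content of a sampling-campaign overview: the maximum cross-dated
#' age, the number of individuals sampled, and the percentages of living and
#' dead individuals. Because sampling targets the oldest-looking
#' individuals, only maxima are reported — no population age structure is
#' inferred. Undatable samples are counted but excluded from the maximum.
#'
#' @param reports List of `age_report` objects.
#' @return A data.frame sorted by `site_id`: `site_id`, `n_sampled`,
#'   `n_dated`, `max_age`, `pct_living`, `pct_dead`.
#' @export
site_summary <- function(reports) {
  if (inherits(reports, "age_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report", call. = FALSE)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(site_id = r$site_id, status = r$status, dated = r$dated,
               age = if (r$dated) r$age_years else NA_integer_)))
  out <- do.call(rbind, lapply(split(df, df$site_id), function(g)
    data.frame(site_id = g$site_id[1],
               n_sampled = nrow(g),
               n_dated = sum(g$dated),
               max_age = if (any(g$dated)) max(g$age, na.rm = TRUE) else NA_integer_,
               pct_living = 100 * mean(g$status == "living"),
               pct_dead = 100 * mean(g$status == "dead"))))
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan indexing methods and comparison windows for a dated pair
#'
#' Recomputes the three dating statistics (GLK, correlation, t-value) for a
#' dated sample against a reference under every combination of indexing
#' method (moving-average ratio with windows 5, 7, 9; log difference) and
#' comparison window (the first `inner_years` rings of the sample vs the
#' full overlap). Useful for reconciling published dating statistics whose
#' exact standardization settings are unstated.
#'
#' @param sample Dated `ring_series`.
#' @param reference Dated `chronology` or `indexed_series`.
#' @param inner_years Length of the inner comparison window (default 320).
#' @param min_overlap Minimum overlap (default 30).
#' @return A data.frame: `method`, `window`, `span`, `overlap_n`, `glk`,
#'   `corr`, `tvalue`.
#' @export
scan_indexing_methods <- function(sample, reference, inner_years = 320L,
                                  min_overlap = 30L) {
  stopifnot(inherits(sample, "ring_series"), is_dated(sample))
  ri <- as_index(reference)
  combos <- rbind(data.frame(method = "moving_ratio", window = c(5L, 7L, 9L)),
                  data.frame(method = "log_diff", window = NA_integer_))
  inner <- sample
  inner$widths <- utils::head(inner$widths, inner_years)
  inner$ring_flags <- utils::head(inner$ring_flags, inner_years)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    for (span in c("inner", "full")) {
      s <- if (span == "inner") inner else sample
      xi <- if (combos$method[i] == "moving_ratio")
        index_series(s, "moving_ratio", window = combos$window[i])
      else index_series(s, "log_diff")
      oc <- overlap_corr(xi, ri, min_overlap = min_overlap)
      g <- glk(xi, ri)
      t <- if (!is.na(oc$r) && oc$n > 2L) bp_tvalue(oc$r, oc$n) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(method = combos$method[i], window = combos$window[i],
                   span = span, overlap_n = oc$n, glk = g, corr = oc$r,
                   tvalue = t)
    }
  }
  do.call(rbind, rows)
}
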