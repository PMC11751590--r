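#' Construct a ring-width series
#'
#' A `ring_series` holds one measured radius (or a sample/site mean) as an
#' ordered vector of annual ring widths in millimetres, innermost ring first.
#' Ring `i` (1-based) of a dated series formed in calendar year
#' `first_year + i - 1`. Width 0 is reserved for missing rings inserted during
#' cross-dating (`ring_flags == "missing_inserted"`); measured rings must be
#' strictly positive.
#'
#' @param widths Numeric vector of ring widths in mm, innermost first. Length
#'   at least 1, all values >= 0; zeros are only legal where `ring_flags` is
#'   `"missing_inserted"`.
#' @param first_year Calendar year (integer) of the innermost ring, or `NA`
#'   for an undated series.
#' @param series_id,sample_id,site_id Identifiers. `series_id` names one
#'   measurement radius; radii from one disk share `sample_id`.
#' @param radius_no Integer >= 1, which radius of the disk this is.
#' @param status One of `"living"`, `"dead"`, `"unknown"`.
#' @param ring_flags Character vector, same length as `widths`, each element
#'   `"measured"` or `"missing_inserted"`. Defaults to all `"measured"`.
#' @return An object of class `ring_series`.
#' @examples
#' rs <- ring_series(c(0.12, 0.08, 0.10), series_id = "J001A")
#' calendar_span(rs)
#' @export
ring_series <- function(widths, first_year = NA, series_id = "series",
                        sample_id = series_id, site_id = "",
                        radius_no = 1L,
                        status = c("unknown", "living", "dead"),
                        ring_flags = NULL) {
  status <- match.arg(status)
  if (length(widths) == 0L)
    stop("'widths' must contain at least one ring", call. = FALSE)
  widths <- as.numeric(widths)
  if (anyNA(widths))
    stop("'widths' must not contain NA; missing rings are width 0 with flag 'missing_inserted'",
         call. = FALSE)
  if (any(widths < 0))
    stop("ring widths must be >= 0 mm", call. = FALSE)
  if (is.null(ring_flags)) ring_flags <- rep("measured", length(widths))
  if (length(ring_flags) != length(widths))
    stop("'ring_flags' must have the same length as 'widths'", call. = FALSE)
  if (!all(ring_flags %in% c("measured", "missing_inserted")))
    stop("ring flags must be 'measured' or 'missing_inserted'", call. = FALSE)
  bad_zero <- widths == 0 & ring_flags == "measured"
  if (any(bad_zero))
    stop("zero width at measured ring(s) ", paste(which(bad_zero), collapse = ", "),
         ": width 0 is reserved for missing rings; insert them with apply_missing()",
         call. = FALSE)
  bad_pos <- widths > 0 & ring_flags == "missing_inserted"
  if (any(bad_pos))
    stop("missing_inserted rings must have width 0", call. = FALSE)
  if (!is.na(first_year)) first_year <- as.integer(first_year)
  radius_no <- as.integer(radius_no)
  if (is.na(radius_no) || radius_no < 1L)
    stop("'radius_no' must be an integer >= 1", call. = FALSE)
  structure(
    list(series_id = as.character(series_id),
         sample_id = as.character(sample_id),
         site_id = as.character(site_id),
         radius_no = radius_no, status = status,
         first_year = first_year,
         widths = widths, ring_flags = ring_flags),
    class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  sp <- calendar_span(x)
  span <- if (is_dated(x)) sprintf("%d-%d", sp[1], sp[2]) else "undated"
  cat(sprintf("<ring_series> %s (sample %s, site %s, radius %d, %s)\n",
              x$series_id, x$sample_id, x$site_id, x$radius_no, x$status))
  cat(sprintf("  %d rings (%d measured, %d missing inserted), %s\n",
              length(x$widths), sum(x$ring_flags == "measured"),
              sum(x$ring_flags == "missing_inserted"), span))
  invisible(x)
}

#' Is a series anchored to the calendar?
#' @param x A `ring_series` or `indexed_series`.
#' @return `TRUE` if `first_year` is known.
#' @export
is_dated <- function(x) !is.na(x$first_year)

#' Calendar span of a dated series
#'
#' @param series A `ring_series`.
#' @return Integer vector `c(first_year, last_year)` for a dated series;
#'   `NA` for an undated one. A series of length `L` spans
#'   `first_year .. first_year + L - 1`.
#' @export
calendar_span <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  if (!is_dated(series)) return(NA_integer_)
  c(series$first_year, series$first_year + length(series$widths) - 1L)
}

#' Drop the calendar anchoring of a series
#'
#' Returns a copy with `first_year` set to `NA`; used to pose a dating problem
#' for a series whose true placement is known.
#' @param series A `ring_series`.
#' @return The undated copy.
#' @export
undate <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  series$first_year <- NA_integer_
  series
}

#' Per-sample age report
#'
#' Ages are cross-dated ring counts at the sampling point: measured rings plus
#' statistically inserted missing rings. No allowance is made for unmeasured
#' inner wood or pith offset, so the true age of the individual almost
#' certainly exceeds `age_years`; the fixed `caveat` string records this.
#'
#' @param sample_id Sample identifier.
#' @param n_measured,n_missing Ring counts; `age_years` is their sum.
#' @param first_year First (innermost) dated year, `NA` if undatable.
#' @param site_id Site identifier carried through to site summaries.
#' @param status `"living"`, `"dead"` or `"unknown"`.
#' @param dated Logical; `FALSE` for samples with no significant placement.
#' @param pith_offset_range Optional informational range of unsampled inner
#'   years (e.g. `c(10, 200)`); never added to `age_years`.
#' @return An object of class `age_report`.
#' @export
age_report <- function(sample_id, n_measured, n_missing, first_year = NA,
                       site_id = "", status = "unknown", dated = !is.na(first_year),
                       pith_offset_range = NULL) {
  n_measured <- as.integer(n_measured); n_missing <- as.integer(n_missing)
  stopifnot(n_measured >= 0L, n_missing >= 0L)
  age <- n_measured + n_missing
  fy <- if (dated) as.integer(first_year) else NA_integer_
  structure(
    list(sample_id = as.character(sample_id), site_id = as.character(site_id),
         status = status, dated = isTRUE(dated),
         n_measured = n_measured, n_missing = n_missing,
         age_years = age,
         first_year = fy,
         last_year = if (dated) fy + age - 1L else NA_integer_,
         pith_offset_applied = FALSE,
         pith_offset_range = pith_offset_range,
         caveat = paste("Age is the cross-dated ring count at the sampling",
                        "point; no missing inner part or pith offset is added,",
                        "so the individual is almost certainly older than the",
                        "reported age.")),
    class = "age_report")
}

#' @export
print.age_report <- function(x, ...) {
  cat(sprintf("<age_report> %s (%s, %s)\n", x$sample_id, x$site_id, x$status))
  if (x$dated) {
    cat(sprintf("  age %d years (%d measured + %d missing), %d-%d\n",
                x$age_years, x$n_measured, x$n_missing, x$first_year, x$last_year))
  } else {
    cat(sprintf("  UNDATED: %d measured rings, no age claimed\n", x$n_measured))
  }
  cat("  note:", x$caveat, "\n")
  invisible(x)
}
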