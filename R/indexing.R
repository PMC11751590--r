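#' Construct an indexed (high-pass) series
#'
#' Container for the dimensionless index all cross-dating statistics operate
#' on. `valid` marks positions usable for statistics; positions lost to edge
#' effects of the detrending window or occupied by inserted missing rings are
#' invalid and excluded downstream, never imputed.
#'
#' @param index Numeric vector of index values (may contain NA at invalid
#'   positions).
#' @param first_year Calendar year of position 1, or `NA` if undated.
#' @param valid Logical vector, same length as `index`.
#' @param source_id Identifier of the series the index came from.
#' @return An object of class `indexed_series`.
#' @export
indexed_series <- function(index, first_year = NA, valid = !is.na(index),
                           source_id = "index") {
  index <- as.numeric(index)
  if (length(valid) != length(index))
    stop("'valid' must have the same length as 'index'", call. = FALSE)
  if (!is.na(first_year)) first_year <- as.integer(first_year)
  structure(list(source_id = as.character(source_id),
                 first_year = first_year,
                 index = index, valid = as.logical(valid) & !is.na(index)),
            class = "indexed_series")
}

#' @export
print.indexed_series <- function(x, ...) {
  span <- if (!is.na(x$first_year))
    sprintf("%d-%d", x$first_year, x$first_year + length(x$index) - 1L) else "undated"
  cat(sprintf("<indexed_series> %s: %d positions (%d valid), %s\n",
              x$source_id, length(x$index), sum(x$valid), span))
  invisible(x)
}

#' High-pass index a ring-width series
#'
#' Converts raw widths to a dimensionless index so that cross-dating
#' statistics compare year-to-year variation rather than age trend or
#' individual vigor.
#'
#' Two methods are offered. `"moving_ratio"` divides each width by a centred
#' moving average over `window` years (the classical high-pass preceding
#' t-value dating); the `(window-1)/2` positions at each edge are marked
#' invalid, and inserted missing rings are excluded from the moving average
#' (their position is invalid and they contribute no width to their
#' neighbours' average). `"log_diff"` takes first differences of log widths;
#' position 1 is invalid, missing rings take the value `zero_replacement`
#' before the log, and both differences touching a missing ring are marked
#' invalid.
#'
#' Both indices are scale invariant: multiplying all widths by a positive
#' constant leaves `moving_ratio` unchanged exactly, and shifts `log_diff`
#' not at all (differences of a constant log offset cancel). The mean of
#' valid `moving_ratio` values is close to the nominal centre 1.0;
#' `log_diff` centres near 0.
#'
#' @param series A `ring_series`.
#' @param method `"moving_ratio"` (default) or `"log_diff"`.
#' @param window Odd integer >= 3; moving-average length for
#'   `"moving_ratio"`.
#' @param zero_replacement Small width in mm substituted for missing rings
#'   before the transform. Default 0.005, half the smallest width expressible
#'   at 0.01 mm resolution.
#' @return An `indexed_series` with the same length and dating as `series`.
#' @examples
#' rs <- ring_series(rep(1, 7))
#' index_series(rs, "moving_ratio", window = 5)$index
#' @export
index_series <- function(series, method = c("moving_ratio", "log_diff"),
                         window = 5L, zero_replacement = 0.005) {
  stopifnot(inherits(series, "ring_series"))
  method <- match.arg(method)
  L <- length(series$widths)
  miss <- series$ring_flags == "missing_inserted"
  w <- pmax(series$widths, zero_replacement)
  if (method == "moving_ratio") {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
      stop("'window' must be an odd integer >= 3", call. = FALSE)
    if (L <= window)
      stop(sprintf("series of length %d is too short for moving_ratio with window %d",
                   L, window), call. = FALSE)
    # the moving average skips missing rings (they carry no measured width;
    # averaging a token width in would distort the index of their neighbours)
    kern <- rep(1, window)
    wsum <- as.numeric(stats::filter(ifelse(miss, 0, w), kern, sides = 2))
    wcnt <- as.numeric(stats::filter(as.numeric(!miss), kern, sides = 2))
    ma <- ifelse(wcnt > 0, wsum / wcnt, NA_real_)
    idx <- w / ma
    valid <- !is.na(idx) & !miss
    idx[!valid] <- NA_real_
  } else {
    if (L < 2L)
      stop("series too short for log_diff (needs >= 2 rings)", call. = FALSE)
    idx <- c(NA_real_, diff(log(w)))
    valid <- rep(TRUE, L)
    valid[1L] <- FALSE
    valid[miss] <- FALSE
    nxt <- which(miss) + 1L              # difference into a missing ring
    valid[nxt[nxt <= L]] <- FALSE
    idx[!valid] <- NA_real_
  }
  indexed_series(idx, first_year = series$first_year, valid = valid,
                 source_id = series$series_id)
}

# Coerce ring_series / chronology to indexed_series for the statistics layer.
as_index <- function(x, ...) {
  if (inherits(x, "indexed_series")) return(x)
  if (inherits(x, "ring_series")) return(index_series(x, ...))
  if (inherits(x, "chronology")) {
    ok <- x$depth >= 1L & !is.na(x$values)
    return(indexed_series(x$values, first_year = x$first_year, valid = ok,
                          source_id = "chronology"))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an indexed series", call. = FALSE)
}
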