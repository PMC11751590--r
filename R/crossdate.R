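# Alignment of two position-indexed vectors: position i of `a` is paired with
# position i + offset of `b`. Returns NULL when there is no overlap.
align_pair <- function(av, avalid, bv, bvalid, offset) {
  na <- length(av); nb <- length(bv)
  i0 <- max(1L, 1L - offset)
  i1 <- min(na, nb - offset)
  if (i1 < i0) return(NULL)
  ia <- i0:i1
  list(x = av[ia], y = bv[ia + offset],
       valid = avalid[ia] & bvalid[ia + offset], ia = ia)
}

# Resolve the pairing offset: explicit, or derived from two dated inputs.
resolve_offset <- function(a, b, offset) {
  if (!is.null(offset)) return(as.integer(offset))
  if (is.na(a$first_year) || is.na(b$first_year))
    stop("'offset' must be given when either series is undated", call. = FALSE)
  a$first_year - b$first_year
}

#' Gleichlaeufigkeit (sign-agreement) statistic
#'
#' Fraction of year-to-year changes on which two overlapping series agree in
#' sign. Over the aligned overlap, first differences of both series are
#' compared pairwise: a pair scores 1 when the signs agree strictly, 0 when
#' they are strictly opposite, and 1/2 when either difference is exactly
#' zero. GLK is the mean score, in [0, 1]; 0.5 is chance agreement.
#'
#' GLK is symmetric: `glk(a, b, k) == glk(b, a, -k)`.
#'
#' @param a,b `ring_series` or `indexed_series`. Raw series are compared on
#'   raw width differences, indexed series on index differences; mixing the
#'   two is not allowed.
#' @param offset Integer pairing offset: position `i` of `a` is paired with
#'   position `i + offset` of `b`. Defaults to the offset implied by the two
#'   `first_year`s when both are dated.
#' @param min_pairs Minimum number of difference pairs required; below it the
#'   statistic is undefined and `NA` is returned.
#' @return GLK in [0, 1], or `NA` when fewer than `min_pairs` difference
#'   pairs are available.
#' @export
glk <- function(a, b, offset = NULL, min_pairs = 1L) {
  va <- series_values(a); vb <- series_values(b)
  off <- resolve_offset(va, vb, offset)
  al <- align_pair(va$values, va$valid, vb$values, vb$valid, off)
  if (is.null(al) || length(al$x) < 2L) return(NA_real_)
  ok <- al$valid[-length(al$valid)] & al$valid[-1L]
  dx <- diff(al$x)[ok]
  dy <- diff(al$y)[ok]
  if (length(dx) < min_pairs) return(NA_real_)
  s <- ifelse(dx == 0 | dy == 0, 0.5, as.numeric(sign(dx) == sign(dy)))
  mean(s)
}

# Uniform view of values + validity for glk/correlation inputs.
series_values <- function(x) {
  if (inherits(x, "indexed_series"))
    return(list(values = x$index, valid = x$valid, first_year = x$first_year))
  if (inherits(x, "ring_series"))
    return(list(values = x$widths, valid = x$ring_flags == "measured",
                first_year = x$first_year))
  if (inherits(x, "chronology")) {
    xi <- as_index(x)
    return(list(values = xi$index, valid = xi$valid, first_year = xi$first_year))
  }
  stop("expected a ring_series, indexed_series or chronology", call. = FALSE)
}

#' Overlap Pearson correlation
#'
#' Pearson correlation between two series over their jointly valid overlap at
#' a given pairing offset, returned together with the overlap size actually
#' used.
#'
#' @inheritParams glk
#' @param min_overlap Minimum jointly valid overlap; below it `r` is `NA`
#'   (the overlap count is still returned).
#' @return A list with elements `r` (Pearson correlation, `NA` when the
#'   overlap is insufficient or either window has zero variance) and `n`
#'   (number of jointly valid positions).
#' @export
overlap_corr <- function(a, b, offset = NULL, min_overlap = 50L) {
  va <- series_values(a); vb <- series_values(b)
  off <- resolve_offset(va, vb, offset)
  al <- align_pair(va$values, va$valid, vb$values, vb$valid, off)
  if (is.null(al)) return(list(r = NA_real_, n = 0L))
  n <- sum(al$valid)
  if (n < min_overlap) return(list(r = NA_real_, n = n))
  x <- al$x[al$valid]; y <- al$y[al$valid]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(list(r = NA_real_, n = n))
  list(r = stats::cor(x, y), n = n)
}

#' Baillie-Pilcher t-value
#'
#' Transforms an overlap correlation into the classical dating score:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, a t statistic on `n - 2` degrees of
#' freedom. Negative correlations yield negative t; callers rank on t, not
#' |t|, because inverted matches are physically meaningless for ring series.
#'
#' @param r Pearson correlation in (-1, 1).
#' @param n Overlap length, > 2.
#' @return The t-value. When `|r| >= 1` the formula overflows, and a
#'   documented large sentinel `sign(r) * 1e6` is returned with a warning.
#' @export
bp_tvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (n <= 2) stop("t-value requires overlap n > 2", call. = FALSE)
  if (abs(r) >= 1) {
    warning("|r| >= 1: returning overflow sentinel sign(r) * 1e6")
    return(sign(r) * 1e6)
  }
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Slide an undated series along a dated reference
#'
#' Scans every candidate calendar placement of a series against a dated
#' reference (an `indexed_series` or `chronology`) and scores each with the
#' three dating statistics: overlap correlation, Baillie-Pilcher t-value and
#' GLK. Candidates are ranked by t-value (ties broken by larger GLK, then
#' larger overlap, then smaller |candidate first year|). A candidate is
#' flagged `significant` when `t >= accept_t`, `glk >= accept_glk` and the
#' correlation is positive.
#'
#' @param x The series to place: `ring_series` (indexed with defaults) or
#'   `indexed_series`; may be dated (its dating is ignored during the scan).
#' @param reference Dated `indexed_series` or `chronology`.
#' @param min_overlap Minimum jointly valid overlap for a candidate (default
#'   50 years).
#' @param offset_range Optional inclusive bounds `c(y1, y2)` on the candidate
#'   first year.
#' @param accept_t,accept_glk Screening thresholds for the `significant`
#'   flag; conventional defaults 3.5 and 0.60, reported in the output so the
#'   criteria in force are always explicit.
#' @return A data.frame of class `crossdate_table`, one row per candidate:
#'   `candidate_first_year`, `overlap_n`, `glk`, `corr`, `tvalue`,
#'   `significant`, `rank`, sorted by rank. Attribute `status` is `"ok"` or
#'   explains an empty result; attribute `thresholds` records the screening
#'   settings.
#' @export
slide_date <- function(x, reference, min_overlap = 50L, offset_range = NULL,
                       accept_t = 3.5, accept_glk = 0.60) {
  xi <- as_index(x)
  ri <- as_index(reference)
  if (is.na(ri$first_year))
    stop("'reference' must be dated", call. = FALSE)
  min_overlap <- max(10L, as.integer(min_overlap))
  L <- length(xi$index); nref <- length(ri$index)
  ref_fy <- ri$first_year
  years <- (ref_fy - L + 1L):(ref_fy + nref - 1L)
  if (!is.null(offset_range))
    years <- years[years >= offset_range[1] & years <= offset_range[2]]
  rows <- vector("list", length(years))
  k <- 0L
  for (Y in years) {
    off <- Y - ref_fy
    # raw overlap bound before doing any work
    if (min(L, nref - off) - max(1L, 1L - off) + 1L < min_overlap) next
    oc <- overlap_corr(xi, ri, offset = off, min_overlap = min_overlap)
    if (oc$n < min_overlap) next
    g <- glk(xi, ri, offset = off)
    t <- if (!is.na(oc$r) && oc$n > 2L) {
      if (abs(oc$r) >= 1) sign(oc$r) * 1e6
      else oc$r * sqrt(oc$n - 2) / sqrt(1 - oc$r^2)
    } else NA_real_
    k <- k + 1L
    rows[[k]] <- c(Y, oc$n, g, oc$r, t)
  }
  if (k == 0L) {
    out <- data.frame(candidate_first_year = integer(), overlap_n = integer(),
                      glk = numeric(), corr = numeric(), tvalue = numeric(),
                      significant = logical(), rank = integer())
    attr(out, "status") <- "no candidate placement reaches the minimum overlap"
  } else {
    m <- do.call(rbind, rows[seq_len(k)])
    out <- data.frame(candidate_first_year = as.integer(m[, 1]),
                      overlap_n = as.integer(m[, 2]),
                      glk = m[, 3], corr = m[, 4], tvalue = m[, 5])
    out$significant <- !is.na(out$tvalue) & !is.na(out$glk) &
      out$tvalue >= accept_t & out$glk >= accept_glk & out$corr > 0
    ord <- order(-out$tvalue, -out$glk, -out$overlap_n,
                 abs(out$candidate_first_year), na.last = TRUE)
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    attr(out, "status") <- "ok"
  }
  attr(out, "thresholds") <- c(min_overlap = min_overlap,
                               accept_t = accept_t, accept_glk = accept_glk)
  class(out) <- c("crossdate_table", "data.frame")
  out
}

#' @export
print.crossdate_table <- function(x, n = 5L, ...) {
  cat(sprintf("<crossdate_table> %d candidates (status: %s)\n",
              nrow(x), attr(x, "status")))
  if (nrow(x)) print.data.frame(utils::head(x, n), digits = 3)
  invisible(x)
}
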