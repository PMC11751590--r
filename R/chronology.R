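# One-step Tukey biweight robust mean, tuning constant C (classical choice 9).
# Falls back to the median when the MAD is 0.
tbrm_mean <- function(x, C = 9) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  m <- stats::median(x)
  S <- stats::median(abs(x - m))
  if (S == 0) return(m)
  u <- (x - m) / (C * S)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Build a mean chronology from dated indexed series
#'
#' Collates dated indexed series into a year-indexed reference: for each
#' calendar year, the value is the Tukey biweight robust mean (tuning
#' constant 9) of the contributing valid indices when at least 4 series
#' contribute, and the arithmetic mean otherwise; the per-year sample depth
#' is recorded alongside. Chronologies are always built on indexed series,
#' never raw widths, so that age-trend and vigor differences between
#' individuals do not dominate the mean.
#'
#' @param indexed List of dated `indexed_series` (a single one is accepted).
#' @param robust Logical; `FALSE` forces the arithmetic mean at all depths.
#' @param robust_min_depth Depth at which the biweight kicks in (default 4).
#' @return An object of class `chronology`: `first_year`, `values`, `depth`,
#'   and `rbar` (mean pairwise inter-series correlation over the full span,
#'   `NA` with fewer than 2 series).
#' @export
build_chronology <- function(indexed, robust = TRUE, robust_min_depth = 4L) {
  if (inherits(indexed, "indexed_series")) indexed <- list(indexed)
  if (!length(indexed)) stop("need at least one series", call. = FALSE)
  if (!all(vapply(indexed, inherits, logical(1), "indexed_series")))
    stop("inputs must be indexed_series (see index_series())", call. = FALSE)
  fy <- vapply(indexed, `[[`, integer(1), "first_year")
  if (anyNA(fy)) stop("all series must be dated to build a chronology", call. = FALSE)
  ly <- fy + vapply(indexed, function(s) length(s$index), integer(1)) - 1L
  y0 <- min(fy); y1 <- max(ly)
  nyrs <- y1 - y0 + 1L
  mat <- matrix(NA_real_, nrow = nyrs, ncol = length(indexed))
  for (j in seq_along(indexed)) {
    s <- indexed[[j]]
    rows <- (fy[j] - y0 + 1L):(ly[j] - y0 + 1L)
    v <- s$index
    v[!s$valid] <- NA_real_
    mat[rows, j] <- v
  }
  depth <- rowSums(!is.na(mat))
  values <- rep(NA_real_, nyrs)
  for (i in which(depth >= 1L)) {
    xi <- mat[i, ]
    values[i] <- if (robust && depth[i] >= robust_min_depth) tbrm_mean(xi)
    else mean(xi, na.rm = TRUE)
  }
  # trim leading/trailing years with no contributors
  keep <- range(which(depth >= 1L))
  values <- values[keep[1]:keep[2]]
  depth <- depth[keep[1]:keep[2]]
  rb <- if (length(indexed) >= 2L)
    rbar_eps(indexed)$rbar else NA_real_
  structure(list(first_year = y0 + keep[1] - 1L, values = values,
                 depth = as.integer(depth), rbar = rb),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %d-%d (%d years), depth 1-%d, rbar %s\n",
              x$first_year, x$first_year + length(x$values) - 1L,
              length(x$values), max(x$depth),
              if (is.na(x$rbar)) "NA" else sprintf("%.3f", x$rbar)))
  invisible(x)
}

#' Mean inter-series correlation and expressed population signal
#'
#' Chronology-quality diagnostics: `rbar` is the mean pairwise Pearson
#' correlation between indexed series over a stated common window, and
#' `EPS = n * rbar / (n * rbar + (1 - rbar))` with `n` the mean sample depth
#' in the window — the fraction of the hypothetical population signal
#' expressed by the available sample.
#'
#' @param indexed List of >= 2 dated `indexed_series`.
#' @param window Inclusive year bounds `c(y1, y2)`; default the union span.
#' @param min_pair_overlap Minimum jointly valid years for a pair to
#'   contribute a correlation (default 30).
#' @return A list: `rbar`, `eps`, `n_eff` (mean depth in the window),
#'   `n_pairs` (pairs contributing), and `status`. With insufficient overlap
#'   everything is `NA` and `status` says so.
#' @export
rbar_eps <- function(indexed, window = NULL, min_pair_overlap = 30L) {
  if (length(indexed) < 2L)
    stop("rbar needs at least two series", call. = FALSE)
  fy <- vapply(indexed, `[[`, integer(1), "first_year")
  if (anyNA(fy)) stop("all series must be dated", call. = FALSE)
  ly <- fy + vapply(indexed, function(s) length(s$index), integer(1)) - 1L
  if (is.null(window)) window <- c(min(fy), max(ly))
  rs <- numeric(0)
  for (i in seq_along(indexed)[-length(indexed)]) {
    for (j in (i + 1L):length(indexed)) {
      a <- indexed[[i]]; b <- indexed[[j]]
      # restrict both to the window
      clip <- function(s) {
        yrs <- s$first_year + seq_along(s$index) - 1L
        keep <- yrs >= window[1] & yrs <= window[2]
        if (!any(keep)) return(NULL)
        indexed_series(s$index[keep], first_year = yrs[keep][1],
                       valid = s$valid[keep], source_id = s$source_id)
      }
      ac <- clip(a); bc <- clip(b)
      if (is.null(ac) || is.null(bc)) next
      oc <- overlap_corr(ac, bc, min_overlap = min_pair_overlap)
      if (!is.na(oc$r)) rs <- c(rs, oc$r)
    }
  }
  if (!length(rs))
    return(list(rbar = NA_real_, eps = NA_real_, n_eff = NA_real_,
                n_pairs = 0L,
                status = "no series pair reaches the minimum overlap in the window"))
  rbar <- mean(rs)
  yrs_all <- window[1]:window[2]
  depth <- rowSums(vapply(indexed, function(s) {
    yrs <- s$first_year + seq_along(s$index) - 1L
    out <- logical(length(yrs_all))
    hit <- match(yrs, yrs_all)
    ok <- !is.na(hit)
    out[hit[ok]] <- s$valid[ok]
    out
  }, logical(length(yrs_all))))
  n_eff <- mean(depth[depth >= 1L])
  eps <- n_eff * rbar / (n_eff * rbar + (1 - rbar))
  list(rbar = rbar, eps = eps, n_eff = n_eff, n_pairs = length(rs),
       status = "ok")
}
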