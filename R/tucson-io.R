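#' Tucson dialect description
#'
#' The Tucson decadal (.rwl) interchange format stores integer widths in
#' either hundredths of a millimetre (series terminated by the stop marker
#' 999) or thousandths (stop marker -9999). The two are mutually consistent:
#' the marker identifies the unit.
#'
#' @param units `"hundredths_mm"` or `"thousandths_mm"`.
#' @return A list with `units`, `scale` (counts per mm) and `stop_marker`.
#' @export
tucson_dialect <- function(units = c("hundredths_mm", "thousandths_mm")) {
  units <- match.arg(units)
  if (units == "hundredths_mm")
    list(units = units, scale = 100, stop_marker = 999L)
  else
    list(units = units, scale = 1000, stop_marker = -9999L)
}

#' Read ring-width series from a Tucson decadal (.rwl) file
#'
#' Each data line carries an 8-character series id, the calendar year of the
#' line's first value, and up to 10 integer widths; a series ends with its
#' stop marker. The dialect is detected from the stop marker found in the
#' file (-9999 implies thousandths of a mm, otherwise hundredths); mixing
#' dialects in one file is an error. Value 0 encodes a locally absent
#' (missing) ring and is read back as a width-0 ring flagged
#' `missing_inserted`. Up to three leading non-data header lines are consumed
#' and ignored.
#'
#' @param path Path to the file, or a character vector of lines.
#' @return A list of dated `ring_series`, in file order.
#' @export
read_tucson <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Tucson file", call. = FALSE)

  parse_line <- function(ln) {
    id <- trimws(substr(ln, 1L, 8L))
    rest <- strsplit(trimws(substr(ln, 9L, nchar(ln))), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.integer(rest))
    if (!nzchar(id) || length(vals) < 2L || anyNA(vals)) return(NULL)
    list(id = id, year = vals[1], values = vals[-1])
  }

  parsed <- lapply(lines, parse_line)
  bad <- which(vapply(parsed, is.null, logical(1)))
  if (length(bad)) {
    # tolerate up to 3 leading header lines, nothing else
    if (!all(bad <= 3L) || any(diff(bad) != 1L) || bad[1] != 1L)
      stop("unparseable Tucson data line at line ", bad[which(bad > 3L)[1] %||% bad[1]],
           call. = FALSE)
    parsed <- parsed[-bad]
  }
  if (!length(parsed)) stop("no data lines in Tucson file", call. = FALSE)

  all_vals <- unlist(lapply(parsed, `[[`, "values"))
  thous <- any(all_vals == -9999L)
  dialect <- tucson_dialect(if (thous) "thousandths_mm" else "hundredths_mm")
  if (!thous && any(all_vals < 0))
    stop("negative width value without a -9999 stop marker: mixed or corrupt dialect",
         call. = FALSE)

  ids <- vapply(parsed, `[[`, character(1), "id")
  runs <- rle(ids)
  stops_seen <- 0L
  out <- list()
  pos <- 1L
  for (ri in seq_along(runs$lengths)) {
    idx <- pos:(pos + runs$lengths[ri] - 1L)
    pos <- pos + runs$lengths[ri]
    id <- runs$values[ri]
    vals <- integer(0)
    expect_year <- NA_integer_
    first_year <- parsed[[idx[1]]]$year
    ended <- FALSE
    for (j in idx) {
      p <- parsed[[j]]
      if (ended)
        stop("data after stop marker for series '", id, "'", call. = FALSE)
      if (!is.na(expect_year) && p$year != expect_year)
        stop(sprintf("decade arithmetic broken for series '%s': expected year %d, found %d",
                     id, expect_year, p$year), call. = FALSE)
      v <- p$values
      stop_at <- which(v == dialect$stop_marker)
      if (length(stop_at)) {
        if (stop_at[1] < length(v))
          stop("values after stop marker for series '", id, "'", call. = FALSE)
        v <- v[seq_len(stop_at[1] - 1L)]
        ended <- TRUE
      }
      if (any(v < 0))
        stop("negative width in series '", id, "' is not the dialect's stop marker",
             call. = FALSE)
      vals <- c(vals, v)
      expect_year <- p$year + length(v)
    }
    if (!ended)
      stop("missing stop marker at end of series '", id, "'", call. = FALSE)
    stops_seen <- stops_seen + 1L
    if (!length(vals))
      stop("series '", id, "' has a stop marker but no values", call. = FALSE)
    flags <- ifelse(vals == 0L, "missing_inserted", "measured")
    out[[length(out) + 1L]] <-
      ring_series(vals / dialect$scale, first_year = first_year,
                  series_id = id, sample_id = id,
                  ring_flags = flags)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' Write ring-width series to Tucson decadal (.rwl) format
#'
#' Widths are quantized to the dialect's resolution; any positive width
#' smaller than one quantum is written as one quantum, never as 0, because 0
#' is reserved for missing rings. Series ids longer than 8 characters are
#' deterministically truncated; a collision after truncation is an error. No
#' site header is written.
#'
#' @param series A `ring_series` or list of them; all must be dated.
#' @param path Output file path, or `NULL` to return the lines.
#' @param dialect A [tucson_dialect()]; default hundredths of a mm.
#' @return Invisibly, the character vector of lines written.
#' @export
write_tucson <- function(series, path = NULL,
                         dialect = tucson_dialect("hundredths_mm")) {
  if (inherits(series, "ring_series")) series <- list(series)
  if (!length(series)) stop("no series to write", call. = FALSE)
  ids <- vapply(series, `[[`, character(1), "series_id")
  short <- substr(ids, 1L, 8L)
  if (anyDuplicated(short))
    stop("series ids collide after truncation to 8 characters: ",
         paste(unique(short[duplicated(short)]), collapse = ", "), call. = FALSE)
  lines <- character(0)
  for (k in seq_along(series)) {
    s <- series[[k]]
    if (!is_dated(s))
      stop("series '", s$series_id,
           "' is undated; date it or use write_long_table()", call. = FALSE)
    counts <- as.integer(round(s$widths * dialect$scale))
    counts[s$widths > 0 & counts == 0L] <- 1L      # quantization floor
    counts[s$ring_flags == "missing_inserted"] <- 0L
    stream <- c(counts, dialect$stop_marker)
    yr <- s$first_year
    i <- 1L
    while (i <= length(stream)) {
      n_this <- 10L - (yr %% 10L + 10L) %% 10L
      take <- min(n_this, length(stream) - i + 1L)
      vals <- stream[i:(i + take - 1L)]
      lines <- c(lines, paste0(formatC(short[k], width = -8L),
                               formatC(yr, width = 4L),
                               paste(formatC(vals, width = 6L), collapse = "")))
      yr <- yr + take
      i <- i + take
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read ring-width series from a long-format delimited table
#'
#' Expects a header row and columns for the series id, the year (dated) or
#' ring index (undated), and the width in mm; optional columns give the ring
#' flag, sample id, site id and status. Comma and tab delimiters are
#' auto-detected.
#'
#' @param path File path or character vector of lines.
#' @param column_map Named character vector mapping roles to column names;
#'   recognised roles: `series`, `year`, `index`, `width`, `flag`, `sample`,
#'   `site`, `status`.
#' @return A list of `ring_series`.
#' @export
read_long_table <- function(path,
                            column_map = c(series = "series_id", year = "year",
                                           index = "ring_index", width = "width_mm",
                                           flag = "flag", sample = "sample_id",
                                           site = "site_id", status = "status")) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- function(role) {
    nm <- column_map[[role]]
    if (is.null(nm) || !nm %in% names(df)) NULL else df[[nm]]
  }
  sid <- need("series")
  wid <- need("width")
  if (is.null(sid) || is.null(wid))
    stop("long table must contain the series id and width columns", call. = FALSE)
  yr <- need("year")
  ridx <- need("index")
  if (is.null(yr) && is.null(ridx))
    stop("long table must contain a year or ring index column", call. = FALSE)
  posn <- if (!is.null(yr)) yr else ridx
  flag <- need("flag")
  samp <- need("sample"); site <- need("site"); stat <- need("status")
  out <- list()
  for (id in unique(sid)) {
    rows <- which(sid == id)
    p <- posn[rows]
    if (anyDuplicated(p))
      stop("duplicate (series, year) rows for series '", id, "'", call. = FALSE)
    if (is.unsorted(p, strictly = TRUE))
      stop("years not strictly increasing within series '", id, "'", call. = FALSE)
    if (any(diff(p) != 1L))
      stop("years must be consecutive within series '", id,
           "' (represent missing rings as width 0 rows)", call. = FALSE)
    fl <- if (!is.null(flag)) flag[rows] else
      ifelse(wid[rows] == 0, "missing_inserted", "measured")
    out[[length(out) + 1L]] <- ring_series(
      wid[rows],
      first_year = if (!is.null(yr)) p[1] else NA,
      series_id = id,
      sample_id = if (!is.null(samp)) samp[rows][1] else id,
      site_id = if (!is.null(site)) site[rows][1] else "",
      status = if (!is.null(stat)) stat[rows][1] else "unknown",
      ring_flags = fl)
  }
  out
}

#' Write ring-width series as a long-format table
#'
#' One row per ring with columns `series_id`, `sample_id`, `site_id`,
#' `status`, `year` (or `ring_index` for undated series), `width_mm`,
#' `flag`. Round-trips through [read_long_table()].
#'
#' @param series A `ring_series` or list of them.
#' @param path Output path, or `NULL` to return lines.
#' @param sep Field separator, default comma.
#' @return Invisibly, the lines written.
#' @export
write_long_table <- function(series, path = NULL, sep = ",") {
  if (inherits(series, "ring_series")) series <- list(series)
  dated <- all(vapply(series, is_dated, logical(1)))
  poscol <- if (dated) "year" else "ring_index"
  rows <- lapply(series, function(s) {
    L <- length(s$widths)
    p <- if (dated) s$first_year + seq_len(L) - 1L else seq_len(L)
    data.frame(series_id = s$series_id, sample_id = s$sample_id,
               site_id = s$site_id, status = s$status,
               pos = p, width_mm = s$widths, flag = s$ring_flags,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "pos"] <- poscol
  lines <- c(paste(names(df), collapse = sep),
             do.call(paste, c(unname(df), sep = sep)))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
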