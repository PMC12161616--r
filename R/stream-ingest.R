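#' Read raw sensor stream files
#'
#' Reads the three-stream CSV dialect (see [write_streams()]) from a
#' directory or an explicit set of paths, parses ISO-8601 timestamps to
#' seconds since local midnight, drops malformed rows with a counted
#' warning, and infers watch-data gaps from missing accelerometer
#' minutes.
#'
#' Contract: one calendar day per file set. A file whose header does not
#' match the dialect is a hard error; a row whose timestamp or value
#' fields do not parse is skipped and counted; out-of-order timestamps
#' within a stream are a hard error naming the offending row.
#'
#' @param dir directory containing `accel.csv`, `hr.csv`, `wheel.csv`.
#'   Missing `hr.csv` / `wheel.csv` are treated as empty streams.
#' @param paths optional named list overriding individual file paths
#'   (`accel`, `hr`, `wheel`).
#' @param day_date optional Date; defaults to the date of the first
#'   parsed sample. Samples on any other date are an error.
#' @return a `wf_streams` object (see [render_streams()]) with an extra
#'   `skipped` field: named counts of dropped rows per stream.
#' @export
read_streams <- function(dir = NULL, paths = NULL, day_date = NULL) {
  p <- list(accel = "accel.csv", hr = "hr.csv", wheel = "wheel.csv")
  if (!is.null(dir)) p <- lapply(p, function(f) file.path(dir, f))
  if (!is.null(paths)) p[names(paths)] <- paths
  if (!file.exists(p$accel)) stop("accelerometer file not found: ", p$accel)

  acc <- read_stream_file(p$accel, c("ax", "ay", "az"))
  hr <- if (file.exists(p$hr)) read_stream_file(p$hr, "bpm") else empty_stream("bpm")
  whl <- if (file.exists(p$wheel)) read_stream_file(p$wheel, "rotations") else
    empty_stream("rotations")

  dates <- unique(c(acc$date, hr$date, whl$date))
  if (is.null(day_date)) {
    day_date <- if (length(dates)) as.Date(dates[1]) else Sys.Date()
  }
  if (length(dates) && !all(dates == format(day_date))) {
    stop("samples outside day ", format(day_date), ": found date(s) ",
         paste(setdiff(dates, format(day_date)), collapse = ", "))
  }

  skipped <- c(accel = acc$skipped, hr = hr$skipped, wheel = whl$skipped)
  if (sum(skipped) > 0) {
    warning(sum(skipped), " malformed row(s) skipped (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  }
  structure(
    list(participant_id = NA_character_, day_date = day_date,
         accel = acc$data, hr = hr$data, wheel = whl$data,
         gaps = gaps_from_minutes(unique(floor(acc$data$time / 60))),
         skipped = skipped),
    class = "wf_streams")
}

empty_stream <- function(value_cols) {
  d <- c(list(time = numeric()),
         stats::setNames(rep(list(numeric()), length(value_cols)), value_cols))
  list(data = data.table::as.data.table(d), date = character(), skipped = 0L)
}

ISO_RE <- "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?$"

read_stream_file <- function(path, value_cols) {
  dt <- data.table::fread(path, colClasses = "character")
  expected <- c("iso_timestamp", value_cols)
  if (!identical(names(dt), expected)) {
    stop("unparseable header in ", path, ": expected columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    out <- empty_stream(value_cols)
    return(out)
  }
  ts_ok <- grepl(ISO_RE, dt$iso_timestamp)
  vals <- lapply(value_cols, function(cn) suppressWarnings(as.numeric(dt[[cn]])))
  val_ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  keep <- ts_ok & val_ok
  skipped <- sum(!keep)
  dt <- dt[keep]
  vals <- lapply(vals, function(v) v[keep])
  ts <- dt$iso_timestamp
  secs <- as.numeric(substr(ts, 12, 13)) * 3600 +
    as.numeric(substr(ts, 15, 16)) * 60 +
    as.numeric(substr(ts, 18, nchar(ts)))
  bad <- which(diff(secs) <= 0)
  if (length(bad)) {
    stop("out-of-order timestamp in ", path, " at row ", bad[1] + 1L,
         " (", ts[bad[1] + 1L], ")", call. = FALSE)
  }
  data <- data.table::as.data.table(
    c(list(time = secs), stats::setNames(vals, value_cols)))
  list(data = data, date = unique(substr(ts, 1, 10)), skipped = skipped)
}

#' Bin streams onto the 1440-minute day grid
#'
#' Assigns samples to half-open minute intervals `[t, t + 60 s)` anchored
#' at local midnight (a sample exactly on a boundary belongs to the later
#' minute) and sums wheel rotation counts per minute. A minute is null
#' iff it holds zero accelerometer samples.
#'
#' @param streams a `wf_streams`.
#' @return an object of class `wf_bins`: list with `day_date`, `accel`
#'   (data.table: minute, mag — vector magnitude per sample), `hr`
#'   (data.table: minute, time, bpm), integer vectors `n_accel` and
#'   `rotations` of length 1440, logical `null_minute` and
#'   `nonzero_minute` (has at least one sample of nonzero magnitude).
#' @export
bin_minutes <- function(streams) {
  stopifnot(inherits(streams, "wf_streams"))
  a <- streams$accel
  minute <- as.integer(floor(a$time / 60))
  if (length(minute) && any(minute < 0 | minute >= .MINUTES_PER_DAY)) {
    stop("accelerometer sample outside the day grid")
  }
  mag <- sqrt(a$ax^2 + a$ay^2 + a$az^2)
  accel <- data.table::data.table(minute = minute, mag = mag)
  n_accel <- tabulate(minute + 1L, .MINUTES_PER_DAY)
  nz <- rep(FALSE, .MINUTES_PER_DAY)
  if (length(minute)) {
    nzm <- unique(minute[mag > 0])
    nz[nzm + 1L] <- TRUE
  }
  rot <- rep(0L, .MINUTES_PER_DAY)
  if (nrow(streams$wheel)) {
    wm <- as.integer(floor(streams$wheel$time / 60))
    agg <- tapply(streams$wheel$rotations, wm, sum)
    rot[as.integer(names(agg)) + 1L] <- as.integer(agg)
  }
  hr <- if (nrow(streams$hr)) {
    data.table::data.table(minute = as.integer(floor(streams$hr$time / 60)),
                           time = streams$hr$time, bpm = streams$hr$bpm)
  } else {
    data.table::data.table(minute = integer(), time = numeric(), bpm = numeric())
  }
  structure(
    list(day_date = streams$day_date, accel = accel, hr = hr,
         n_accel = n_accel, rotations = rot,
         null_minute = n_accel == 0L, nonzero_minute = nz),
    class = "wf_bins")
}

#' Daily accelerometer coverage
#'
#' Fraction of minutes holding at least one accelerometer sample of
#' nonzero vector magnitude ("non-null or non-zero" watch data). The
#' default denominator is the full 1440-minute day; `denominator =
#' "awake"` divides by the awake-window length instead (requires
#' `waketime`/`bedtime`).
#'
#' @param bins a `wf_bins`.
#' @param denominator `"day"` (1440 minutes) or `"awake"`.
#' @param waketime,bedtime awake window in minutes since midnight
#'   (only used for `denominator = "awake"`).
#' @return fraction in `[0, 1]`.
#' @export
day_coverage <- function(bins, denominator = c("day", "awake"),
                         waketime = NULL, bedtime = NULL) {
  stopifnot(inherits(bins, "wf_bins"))
  denominator <- match.arg(denominator)
  good <- !bins$null_minute & bins$nonzero_minute
  if (denominator == "day") {
    return(sum(good) / .MINUTES_PER_DAY)
  }
  if (is.null(waketime) || is.null(bedtime) || bedtime <= waketime) {
    stop("awake denominator needs waketime < bedtime")
  }
  idx <- seq(waketime, bedtime - 1L) + 1L
  sum(good[idx]) / (bedtime - waketime)
}
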