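#' Assign each record the nearest exposure grid cell
#'
#' Matches residential coordinates to the closest cell of a gridded
#' exposure product by great-circle (haversine) distance on WGS84
#' longitude/latitude. Exposure is assigned once per record from the
#' residential address, not re-assigned per day. Distance ties (equal to
#' within one micron, absorbing floating-point jitter in the spherical
#' formula) are broken deterministically by the lexicographically
#' smallest `cell_id`.
#'
#' @param lon,lat Numeric vectors of record coordinates (decimal degrees).
#' @param cells Data frame with columns `cell_id`, `lon`, `lat`.
#' @return Character vector of assigned cell ids, one per record.
#' @export
assign_nearest_cell <- function(lon, lat, cells) {
  stopifnot(length(lon) == length(lat))
  if (!all(c("cell_id", "lon", "lat") %in% names(cells))) {
    stop("cells must have columns cell_id, lon, lat")
  }
  if (nrow(cells) == 0) stop("no exposure grid cells supplied")
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("record coordinates must be finite")
  }
  ord <- order(as.character(cells$cell_id))
  cells <- cells[ord, , drop = FALSE]
  pts <- cbind(lon, lat)
  best_d <- rep(Inf, length(lon))
  best_id <- rep(NA_character_, length(lon))
  for (i in seq_len(nrow(cells))) {
    d <- geosphere::distHaversine(pts, c(cells$lon[i], cells$lat[i]))
    hit <- d < best_d - 1e-6  # earlier (smaller) id wins ties within 1 um
    best_d[hit] <- d[hit]
    best_id[hit] <- as.character(cells$cell_id[i])
  }
  best_id
}

#' Lagged moving-average of a daily series at a given date
#'
#' Returns the arithmetic mean of `values` at `date - lag` for each lag in
#' `lags`. The two-day mean of the current and previous day corresponds to
#' `lags = c(0, 1)`; a single-lag value to `lags = 1`. If any constituent
#' daily value is absent the window is undefined and `NA` is returned, so
#' the affected day can be excluded downstream rather than imputed.
#'
#' @param values Numeric daily values.
#' @param dates `Date` vector aligned with `values`.
#' @param at `Date` (vectorized) at which to evaluate the window.
#' @param lags Non-negative integer lags defining the window.
#' @return Numeric vector of window means (`NA` where undefined).
#' @export
window_mean <- function(values, dates, at, lags = c(0, 1)) {
  stopifnot(length(values) == length(dates))
  if (any(lags < 0) || any(lags != floor(lags))) {
    stop("lags must be non-negative integers")
  }
  at <- as.Date(at)
  dates <- as.Date(dates)
  acc <- matrix(NA_real_, nrow = length(at), ncol = length(lags))
  for (j in seq_along(lags)) {
    idx <- match(at - lags[j], dates)
    acc[, j] <- values[idx]
  }
  rowMeans(acc)  # NA if any lag day missing
}

#' Read and validate a gridded daily exposure table
#'
#' Expects a long CSV with header
#' `cell_id,lon,lat,date,pm25,temperature` and ISO-8601 dates. Checks
#' that each cell has exactly one row per date, that the dates form a
#' contiguous daily calendar, and that PM2.5 is non-negative.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with a `Date`-classed `date` column.
#' @export
read_exposure_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(cell_id = "character"))
  df$date <- as.Date(df$date)
  validate_exposure(df)
}

#' Validate a gridded daily exposure table
#'
#' @param df Long exposure data frame (`cell_id`, `lon`, `lat`, `date`,
#'   `pm25`, `temperature`).
#' @return The validated data frame.
#' @export
validate_exposure <- function(df) {
  need <- c("cell_id", "lon", "lat", "date", "pm25", "temperature")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("exposure table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$pm25 < 0, na.rm = TRUE)) stop("pm25 must be non-negative")
  dt <- data.table::as.data.table(df)
  chk <- dt[, list(
    n = .N,
    ndist = data.table::uniqueN(date),
    span = as.integer(max(date) - min(date)) + 1L), by = "cell_id"]
  if (any(chk$n != chk$ndist)) {
    stop("duplicate (cell, date) rows in exposure table")
  }
  if (any(chk$n != chk$span)) {
    stop("exposure dates are not a contiguous daily calendar for every cell")
  }
  df
}

#' Per-cell lag-window exposure series
#'
#' Precomputes, for every grid cell and date, the moving-average PM2.5 and
#' temperature over the configured lag window. Days whose window reaches
#' before the start of the series get `NA`.
#'
#' @param exposure Long exposure table (see [read_exposure_csv()]).
#' @param lags Non-negative integer lags, default `c(0, 1)` (two-day mean).
#' @return `data.table` keyed by (`cell_id`, `date`) with columns `pm25`
#'   (the day's own value), `pm25_window`, `temp_window`.
#' @export
exposure_windows <- function(exposure, lags = c(0, 1)) {
  if (any(lags < 0) || any(lags != floor(lags))) {
    stop("lags must be non-negative integers")
  }
  dt <- data.table::as.data.table(
    exposure[, c("cell_id", "date", "pm25", "temperature")])
  data.table::setkeyv(dt, c("cell_id", "date"))
  lagmat <- function(x) {
    m <- vapply(lags, function(l) data.table::shift(x, l), numeric(length(x)))
    rowMeans(matrix(m, ncol = length(lags)))
  }
  dt[, `:=`(pm25_window = lagmat(pm25), temp_window = lagmat(temperature)),
     by = "cell_id"]
  dt[, list(cell_id, date, pm25, pm25_window, temp_window)]
}

#' Day-of-week as a Sunday-first factor
#'
#' Locale-independent day-of-week labels used for the mortality model's
#' day-of-week indicators (Sunday is the reference level downstream).
#'
#' @param date `Date` vector.
#' @return Factor with levels `Sun`, `Mon`, ..., `Sat`.
#' @export
day_of_week <- function(date) {
  idx <- (as.integer(as.Date(date)) + 4L) %% 7L  # 1970-01-01 was a Thursday
  factor(c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[idx + 1L],
         levels = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
}

#' Case-day covariates for event records
#'
#' Builds the per-record covariate table: each record's lag-window PM2.5
#' and temperature on its event date (from its assigned grid cell) and
#' the day-of-week category.
#'
#' @param records Data frame with `record_id`, `death_date`, `cell_id`.
#' @param exposure Long exposure table.
#' @param lags Lag window, default two-day mean `c(0, 1)`.
#' @return Data frame `record_id`, `date`, `pm25_window`, `temp_window`,
#'   `dow` (window values `NA` where a constituent day is missing).
#' @export
record_covariates <- function(records, exposure, lags = c(0, 1)) {
  win <- exposure_windows(exposure, lags)
  key <- paste(records$cell_id, as.character(records$death_date))
  idx <- match(key, paste(win$cell_id, as.character(win$date)))
  data.frame(
    record_id = records$record_id,
    date = as.Date(records$death_date),
    pm25_window = win$pm25_window[idx],
    temp_window = win$temp_window[idx],
    dow = day_of_week(records$death_date),
    stringsAsFactors = FALSE)
}
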