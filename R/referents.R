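#' Time-stratified referent days for a case day
#'
#' Selects control days for a case-crossover analysis: every 3rd day
#' before and after the case day that falls within the same calendar
#' month and year, i.e. all days of the month sharing the case day's
#' day-of-month residue modulo 3, excluding the case day itself. Because
#' the referent stratum is fixed by (year, month, day-of-month mod 3),
#' this scheme is free of the overlap bias of unidirectional referent
#' selection. Every calendar day yields between 8 and 10 referents.
#'
#' @param case_day A single `Date` (or coercible).
#' @return Ascending `Date` vector of referent days.
#' @examples
#' select_referents(as.Date("2005-07-15"))
#' @export
select_referents <- function(case_day) {
  case_day <- as.Date(case_day)
  stopifnot(length(case_day) == 1, !is.na(case_day))
  stratum <- referent_stratum(case_day)
  stratum[stratum != case_day]
}

#' All days of a case day's referent stratum (case day included)
#'
#' @param case_day A single `Date`.
#' @return Ascending `Date` vector: the case day plus its referents.
#' @export
referent_stratum <- function(case_day) {
  case_day <- as.Date(case_day)
  lt <- as.POSIXlt(case_day)
  dom <- lt$mday
  first <- case_day - (dom - 1L)
  ndays <- days_in_month(lt$year + 1900L, lt$mon + 1L)
  doms <- seq_len(ndays)
  first + (doms[doms %% 3L == dom %% 3L] - 1L)
}

days_in_month <- function(year, month) {
  # difference of first-of-month dates; handles leap years
  nxt <- ifelse(month == 12L,
                paste0(year + 1L, "-01-01"),
                sprintf("%d-%02d-01", year, month + 1L))
  as.integer(as.Date(nxt) - as.Date(sprintf("%d-%02d-01", year, month)))
}

#' Build time-stratified matched sets with aligned covariates
#'
#' For each event record, forms the matched set of its case day plus the
#' time-stratified referent days, attaches lag-window PM2.5 and
#' temperature from the record's assigned grid cell, the day-of-week
#' category, and carries every person/place attribute of the record
#' (race, modifier scores, ...) onto all rows of its set.
#'
#' Days whose exposure window is undefined (a constituent daily value is
#' missing) are dropped: a referent day is dropped from its set; a
#' missing case day drops the whole record. A set also needs at least one
#' surviving referent. The counts of retained and dropped records are
#' returned in the `log` attribute.
#'
#' @param records Data frame with at least `record_id`, `death_date`
#'   (`Date`), `cell_id`; extra columns are carried onto the design.
#' @param exposure Long exposure table (see [read_exposure_csv()]), or a
#'   precomputed [exposure_windows()] table.
#' @param lags Exposure window lags, default `c(0, 1)`.
#' @return Long-format design `data.table` with columns `record_id`,
#'   `date`, `is_case` (0/1), `pm25` (daily), `pm25_window`,
#'   `temp_window`, `dow`, plus carried record columns; attribute `log`
#'   holds retention counts.
#' @export
build_matched_sets <- function(records, exposure, lags = c(0, 1)) {
  records <- as.data.frame(records)
  need <- c("record_id", "death_date", "cell_id")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(records$record_id)) stop("duplicate record_id")

  win <- if (all(c("pm25_window", "temp_window") %in% names(exposure))) {
    data.table::as.data.table(exposure)
  } else {
    exposure_windows(exposure, lags)
  }

  empty <- data.table::data.table(
    record_id = character(0), date = as.Date(character(0)),
    is_case = integer(0), pm25 = numeric(0), pm25_window = numeric(0),
    temp_window = numeric(0),
    dow = factor(character(0), levels = levels(day_of_week(Sys.Date()))))
  if (nrow(records) == 0) {
    attr(empty, "log") <- list(n_records = 0L, n_retained = 0L,
                               n_dropped_case_missing = 0L,
                               n_referent_days_dropped = 0L)
    return(empty)
  }

  records$death_date <- as.Date(records$death_date)

  # stratum days per unique case date, then one row per (record, day)
  udates <- sort(unique(records$death_date))
  strata <- lapply(udates, referent_stratum)
  smap <- data.table::data.table(
    death_date = rep(udates, lengths(strata)),
    date = as.Date(unlist(strata), origin = "1970-01-01"))
  rec <- data.table::as.data.table(records)
  rec$record_id <- as.character(rec$record_id)
  dsn <- merge(rec, smap, by = "death_date", allow.cartesian = TRUE)
  dsn[, is_case := as.integer(date == death_date)]

  # covariates from the record's assigned cell
  dsn <- merge(dsn, win, by = c("cell_id", "date"), all.x = TRUE, sort = FALSE)
  dsn[, dow := day_of_week(date)]

  n_refs_dropped <- dsn[is_case == 0L & is.na(pm25_window), .N]
  bad_case <- dsn[is_case == 1L & is.na(pm25_window), record_id]
  dsn <- dsn[!is.na(pm25_window) & !(record_id %in% bad_case)]
  # require >= 1 referent
  nref <- dsn[, list(nref = sum(is_case == 0L)), by = "record_id"]
  no_ref <- nref[nref == 0L, record_id]
  dsn <- dsn[!(record_id %in% no_ref)]

  data.table::setorderv(dsn, c("record_id", "date"))
  carried <- setdiff(names(records), c("death_date"))
  cols <- c("record_id", "date", "is_case", "pm25", "pm25_window",
            "temp_window", "dow",
            setdiff(carried, c("record_id", "cell_id")), "cell_id")
  out <- dsn[, cols, with = FALSE]
  attr(out, "log") <- list(
    n_records = nrow(records),
    n_retained = length(unique(out$record_id)),
    n_dropped_case_missing = length(unique(bad_case)),
    n_dropped_no_referent = length(no_ref),
    n_referent_days_dropped = n_refs_dropped)
  out
}

#' Write a long-format matched-set design to CSV
#'
#' @param design Result of [build_matched_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
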