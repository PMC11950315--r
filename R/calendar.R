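# Calendar handling. Two calendars are supported: "standard" (proleptic
# Gregorian, leap days present) and "noleap" (365-day model calendar, the
# CMIP6 convention). A daily series stores year + day-of-year; ISO dates are
# derived for IO. In the noleap calendar doy runs 1..365 and maps to the
# month-day layout of a non-leap year.

.CALENDARS <- c("standard", "noleap")

days_in_year <- function(year, calendar = "noleap") {
  calendar <- match.arg(calendar, .CALENDARS)
  if (calendar == "noleap") return(rep(365L, length(year)))
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

# month-day strings for a 365-day year (2001 layout), used for noleap dates
.NOLEAP_MMDD <- format(seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day"),
                       "%m-%d")

#' Build a gap-free daily calendar
#'
#' @param start_year,end_year inclusive calendar years.
#' @param calendar `"noleap"` (365-day) or `"standard"`.
#' @return data.frame with columns `year`, `doy`, `date` (ISO-8601 character).
#' @export
daily_calendar <- function(start_year, end_year, calendar = "noleap") {
  calendar <- match.arg(calendar, .CALENDARS)
  stopifnot(end_year >= start_year)
  years <- start_year:end_year
  if (calendar == "noleap") {
    year <- rep(years, each = 365L)
    doy <- rep.int(1:365, length(years))
    date <- paste0(year, "-", .NOLEAP_MMDD[doy])
  } else {
    d <- seq(as.Date(paste0(start_year, "-01-01")),
             as.Date(paste0(end_year, "-12-31")), by = "day")
    year <- as.integer(format(d, "%Y"))
    doy <- as.integer(format(d, "%j"))
    date <- format(d, "%Y-%m-%d")
  }
  data.frame(year = as.integer(year), doy = as.integer(doy), date = date,
             stringsAsFactors = FALSE)
}

# ISO date string -> (year, doy) under a declared calendar; rejects Feb 29
# in the noleap calendar.
parse_dates <- function(date, calendar = "noleap") {
  calendar <- match.arg(calendar, .CALENDARS)
  d <- as.Date(date)
  if (anyNA(d)) stop("unparseable date(s): ", date[which(is.na(d))[1]])
  year <- as.integer(format(d, "%Y"))
  if (calendar == "noleap") {
    mmdd <- format(d, "%m-%d")
    if (any(mmdd == "02-29")) {
      stop("date ", date[which(mmdd == "02-29")[1]],
           " (29 Feb) invalid in the noleap calendar")
    }
    doy <- match(mmdd, .NOLEAP_MMDD)
  } else {
    doy <- as.integer(format(d, "%j"))
  }
  data.frame(year = year, doy = as.integer(doy))
}

# Assert (year, doy) advance by exactly one day; names the first offence.
validate_gap_free <- function(year, doy, calendar = "noleap", what = "series") {
  if (length(year) == 0L) return(invisible(TRUE))
  diy <- days_in_year(year, calendar)
  nxt_year <- ifelse(doy < diy, year, year + 1L)
  nxt_doy <- ifelse(doy < diy, doy + 1L, 1L)
  n <- length(year)
  if (n > 1L) {
    ok <- year[-1L] == nxt_year[-n] & doy[-1L] == nxt_doy[-n]
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(what, " has a date gap or duplicate after year ", year[i],
           " day ", doy[i], " (next record: year ", year[i + 1L],
           " day ", doy[i + 1L], ")")
    }
  }
  invisible(TRUE)
}
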