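#' Define the season window used to index observation days
#'
#' Observations are analysed within a fixed seasonal window each year, indexed
#' by `day` = 1 on the window's first calendar day. The default window starts
#' April 1 and spans 90 days (April--June), the main breeding season for
#' wetland birds at the latitudes this workflow was designed around.
#'
#' @param start Window start as `"MM-DD"` (applied within every year).
#' @param days Window length `D` in days (default 90).
#' @return A list of class `season_window` with elements `start` and `days`.
#' @examples
#' season_window()
#' season_window("05-01", 60)
#' @export
season_window <- function(start = "04-01", days = 90L) {
  if (!grepl("^\\d{2}-\\d{2}$", start)) abort('`start` must be "MM-DD"')
  days <- assert_scalar_int(days, "days", min = 2L)
  structure(list(start = start, days = days), class = "season_window")
}

window_start_date <- function(window, year) {
  as.Date(sprintf("%d-%s", year, window$start))
}

# accepted header aliases (Darwin Core)
.col_aliases <- c(
  species = "scientificName", site = "locality",
  date = "eventDate", observer = "recordedBy"
)

#' Read opportunistic observation records
#'
#' Reads a delimited text file (CSV or TSV, autodetected from the extension)
#' of presence-only species observations with columns `species`, `site`,
#' `date`, `observer` (Darwin Core aliases `scientificName`, `locality`,
#' `eventDate`, `recordedBy` are accepted). Dates must be ISO 8601. Records
#' are assigned a 1-based `day` index within the season window; records
#' outside the window are dropped with a logged count, and exact duplicate
#' rows collapse to one record.
#'
#' @param path Path to a CSV/TSV file.
#' @param window A [season_window()].
#' @param quiet Suppress log messages.
#' @return A tibble with columns `species`, `site`, `year`, `day`, `observer`.
#' @export
read_observations <- function(path, window = season_window(), quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  prb <- readr::problems(raw)
  if (nrow(prb) > 0)
    abort(sprintf("unparseable input at line %d of %s: %s",
                  prb$row[1] + 1L, path, prb$expected[1]))
  for (std in names(.col_aliases)) {
    if (!std %in% names(raw) && .col_aliases[[std]] %in% names(raw))
      names(raw)[names(raw) == .col_aliases[[std]]] <- std
  }
  missing <- setdiff(c("species", "site", "date", "observer"), names(raw))
  if (length(missing) > 0)
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    abort(sprintf("unparseable date '%s' at line %d of %s", raw$date[bad], bad + 1L, path))
  }
  yr <- as.integer(format(dates, "%Y"))
  day <- as.integer(dates - window_start_date(window, yr)) + 1L
  keep <- day >= 1L & day <= window$days
  if (sum(!keep) > 0)
    su_inform("read_observations: dropped %d record(s) outside the %d-day window",
              sum(!keep), window$days, quiet = quiet)
  out <- tibble(
    species = raw$species[keep], site = raw$site[keep],
    year = yr[keep], day = day[keep], observer = raw$observer[keep]
  )
  out <- distinct(out)
  if (nrow(out) == 0) abort("no observations fall inside the season window")
  validate_observations(out, window$days)
  out
}

#' Write observation records
#'
#' Inverse of [read_observations()]: converts the `(year, day)` index back to
#' calendar dates using the season window and writes a CSV with columns
#' `species`, `site`, `date`, `observer`.
#'
#' @param observations Tibble as returned by [read_observations()] or
#'   [simulate_detections()].
#' @param path Output CSV path.
#' @param window A [season_window()].
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path, window = season_window()) {
  validate_observations(observations, window$days)
  out <- tibble(
    species = observations$species, site = observations$site,
    date = window_start_date(window, observations$year) + observations$day - 1L,
    observer = observations$observer
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_observations <- function(observations, n_days = NULL) {
  need <- c("species", "site", "year", "day", "observer")
  missing <- setdiff(need, names(observations))
  if (length(missing) > 0)
    abort(sprintf("observations lack column(s): %s", paste(missing, collapse = ", ")))
  chr <- c("species", "site", "observer")
  for (cc in chr) {
    v <- observations[[cc]]
    if (anyNA(v) || any(!nzchar(as.character(v))))
      abort(sprintf("column `%s` contains empty or missing identifiers", cc))
  }
  if (anyNA(observations$day) || any(observations$day < 1))
    abort("`day` must be a positive day index")
  if (!is.null(n_days) && any(observations$day > n_days))
    abort(sprintf("`day` exceeds the %d-day window", n_days))
  invisible(observations)
}
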