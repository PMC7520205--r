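#' Assemble visits from observation records
#'
#' A visit is the set of all observations made by one observer (or reporting
#' group) at one site on one day of one year. Its species list length (SLL,
#' the number of distinct species reported) is the per-visit effort proxy used
#' by the detection submodel.
#'
#' @param observations Tibble with columns `species`, `site`, `year`, `day`,
#'   `observer` (see [read_observations()]).
#' @return A tibble with one row per visit: `visit_id`, `site`, `year`, `day`,
#'   `observer`, `sll`, and a `species` list-column of the species reported.
#'   Visit ids number visits in order of first appearance in the input.
#' @examples
#' obs <- tibble::tibble(
#'   species = c("A", "B", "C"), site = "w1", year = 2014L,
#'   day = 5L, observer = "o1"
#' )
#' assemble_visits(obs)
#' @export
assemble_visits <- function(observations) {
  validate_observations(observations)
  obs <- distinct(observations, .data$species, .data$site, .data$year,
                  .data$day, .data$observer)
  visits <- obs |>
    group_by(.data$site, .data$year, .data$day, .data$observer) |>
    summarise(species = list(sort(unique(.data$species))), .groups = "drop")
  # id visits by first appearance of their key in the input
  key_in <- paste(obs$site, obs$year, obs$day, obs$observer, sep = "\r")
  first_pos <- tapply(seq_along(key_in), key_in, min)
  key_v <- paste(visits$site, visits$year, visits$day, visits$observer, sep = "\r")
  visits <- visits[order(first_pos[key_v]), ]
  visits |>
    mutate(visit_id = row_number(),
           sll = vapply(.data$species, length, integer(1))) |>
    select("visit_id", "site", "year", "day", "observer", "sll", "species")
}

#' Cap the number of visits per site and day
#'
#' Retains at most `max_per_site_day` visits for every (site, year, day)
#' combination, keeping the visits with the longest species lists. Ties in
#' SLL are broken by input order (stable), so results are reproducible.
#'
#' @param visits Tibble from [assemble_visits()].
#' @param max_per_site_day Maximum visits retained per site-day (default 40).
#' @return The capped visit tibble, in the original row order.
#' @export
cap_visits <- function(visits, max_per_site_day = 40L) {
  max_per_site_day <- assert_scalar_int(max_per_site_day, "max_per_site_day")
  visits |>
    group_by(.data$site, .data$year, .data$day) |>
    mutate(.rank = row_number(dplyr::desc(.data$sll))) |>
    ungroup() |>
    filter(.data$.rank <= max_per_site_day) |>
    select(-".rank")
}

#' Compute effort covariates for the detection submodel
#'
#' Two covariates describe observer effort beyond SLL itself: the annual
#' proportion of long lists (PLL: visits whose SLL is at least
#' `long_list_threshold`), a proxy for each year's general reporting
#' behaviour, and the half of the season a visit falls in (days `1..ceil(D/2)`
#' are "first"). PLL is computed on the visits actually retained for
#' modelling, i.e. after [cap_visits()].
#'
#' @param visits Tibble of (capped) visits.
#' @param long_list_threshold SLL at or above which a list counts as long
#'   (default 10).
#' @param n_days Season length `D`.
#' @param years Optional integer vector of years that must all have visits;
#'   a listed year with no visits is an error (its PLL is undefined).
#' @return An object of class `effort_covariates`: a list with tibbles
#'   `pll` (`year`, `pll`) and `season_half` (`day`, `half`).
#' @examples
#' v <- tibble::tibble(
#'   visit_id = 1:4, site = "w1", year = 2014L, day = c(3L, 4L, 5L, 6L),
#'   observer = "o1", sll = c(1L, 12L, 10L, 3L),
#'   species = replicate(4, "A", simplify = FALSE)
#' )
#' compute_effort_covariates(v, n_days = 90)$pll
#' @export
compute_effort_covariates <- function(visits, long_list_threshold = 10L,
                                      n_days, years = NULL) {
  long_list_threshold <- assert_scalar_int(long_list_threshold, "long_list_threshold")
  n_days <- assert_scalar_int(n_days, "n_days", min = 2L)
  if (nrow(visits) == 0) abort("no visits: PLL is undefined")
  pll <- visits |>
    group_by(year = .data$year) |>
    summarise(pll = mean(.data$sll >= long_list_threshold), .groups = "drop") |>
    arrange(.data$year)
  if (!is.null(years)) {
    missing <- setdiff(as.integer(years), pll$year)
    if (length(missing) > 0)
      abort(sprintf("year(s) with zero visits, PLL undefined: %s",
                    paste(missing, collapse = ", ")))
  }
  half_cut <- ceiling(n_days / 2)
  season_half <- tibble(
    day = seq_len(n_days),
    half = ifelse(seq_len(n_days) <= half_cut, "first", "second")
  )
  structure(
    list(pll = pll, season_half = season_half,
         long_list_threshold = long_list_threshold, n_days = n_days),
    class = "effort_covariates"
  )
}

#' @export
print.effort_covariates <- function(x, ...) {
  cat(sprintf("<effort_covariates> D = %d, long-list threshold = %d\n",
              x$n_days, x$long_list_threshold))
  print(x$pll)
  invisible(x)
}

#' Build per-species detection histories with pseudo-nondetections
#'
#' Presence-only data contain no explicit absences; a pseudo-nondetection is
#' inferred when an observer reported at least one species on a visit but not
#' the focal one. For every retained visit and every species in the pool this
#' returns the binary outcome `y`: 1 if the species is on the visit's list,
#' 0 otherwise. Site-days with no visits contribute no rows (no information).
#'
#' @param visits Tibble of (capped) visits.
#' @param species_pool Character vector of species to build histories for;
#'   defaults to all species occurring in `visits`. Species present in the
#'   visits but absent from the pool are an error.
#' @return A tibble with columns `species`, `site`, `year`, `day`, `visit_id`,
#'   `sll`, `y`, with `length(species_pool) * nrow(visits)` rows.
#' @export
build_detection_histories <- function(visits, species_pool = NULL) {
  seen <- sort(unique(unlist(visits$species)))
  if (is.null(species_pool)) species_pool <- seen
  offenders <- setdiff(seen, species_pool)
  if (length(offenders) > 0)
    abort(sprintf("species in visits but absent from pool: %s",
                  paste(offenders, collapse = ", ")))
  meta <- select(visits, "visit_id", "site", "year", "day", "sll")
  detected <- visits |>
    select("visit_id", "species") |>
    tidyr::unnest("species") |>
    mutate(y = 1L)
  tidyr::expand_grid(species = species_pool, meta) |>
    left_join(detected, by = c("visit_id", "species")) |>
    mutate(y = dplyr::coalesce(.data$y, 0L)) |>
    select("species", "site", "year", "day", "visit_id", "sll", "y")
}
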