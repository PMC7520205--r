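#' Expected richness from an inclusion-probability table
#'
#' Local species richness under a criterion is the expected number of
#' species present: the sum of posterior inclusion probabilities across all
#' species of the pool at a site.
#'
#' @param inclusion_table Tibble from [inclusion_probability()].
#' @param species_pool Character vector of species that must all be present
#'   for every site/criterion (default: all species in the table).
#' @return A tibble `site`, `k`, `mode`, `S`.
#' @export
estimated_richness <- function(inclusion_table, species_pool = NULL) {
  species_pool <- species_pool %||% unique(inclusion_table$species)
  check <- inclusion_table |>
    count(.data$site, .data$k, .data$mode) |>
    filter(.data$n != length(species_pool))
  missing <- setdiff(species_pool, unique(inclusion_table$species))
  if (nrow(check) > 0 || length(missing) > 0)
    abort("inclusion table does not cover the full species pool for every site and criterion")
  inclusion_table |>
    group_by(.data$site, .data$k, .data$mode) |>
    summarise(S = sum(.data$prob), .groups = "drop")
}

#' Richness estimates with credible intervals per site and criterion
#'
#' Computes, for every site and criterion, the expected species richness
#' (sum of posterior inclusion probabilities) together with a central
#' credible interval derived from the per-draw richness distribution (number
#' of species whose trajectory satisfies the criterion in that draw).
#'
#' @param fit A `siteuse_fit`.
#' @param criteria Tibble from [inclusion_criteria()].
#' @param level Credible level (default 0.95).
#' @return A tibble `site`, `k`, `mode`, `S`, `lower`, `upper`.
#' @export
richness_table <- function(fit, criteria = inclusion_criteria(), level = 0.95) {
  stopifnot(inherits(fit, "siteuse_fit"), level > 0, level < 1)
  sp_names <- names(fit$species)
  sites <- fit$sites
  a <- (1 - level) / 2
  # per species / site: draw-level criterion indicators
  out <- vector("list", nrow(criteria))
  stats_by_sp <- lapply(sp_names, function(sp) {
    traj <- fit$species[[sp]]$traj
    lapply(seq_along(sites), function(si) run_stats_cpp(traj[, si, , drop = TRUE]))
  })
  nd <- dim(fit$species[[1]]$traj)[1]
  for (i in seq_len(nrow(criteria))) {
    k <- criteria$k[i]; mode <- criteria$mode[i]
    per_site <- lapply(seq_along(sites), function(si) {
      rich <- rep(0L, nd)
      for (s in seq_along(sp_names))
        rich <- rich + criterion_met(stats_by_sp[[s]][[si]], k, mode)
      tibble(site = sites[si], k = k, mode = mode,
             S = mean(rich),
             lower = quantile(rich, a, names = FALSE),
             upper = quantile(rich, 1 - a, names = FALSE))
    })
    out[[i]] <- bind_rows(per_site)
  }
  bind_rows(out) |> arrange(.data$mode, .data$k, .data$site)
}

#' Observed richness from raw records under a day-count criterion
#'
#' The raw-data counterpart of [richness_table()]: the number of species
#' observed at a site on at least `k` distinct days of the target year.
#' Observed richness is only defined nonconsecutively (raw detection days
#' say nothing about presence on the days between them), so requesting the
#' consecutive mode is an error.
#'
#' @param observations Records tibble (`species`, `site`, `year`, `day`, ...).
#' @param k Day threshold.
#' @param target_year Year to evaluate.
#' @param mode Must be `"nonconsecutive"`.
#' @param sites Optional site universe; sites with no qualifying species get
#'   an explicit 0.
#' @return A tibble `site`, `k`, `observed_S` (integer).
#' @export
observed_richness <- function(observations, k, target_year,
                              mode = "nonconsecutive", sites = NULL) {
  k <- assert_scalar_int(k, "k")
  if (!identical(mode, "nonconsecutive"))
    abort("observed richness is only defined for the nonconsecutive mode")
  validate_observations(observations)
  sites <- sites %||% sort(unique(observations$site))
  counts <- observations |>
    filter(.data$year == target_year) |>
    distinct(.data$species, .data$site, .data$day) |>
    count(.data$species, .data$site, name = "n_days") |>
    filter(.data$n_days >= k) |>
    count(.data$site, name = "observed_S")
  tibble(site = sites, k = k) |>
    left_join(counts, by = "site") |>
    mutate(observed_S = as.integer(dplyr::coalesce(.data$observed_S, 0L)))
}

#' Detection-corrected expected daily richness
#'
#' Sums, over species, the posterior mean of the daily occupancy indicator,
#' giving the expected number of species present at each site on each day of
#' the target year.
#'
#' @param fit A `siteuse_fit`.
#' @return A tibble `site`, `day`, `S_day`.
#' @export
daily_richness <- function(fit) {
  stopifnot(inherits(fit, "siteuse_fit"))
  acc <- matrix(0, length(fit$sites), fit$n_days,
                dimnames = list(fit$sites, NULL))
  for (sp in names(fit$species))
    acc <- acc + apply(fit$species[[sp]]$traj, c(2, 3), mean)
  as_tibble(as.data.frame.table(acc, responseName = "S_day")) |>
    mutate(site = as.character(.data$Var1),
           day = as.integer(.data$Var2)) |>
    select("site", "day", "S_day") |>
    arrange(.data$site, .data$day)
}

#' Observed daily richness from raw records
#'
#' Number of distinct species reported per site and day of the target year;
#' site-days without records count 0 species.
#'
#' @inheritParams observed_richness
#' @param n_days Season length (fills unvisited days with 0).
#' @return A tibble `site`, `day`, `S_day_obs`.
#' @export
observed_daily_richness <- function(observations, target_year, n_days,
                                    sites = NULL) {
  validate_observations(observations, n_days)
  sites <- sites %||% sort(unique(observations$site))
  counts <- observations |>
    filter(.data$year == target_year) |>
    distinct(.data$species, .data$site, .data$day) |>
    count(.data$site, .data$day, name = "S_day_obs")
  tidyr::expand_grid(site = sites, day = seq_len(n_days)) |>
    left_join(counts, by = c("site", "day")) |>
    mutate(S_day_obs = as.integer(dplyr::coalesce(.data$S_day_obs, 0L)))
}
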