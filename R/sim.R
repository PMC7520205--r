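#' Draw ground-truth species parameters for the simulator
#'
#' Species-level parameters are drawn uniformly within the configured ranges;
#' site and year random effects (on detection steepness, persistence and
#' colonization) are drawn from centred normals with the configured standard
#' deviations. One true annual PLL covariate value per year is drawn as well.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with one row per species: scalar parameter columns and
#'   list-columns `alpha_site` (site-level log steepness, length `n_sites`),
#'   `phi_site`, `gamma_site`, `phi_year`, `gamma_year`. The true PLL values
#'   are attached as attribute `pll_true` (named by year).
#' @export
draw_species_params <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(op_seed(seed, "draw_species_params"), {
    r <- config$ranges
    sg <- config$sigma
    n <- config$n_species
    S <- config$n_sites
    Ty <- config$n_years
    draw <- function(nm) runif(n, r[[nm]][1], r[[nm]][2])
    params <- tibble(
      species = sim_species_names(config),
      pmax = draw("pmax"), psi1 = draw("psi1"),
      alpha = draw("alpha"), eta2 = draw("eta2"), delta = draw("delta"),
      b0 = draw("b0"), b1 = draw("b1"), b2 = draw("b2"),
      c0 = draw("c0"), c1 = draw("c1"), c2 = draw("c2"),
      alpha_site = lapply(seq_len(n), function(i) rnorm(S, 0, sg$alpha_site)),
      phi_site = lapply(seq_len(n), function(i) rnorm(S, 0, sg$phi_site)),
      gamma_site = lapply(seq_len(n), function(i) rnorm(S, 0, sg$gamma_site)),
      phi_year = lapply(seq_len(n), function(i) rnorm(Ty, 0, sg$phi_year)),
      gamma_year = lapply(seq_len(n), function(i) rnorm(Ty, 0, sg$gamma_year))
    )
    pll_true <- runif(Ty, config$pll_range[1], config$pll_range[2])
    names(pll_true) <- as.character(sim_years(config))
    attr(params, "pll_true") <- pll_true
    params
  })
}

#' Simulate true daily occupancy trajectories
#'
#' Day-1 occupancy is Bernoulli(`psi1`); thereafter occupancy follows the
#' daily colonization--extinction chain with day-varying persistence and
#' colonization from [transition_probabilities()], including the species'
#' site and year random effects.
#'
#' @param params Tibble from [draw_species_params()].
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return A tibble `species`, `site`, `year`, `day`, `u` (0/1) with
#'   `n_species * n_sites * n_years * n_days` rows.
#' @export
simulate_occupancy <- function(params, config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  D <- config$n_days
  sites <- sim_site_names(config)
  years <- sim_years(config)
  S <- length(sites)
  z <- standardize_day(seq_len(D - 1), D)
  local_seed(op_seed(seed, "simulate_occupancy"), {
    out <- vector("list", nrow(params) * length(years))
    k <- 0
    for (s in seq_len(nrow(params))) {
      pr <- params[s, ]
      for (ti in seq_along(years)) {
        phi <- plogis(outer(pr$phi_site[[1]],
                            pr$b0 + pr$b1 * z + pr$b2 * z^2 + pr$phi_year[[1]][ti], "+"))
        gam <- plogis(outer(pr$gamma_site[[1]],
                            pr$c0 + pr$c1 * z + pr$c2 * z^2 + pr$gamma_year[[1]][ti], "+"))
        u <- matrix(0L, S, D)
        u[, 1] <- rbinom(S, 1L, pr$psi1)
        for (d in seq_len(D - 1)) {
          pstay <- ifelse(u[, d] == 1L, phi[, d], gam[, d])
          u[, d + 1] <- rbinom(S, 1L, pstay)
        }
        k <- k + 1
        out[[k]] <- tibble(
          species = pr$species, site = rep(sites, D),
          year = years[ti], day = rep(seq_len(D), each = S),
          u = as.integer(u)
        )
      }
    }
    bind_rows(out)
  })
}

#' Simulate the visit schedule
#'
#' Visit counts per site-day are negative binomial with a log-mean that
#' changes linearly over the season (declining effort for negative trend),
#' truncated at `visit_max`. Each visit gets a target list length drawn from
#' the skewed SLL distribution; the target parameterizes observer
#' thoroughness, while the realized SLL emerges from detection.
#'
#' @inheritParams draw_species_params
#' @return A tibble `site`, `year`, `day`, `observer`, `sll_target`.
#' @export
simulate_visit_schedule <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  D <- config$n_days
  grid <- tidyr::expand_grid(
    site = sim_site_names(config), year = sim_years(config), day = seq_len(D)
  )
  local_seed(op_seed(seed, "simulate_visit_schedule"), {
    frac <- (grid$day - 1) / (D - 1)
    mu <- config$visit_mean * exp(config$visit_trend * (frac - 0.5))
    nvis <- pmin(rnbinom(nrow(grid), mu = mu, size = config$visit_dispersion),
                 config$visit_max)
    sched <- grid[rep(seq_len(nrow(grid)), nvis), ]
    sched$observer <- unlist(lapply(nvis[nvis > 0], function(n) paste0("obs", seq_len(n))),
                             use.names = FALSE)
    n <- nrow(sched)
    single <- runif(n) < config$sll_p1
    tail_len <- 2L + rnbinom(n, mu = max(config$sll_tail_mu - 2, 0.1),
                             size = config$sll_tail_size)
    sched$sll_target <- as.integer(pmin(ifelse(single, 1L, tail_len), config$sll_max))
    as_tibble(sched)
  })
}

#' Simulate presence-only detections
#'
#' For every visit and species, a detection occurs with probability
#' `u * p(sll_target)` where `p` is the saturating detection function with
#' the species' site steepness, season-half offset and PLL slope, and the
#' visit's target list length stands in for observer thoroughness. Detected
#' species form the visit's realized species list; visits detecting nothing
#' leave no record (presence-only reporting).
#'
#' Background species (see [sim_config()]) are reported alongside the focal
#' ones: each appears on a visit's list with probability
#' `min(1, (sll_target - 1) / n_background)`, so thorough visits carry long
#' lists even when few focal species are present. This reproduces the
#' situation the list-length effort proxy relies on: the focal community is
#' a small subset of everything observers report, so a visit's list length
#' reflects effort rather than the focal species' own detections.
#'
#' @param occupancy Tibble from [simulate_occupancy()].
#' @param schedule Tibble from [simulate_visit_schedule()].
#' @param params Tibble from [draw_species_params()] (carries `pll_true`).
#' @param config The matching [sim_config()].
#' @param seed Integer seed.
#' @return A tibble of observation records `species`, `site`, `year`, `day`,
#'   `observer`, validated for [assemble_visits()].
#' @export
simulate_detections <- function(occupancy, schedule, params,
                                config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  D <- config$n_days
  pll_true <- attr(params, "pll_true")
  if (is.null(pll_true)) abort("`params` lacks the `pll_true` attribute")
  half_cut <- ceiling(D / 2)
  sched <- schedule |>
    mutate(eta_on = as.numeric(.data$day > half_cut),
           pll = unname(pll_true[as.character(.data$year)]))
  site_index <- match(sched$site, sim_site_names(config))
  local_seed(op_seed(seed, "simulate_detections"), {
    per_species <- lapply(seq_len(nrow(params)), function(s) {
      pr <- params[s, ]
      us <- occupancy |> filter(.data$species == pr$species)
      key <- paste(us$site, us$year, us$day)
      u <- us$u[match(paste(sched$site, sched$year, sched$day), key)]
      p <- detection_probability(
        sched$sll_target, pmax = pr$pmax,
        alpha = pr$alpha + pr$alpha_site[[1]][site_index],
        eta = pr$eta2 * sched$eta_on, delta = pr$delta, pll = sched$pll
      )
      hit <- rbinom(nrow(sched), 1L, u * p) == 1L
      tibble(species = pr$species, site = sched$site[hit],
             year = sched$year[hit], day = sched$day[hit],
             observer = sched$observer[hit])
    })
    bg <- sim_background_names(config)
    per_background <- lapply(bg, function(bsp) {
      pb <- pmin(1, (sched$sll_target - 1) / config$n_background)
      hit <- rbinom(nrow(sched), 1L, pb) == 1L
      tibble(species = bsp, site = sched$site[hit], year = sched$year[hit],
             day = sched$day[hit], observer = sched$observer[hit])
    })
    bind_rows(c(per_species, per_background)) |>
      arrange(.data$site, .data$year, .data$day, .data$observer, .data$species)
  })
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Convenience wrapper chaining [draw_species_params()],
#' [simulate_occupancy()], [simulate_visit_schedule()] and
#' [simulate_detections()]. Each stage uses its own RNG stream derived from
#' `seed`, so the whole dataset is reproducible.
#'
#' @inheritParams draw_species_params
#' @return A list of class `siteuse_simulation`: `observations` (records),
#'   `truth` (true occupancy), `params`, `schedule`, `pll_true`, `config`,
#'   `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  params <- draw_species_params(config, seed)
  truth <- simulate_occupancy(params, config, seed)
  schedule <- simulate_visit_schedule(config, seed)
  observations <- simulate_detections(truth, schedule, params, config, seed)
  structure(
    list(observations = observations, truth = truth, params = params,
         schedule = schedule, pll_true = attr(params, "pll_true"),
         focal_species = params$species,
         background_species = sim_background_names(config),
         config = config, seed = seed),
    class = "siteuse_simulation"
  )
}

#' @export
print.siteuse_simulation <- function(x, ...) {
  cat(sprintf(paste0("<siteuse_simulation> %d species x %d sites x %d year(s), ",
                     "D = %d\n  %d observation records from %d scheduled visits ",
                     "(seed %d)\n"),
              x$config$n_species, x$config$n_sites, x$config$n_years,
              x$config$n_days, nrow(x$observations), nrow(x$schedule), x$seed))
  invisible(x)
}
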