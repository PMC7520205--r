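#' MCMC settings for the site-use model
#'
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param warmup Adaptation iterations discarded per chain.
#' @param samples Post-warmup iterations per chain.
#' @param thin Keep every `thin`-th post-warmup iteration.
#' @param step_init Initial random-walk proposal standard deviation; each
#'   coordinate adapts towards a 0.44 acceptance rate during warmup.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, warmup = 1000L, samples = 1000L,
                        thin = 1L, step_init = 0.3) {
  chains <- assert_scalar_int(chains, "chains")
  warmup <- assert_scalar_int(warmup, "warmup", min = 0L)
  samples <- assert_scalar_int(samples, "samples")
  thin <- assert_scalar_int(thin, "thin")
  if (samples %% thin != 0) abort("`samples` must be a multiple of `thin`")
  structure(list(chains = chains, warmup = warmup, samples = samples,
                 thin = thin, step_init = step_init), class = "mcmc_config")
}

#' Prior hyperparameters for the site-use model
#'
#' Weakly informative defaults: Normal(0, `coef_sd`) on all logit/log-scale
#' intercepts and slopes, half-Normal(`sd_scale`) on random-effect standard
#' deviations, Beta priors on the maximum detection probability and on
#' initial occupancy.
#'
#' @param coef_sd SD of the normal prior on coefficients (default 1.5).
#' @param sd_scale Scale of the half-normal prior on random-effect SDs.
#' @param pmax_shape Length-2 Beta shape for `pmax` (default `c(2, 2)`).
#' @param psi1_shape Length-2 Beta shape for `psi1` (default `c(1, 1)`).
#' @return A list of class `siteuse_priors`.
#' @export
siteuse_priors <- function(coef_sd = 1.5, sd_scale = 1,
                           pmax_shape = c(2, 2), psi1_shape = c(1, 1)) {
  stopifnot(coef_sd > 0, sd_scale > 0, length(pmax_shape) == 2,
            length(psi1_shape) == 2, all(pmax_shape > 0), all(psi1_shape > 0))
  structure(list(coef_sd = coef_sd, sd_scale = sd_scale,
                 pmax_shape = pmax_shape, psi1_shape = psi1_shape),
            class = "siteuse_priors")
}

siteuse_param_names <- function(sites, years) {
  c("logit_pmax", "logit_psi1", "mu_alpha", "eta2", "delta",
    "b0", "b1", "b2", "c0", "c1", "c2",
    "log_sigma_alpha", "log_sigma_phi_site", "log_sigma_phi_year",
    "log_sigma_gamma_site", "log_sigma_gamma_year",
    paste0("alpha_raw[", sites, "]"),
    paste0("phi_site_raw[", sites, "]"),
    paste0("gamma_site_raw[", sites, "]"),
    paste0("phi_year_raw[", years, "]"),
    paste0("gamma_year_raw[", years, "]"))
}

# natural-scale view of the unconstrained draws
natural_name <- function(nm) {
  out <- sub("^logit_", "", nm)
  sub("^log_", "", out)
}
natural_transform <- function(draws, names_raw) {
  out <- draws
  logit_cols <- grepl("^logit_", names_raw)
  log_cols <- grepl("^log_", names_raw)
  out[, logit_cols] <- plogis(out[, logit_cols, drop = FALSE])
  out[, log_cols] <- exp(out[, log_cols, drop = FALSE])
  colnames(out) <- natural_name(names_raw)
  out
}

# build the per-site-year visit blocks for one species
build_species_blocks <- function(hist_sp, sites, years, pll_lookup, half_cut) {
  blocks <- vector("list", length(sites) * length(years))
  k <- 0
  idx <- split(seq_len(nrow(hist_sp)),
               list(factor(hist_sp$site, sites), factor(hist_sp$year, years)),
               drop = FALSE)
  for (ti in seq_along(years)) {
    for (si in seq_along(sites)) {
      rows <- idx[[paste(sites[si], years[ti], sep = ".")]]
      k <- k + 1
      blocks[[k]] <- list(
        site = si, year = ti,
        day = as.integer(hist_sp$day[rows]),
        sll = as.integer(hist_sp$sll[rows]),
        y = as.integer(hist_sp$y[rows]),
        half = as.integer(hist_sp$day[rows] > half_cut),
        pll = unname(pll_lookup[as.character(years[ti])])
      )
    }
  }
  blocks
}

#' Fit the daily site-use occupancy model
#'
#' Fits the hierarchical daily colonization--extinction occupancy model with
#' list-length-dependent detection, separately for each species, in the
#' Bayesian framework. Parameters are updated by componentwise adaptive
#' random-walk Metropolis targeting the marginal posterior (latent occupancy
#' summed out by the forward algorithm); latent daily occupancy trajectories
#' for the target year are drawn by forward-filtering backward-sampling at
#' every kept iteration, so downstream inclusion criteria can be evaluated on
#' whole trajectories rather than daily marginals.
#'
#' @param histories Detection-history tibble from
#'   [build_detection_histories()].
#' @param effort An `effort_covariates` object from
#'   [compute_effort_covariates()].
#' @param mcmc An [mcmc_config()].
#' @param priors A [siteuse_priors()].
#' @param target_year Year whose latent trajectories are stored (default:
#'   the latest year in `histories`).
#' @param species Optional subset of species to fit.
#' @param sites,years Site and year universes (default: those occurring in
#'   `histories`). Must be supplied, together with `species` and `n_days`,
#'   for a prior-only run on empty histories.
#' @param n_days Season length; defaults to `effort$n_days`. `effort` may be
#'   `NULL` (PLL treated as 0) for prior-only runs.
#' @param seed Integer master seed; every chain of every species derives its
#'   own stream, so refits are bit-identical.
#' @param quiet Suppress progress messages.
#' @return An object of class `siteuse_fit`. Use [tidy()] for parameter
#'   summaries, [glance()] for per-species diagnostics,
#'   [convergence_diagnostics()], [richness_table()], [daily_richness()] and
#'   [inclusion_probability()] for derived quantities.
#' @export
fit_siteuse <- function(histories, effort, mcmc = mcmc_config(),
                        priors = siteuse_priors(), target_year = NULL,
                        species = NULL, sites = NULL, years = NULL,
                        n_days = NULL, seed = 1L, quiet = FALSE) {
  stopifnot(inherits(mcmc, "mcmc_config"), inherits(priors, "siteuse_priors"))
  need <- c("species", "site", "year", "day", "visit_id", "sll", "y")
  if (!all(need %in% names(histories)))
    abort("`histories` must come from build_detection_histories()")
  if (!is.null(effort)) stopifnot(inherits(effort, "effort_covariates"))
  D <- n_days %||% effort$n_days
  if (is.null(D)) abort("supply `effort` or `n_days`")
  D <- assert_scalar_int(D, "n_days", min = 2L)
  if (nrow(histories) > 0 && any(histories$day > D))
    abort("history days exceed the season length")
  sites <- sort(unique(c(sites, histories$site)))
  years <- sort(unique(c(years, histories$year)))
  pool <- sort(unique(c(species, histories$species)))
  if (length(sites) == 0 || length(years) == 0 || length(pool) == 0)
    abort(paste("empty detection histories: supply `species`, `sites` and",
                "`years` for a prior-only run"))
  target_year <- target_year %||% max(years)
  if (!target_year %in% years) abort("`target_year` not among the years")
  if (!is.null(species)) pool <- sort(unique(species))
  pll_lookup <- if (is.null(effort)) {
    setNames(rep(0, length(years)), as.character(years))
  } else {
    setNames(effort$pll$pll, as.character(effort$pll$year))
  }
  missing_pll <- setdiff(as.character(sort(unique(histories$year))),
                         names(pll_lookup))
  if (length(missing_pll) > 0)
    abort("`effort` lacks PLL for some years in the histories")
  pll_lookup[setdiff(as.character(years), names(pll_lookup))] <- 0
  half_cut <- ceiling(D / 2)
  z <- standardize_day(seq_len(D - 1), D)
  pr <- list(coef_sd = priors$coef_sd, sd_scale = priors$sd_scale,
             pmax_a = priors$pmax_shape[1], pmax_b = priors$pmax_shape[2],
             psi1_a = priors$psi1_shape[1], psi1_b = priors$psi1_shape[2])
  S <- length(sites); Ty <- length(years)
  P <- 16L + 3L * S + 2L * Ty
  base_init <- c(0, 0, 0, 0, 0, 1, 0, 0, -2, 0, 0, rep(log(0.5), 5),
                 rep(0, 3L * S + 2L * Ty))
  ti_target <- match(target_year, years)
  n_keep <- mcmc$samples %/% mcmc$thin

  by_species <- split(histories, histories$species)
  fits <- vector("list", length(pool))
  names(fits) <- pool
  for (sp in pool) {
    blocks <- build_species_blocks(by_species[[sp]] %||% histories[0, ],
                                   sites, years, pll_lookup, half_cut)
    par_all <- matrix(NA_real_, n_keep * mcmc$chains, P)
    chain_id <- rep(seq_len(mcmc$chains), each = n_keep)
    traj <- array(NA_integer_, c(n_keep * mcmc$chains, S, D))
    arate <- matrix(NA_real_, mcmc$chains, P)
    t0 <- Sys.time()
    for (ch in seq_len(mcmc$chains)) {
      res <- local_seed(op_seed(seed, paste0("fit_", sp, "_chain", ch)), {
        init <- base_init + rnorm(P, 0, 0.1)
        siteuse_mcmc_cpp(blocks, D, S, Ty, z, pr, mcmc$warmup, mcmc$samples,
                         mcmc$thin, init, ti_target, mcmc$step_init)
      })
      rows <- (ch - 1L) * n_keep + seq_len(n_keep)
      par_all[rows, ] <- res$par
      slot <- array(res$traj, c(res$n_keep, length(res$traj_sites), D))
      traj[rows, res$traj_sites, ] <- slot
      arate[ch, ] <- res$accept_rate
    }
    su_inform("fit_siteuse: %s done in %.1fs", sp,
              as.numeric(difftime(Sys.time(), t0, units = "secs")), quiet = quiet)
    colnames(par_all) <- siteuse_param_names(sites, years)
    dimnames(traj) <- list(NULL, sites, NULL)
    fits[[sp]] <- list(draws = par_all, chain = chain_id, traj = traj,
                       accept_rate = colMeans(arate))
  }
  structure(
    list(species = fits, sites = sites, years = years,
         target_year = target_year, n_days = D,
         param_names = siteuse_param_names(sites, years),
         mcmc = mcmc, priors = priors, effort = effort, seed = seed),
    class = "siteuse_fit"
  )
}

#' @export
print.siteuse_fit <- function(x, ...) {
  cat(sprintf(paste0("<siteuse_fit> %d species, %d sites, years %s ",
                     "(trajectories stored for %d)\n  %d chains x %d kept ",
                     "draws, D = %d\n"),
              length(x$species), length(x$sites),
              paste(range(x$years), collapse = "-"), x$target_year,
              x$mcmc$chains, x$mcmc$samples %/% x$mcmc$thin, x$n_days))
  invisible(x)
}

#' Posterior parameter draws on the natural scale
#'
#' @param fit A `siteuse_fit`.
#' @param species One species name.
#' @return A tibble with one row per kept draw: `.chain`, `.iter` and one
#'   column per parameter (`pmax`, `psi1` as probabilities, `sigma_*` as
#'   standard deviations, coefficients as-is, raw random effects unscaled).
#' @export
posterior_params <- function(fit, species) {
  stopifnot(inherits(fit, "siteuse_fit"))
  sp <- fit$species[[species]]
  if (is.null(sp)) abort(sprintf("species '%s' not in fit", species))
  nat <- natural_transform(sp$draws, fit$param_names)
  out <- as_tibble(nat)
  out$.chain <- sp$chain
  out$.iter <- stats::ave(seq_along(sp$chain), sp$chain, FUN = seq_along)
  select(out, ".chain", ".iter", dplyr::everything())
}

#' Posterior latent-trajectory draws for one species
#'
#' @param fit A `siteuse_fit`.
#' @param species One species name.
#' @return Integer array `draw x site x day` of latent daily occupancy for
#'   the fit's target year.
#' @export
posterior_trajectories <- function(fit, species) {
  stopifnot(inherits(fit, "siteuse_fit"))
  sp <- fit$species[[species]]
  if (is.null(sp)) abort(sprintf("species '%s' not in fit", species))
  sp$traj
}
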