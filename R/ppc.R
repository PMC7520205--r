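#' Posterior predictive goodness-of-fit check
#'
#' Simulates replicated detection data from the joint posterior (parameter
#' draws plus the matching latent trajectory draws) for the fit's target year
#' and compares summary statistics of the replicates with the observed data.
#' Three families of statistics are checked: total detections per site,
#' number of sites with at least one detection per day (naive daily
#' occupancy), and total detections per SLL class (1, 2-4, 5+), the latter
#' being sensitive to misspecification of the list-length detection
#' relationship. P-values are mid-p, `P(rep > obs) + 0.5 P(rep = obs)`, so
#' they remain calibrated for discrete counts; values near 0 or 1 flag
#' misfit.
#'
#' @param fit A `siteuse_fit`.
#' @param histories The detection histories the model was fitted to.
#' @param n_rep Number of posterior draws used for replication (default 500,
#'   thinned evenly from the kept draws).
#' @param seed Integer seed for the replication noise.
#' @return A tibble `species`, `statistic`, `group`, `observed`, `p_value`.
#' @export
posterior_predictive_check <- function(fit, histories, n_rep = 500L, seed = 1L) {
  stopifnot(inherits(fit, "siteuse_fit"))
  n_rep <- assert_scalar_int(n_rep, "n_rep")
  half_cut <- ceiling(fit$n_days / 2)
  pll_lookup <- setNames(fit$effort$pll$pll, as.character(fit$effort$pll$year))
  out <- lapply(names(fit$species), function(sp) {
    h <- filter(histories, .data$species == sp, .data$year == fit$target_year)
    if (nrow(h) == 0) return(NULL)
    nat <- natural_transform(fit$species[[sp]]$draws, fit$param_names)
    n_total <- nrow(nat)
    idx <- unique(round(seq(1, n_total, length.out = min(n_rep, n_total))))
    nd <- length(idx)
    nv <- nrow(h)
    site_idx <- match(h$site, fit$sites)
    araw <- nat[idx, paste0("alpha_raw[", fit$sites, "]"), drop = FALSE]
    alpha <- nat[idx, "mu_alpha"] + nat[idx, "sigma_alpha"] * araw[, site_idx, drop = FALSE]
    half_on <- as.numeric(h$day > half_cut)
    pllv <- unname(pll_lookup[as.character(h$year)])
    lam <- exp(alpha + outer(nat[idx, "eta2"], half_on) +
                 outer(nat[idx, "delta"], pllv))
    p <- nat[idx, "pmax"] * (1 - exp(-lam * rep(h$sll, each = nd)))
    traj <- fit$species[[sp]]$traj
    u <- matrix(traj[cbind(rep(idx, nv), rep(site_idx, each = nd),
                           rep(h$day, each = nd))], nd, nv)
    yrep <- local_seed(op_seed(seed, paste0("ppc_", sp)), {
      matrix(rbinom(nd * nv, 1L, as.vector(u * p)), nd, nv)
    })
    mid_p <- function(rep_stat, obs) {
      colMeans(rep_stat > matrix(obs, nrow(rep_stat), length(obs), byrow = TRUE)) +
        0.5 * colMeans(rep_stat == matrix(obs, nrow(rep_stat), length(obs), byrow = TRUE))
    }
    # per-site detection totals
    fsite <- factor(h$site, fit$sites)
    rep_site <- t(rowsum(t(yrep), fsite))
    obs_site <- as.vector(rowsum(h$y, fsite))
    # per-day count of sites with >= 1 detection
    fsd <- factor(paste(h$site, h$day, sep = "\r"))
    day_of_sd <- factor(as.integer(vapply(strsplit(levels(fsd), "\r", fixed = TRUE),
                                          `[`, "", 2)))
    rep_sd <- t(rowsum(t(yrep), fsd)) > 0
    rep_day <- t(rowsum(t(rep_sd) * 1L, day_of_sd))
    obs_sd <- as.vector(rowsum(h$y, fsd)) > 0
    obs_day <- as.vector(rowsum(obs_sd * 1L, day_of_sd))
    # detections per SLL class
    sll_class <- droplevels(cut(h$sll, c(0, 1, 4, Inf),
                                labels = c("1", "2-4", "5+")))
    rep_sll <- t(rowsum(t(yrep), sll_class))
    obs_sll <- as.vector(rowsum(h$y, sll_class))
    bind_rows(
      tibble(species = sp, statistic = "site_total", group = fit$sites,
             observed = as.numeric(obs_site),
             p_value = mid_p(rep_site, obs_site)),
      tibble(species = sp, statistic = "day_occupancy",
             group = levels(day_of_sd),
             observed = as.numeric(obs_day),
             p_value = mid_p(rep_day, obs_day)),
      tibble(species = sp, statistic = "sll_class",
             group = levels(sll_class),
             observed = as.numeric(obs_sll),
             p_value = mid_p(rep_sll, obs_sll))
    )
  })
  bind_rows(out)
}
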