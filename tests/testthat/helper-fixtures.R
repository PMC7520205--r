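# shared fixtures built in code

tiny_obs <- function() {
  tibble::tibble(
    species = c("A", "B", "C", "A", "B", "A"),
    site = c("w1", "w1", "w1", "w2", "w2", "w1"),
    year = 2014L,
    day = c(5L, 5L, 5L, 5L, 5L, 9L),
    observer = c("o1", "o1", "o1", "o1", "o1", "o2")
  )
}

small_sim_config <- function(...) {
  sim_config(n_species = 3L, n_sites = 5L, n_years = 1L, n_days = 30L,
             visit_mean = 3, ...)
}

small_fitted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_sim_config()
      sim <- simulate_dataset(cfg, seed = 11)
      vc <- cap_visits(assemble_visits(sim$observations))
      eff <- compute_effort_covariates(vc, n_days = cfg$n_days)
      hist <- build_detection_histories(
        vc, species_pool = sort(unique(c(unlist(vc$species),
                                         sim$focal_species))))
      fit <- fit_siteuse(hist, eff,
                         mcmc = mcmc_config(chains = 2, warmup = 300,
                                            samples = 300),
                         species = sim$focal_species,
                         sites = sim_config_sites(cfg), seed = 2, quiet = TRUE)
      cache <<- list(config = cfg, sim = sim, visits = vc, effort = eff,
                     histories = hist, fit = fit)
    }
    cache
  }
})

sim_config_sites <- function(cfg) sprintf("site%02d", seq_len(cfg$n_sites))

# the standard parameter-recovery fixture (10 species x 15 sites x 90 days,
# mean 5 visits/site-day) fitted with the default 3 x (1000 + 1000) sampler;
# computed once and reused by the acceptance checks
standard_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()
      sim <- simulate_dataset(cfg, seed = 20)
      vc <- cap_visits(assemble_visits(sim$observations))
      eff <- compute_effort_covariates(vc, n_days = cfg$n_days)
      hist <- build_detection_histories(
        vc, species_pool = sort(unique(c(unlist(vc$species),
                                         sim$focal_species))))
      fit <- fit_siteuse(hist, eff, species = sim$focal_species,
                         sites = sim_config_sites(cfg),
                         seed = 5, quiet = TRUE)
      cache <<- list(config = cfg, sim = sim, visits = vc, effort = eff,
                     histories = hist, fit = fit)
    }
    cache
  }
})
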