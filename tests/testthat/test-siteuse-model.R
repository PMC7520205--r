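test_that("detection probability saturates at pmax and increases with SLL", {
  # direct evaluation of the stated form
  expect_equal(detection_probability(2, pmax = 0.8, alpha = log(0.5)),
               0.8 * (1 - exp(-1)))
  # saturation limit
  expect_equal(detection_probability(1, pmax = 0.7, alpha = 30), 0.7)
  # monotone in sll for arbitrary parameters
  p <- detection_probability(1:10, pmax = 0.9, alpha = -0.3, eta = 0.2,
                             delta = 0.5, pll = 0.1)
  expect_true(all(diff(p) > 0))
  expect_true(all(p <= 0.9))
  expect_error(detection_probability(0, 0.5, 0), "sll")
})

test_that("transition probabilities follow the quadratic logit form", {
  # all coefficients zero -> 0.5
  tp0 <- transition_probabilities(1:9, 10, b = c(0, 0, 0), c = c(0, 0, 0))
  expect_true(all(tp0$phi == 0.5) && all(tp0$gamma == 0.5))
  # intercept 1 -> inverse logit
  tp1 <- transition_probabilities(5, 10, b = c(1, 0, 0), c = c(0, 0, 0))
  expect_equal(tp1$phi, plogis(1 + 0.5^2 * 0))  # z(5, D=10) affects b1,b2 only
  # concave in day when b2 < 0, b1 = 0: maximal mid-season
  tp2 <- transition_probabilities(1:89, 90, b = c(0, 0, -1), c = c(0, 0, 0))
  expect_equal(which.max(tp2$phi), 45)
  expect_error(transition_probabilities(90, 90, b = c(0,0,0), c = c(0,0,0)),
               "\\[1, 89\\]")
})

test_that("forward log-likelihood equals brute-force enumeration", {
  set.seed(101)
  for (r in 1:60) {
    inst <- random_instance()
    ll <- forward_loglik(inst$day, inst$y, inst$p, inst$psi1, inst$phi,
                         inst$gamma, inst$D)
    expect_equal(ll, enum_loglik(inst$day, inst$y, inst$p, inst$psi1,
                                 inst$phi, inst$gamma, inst$D),
                 tolerance = 1e-10)
  }
})

test_that("forward log-likelihood handles edge cases and visit order", {
  # never present, never detected: probability 1
  expect_equal(forward_loglik(integer(0), integer(0), numeric(0), psi1 = 0,
                              phi = rep(0.5, 3), gamma = rep(0, 3), 4), 0)
  # a detection is impossible when the species can never be present
  expect_equal(forward_loglik(2L, 1L, 0.5, psi1 = 0,
                              phi = rep(0.7, 3), gamma = rep(0, 3), 4), -Inf)
  # likelihood invariant to visit order within a day
  set.seed(7)
  inst <- random_instance(D = 6, max_visits_per_day = 3)
  ord <- sample(seq_along(inst$day))
  expect_equal(
    forward_loglik(inst$day, inst$y, inst$p, inst$psi1, inst$phi, inst$gamma, 6),
    forward_loglik(inst$day[ord], inst$y[ord], inst$p[ord], inst$psi1,
                   inst$phi, inst$gamma, 6)
  )
})

test_that("FFBS draws the exact conditional trajectory distribution", {
  # detection days are always occupied
  tr <- ffbs_trajectory(day = c(1L, 2L), y = c(0L, 1L), p = c(0.6, 0.6),
                        psi1 = 0.4, phi = c(0.6, 0.6), gamma = c(0.3, 0.3),
                        n_days = 3, n_draws = 500, seed = 1)
  expect_true(all(tr[, 2] == 1))
  # D = 3 toy chain: empirical trajectory frequencies match enumeration
  day <- c(1L, 3L); y <- c(1L, 0L); p <- c(0.7, 0.5)
  psi1 <- 0.6; phi <- c(0.7, 0.7); gamma <- c(0.25, 0.25)
  n <- 20000
  tr <- ffbs_trajectory(day, y, p, psi1, phi, gamma, 3, n_draws = n, seed = 2)
  cond <- enum_conditional(day, y, p, psi1, phi, gamma, 3)
  key <- apply(cond$trajs, 1, paste, collapse = "")
  emp <- table(factor(apply(tr, 1, paste, collapse = ""), levels = key)) / n
  for (i in seq_along(key)) {
    se <- sqrt(cond$weight[i] * (1 - cond$weight[i]) / n)
    expect_lt(abs(emp[[i]] - cond$weight[i]), 3 * se + 1e-12)
  }
  # no data: marginal occupancy follows the prior chain
  tr0 <- ffbs_trajectory(integer(0), integer(0), numeric(0), psi1 = 0.3,
                         phi = rep(0.8, 4), gamma = rep(0.2, 4), 5,
                         n_draws = 20000, seed = 3)
  marg <- 0.3
  for (d in 1:4) marg <- c(marg, marg[d] * 0.8 + (1 - marg[d]) * 0.2)
  for (d in 1:5) {
    se <- sqrt(marg[d] * (1 - marg[d]) / 20000)
    expect_lt(abs(mean(tr0[, d]) - marg[d]), 3 * se)
  }
})

test_that("posterior sampling is reproducible and prior-centred without data", {
  empty <- tibble::tibble(species = character(), site = character(),
                          year = integer(), day = integer(),
                          visit_id = integer(), sll = integer(), y = integer())
  fit <- fit_siteuse(empty, effort = NULL, species = "spA", sites = "s1",
                     years = 2014L, n_days = 12,
                     mcmc = mcmc_config(chains = 2, warmup = 400, samples = 600),
                     seed = 21, quiet = TRUE)
  dr <- posterior_params(fit, "spA")
  # prior means: pmax ~ Beta(2,2) -> 0.5; b0 ~ N(0, 1.5) -> 0
  mc_se <- function(x) stats::sd(x) / sqrt(max(siteuse:::ess_basic(x, dr$.chain), 4))
  expect_lt(abs(mean(dr$pmax) - 0.5), 3 * mc_se(dr$pmax))
  expect_lt(abs(mean(dr$b0) - 0), 3 * mc_se(dr$b0))
  expect_lt(abs(mean(dr$psi1) - 0.5), 3 * mc_se(dr$psi1))
  # bit-identical refit under the same seed
  fit2 <- fit_siteuse(empty, effort = NULL, species = "spA", sites = "s1",
                      years = 2014L, n_days = 12,
                      mcmc = mcmc_config(chains = 2, warmup = 400, samples = 600),
                      seed = 21, quiet = TRUE)
  expect_identical(fit$species$spA$draws, fit2$species$spA$draws)
  expect_identical(fit$species$spA$traj, fit2$species$spA$traj)
})

test_that("posterior concentrates with more data", {
  # credible interval for pmax narrows as visits per day increase
  widths <- vapply(c(2, 10), function(vm) {
    cfg <- sim_config(n_species = 1, n_sites = 6, n_days = 40, visit_mean = vm,
                      visit_trend = 0, ranges = list(pmax = c(0.7, 0.7),
                                                     psi1 = c(0.5, 0.5),
                                                     b0 = c(2, 2), c0 = c(-1.5, -1.5)))
    sim <- simulate_dataset(cfg, seed = 31)
    vc <- cap_visits(assemble_visits(sim$observations))
    eff <- compute_effort_covariates(vc, n_days = cfg$n_days)
    h <- build_detection_histories(vc)
    fit <- fit_siteuse(h, eff, mcmc = mcmc_config(chains = 2, warmup = 300,
                                                  samples = 300),
                       species = sim$focal_species, seed = 32, quiet = TRUE)
    dr <- posterior_params(fit, sim$params$species[1])
    diff(stats::quantile(dr$pmax, c(0.05, 0.95)))
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("convergence diagnostics flag divergent chains and bound the ESS", {
  fx <- small_fitted()
  diag <- convergence_diagnostics(fx$fit)
  expect_true(all(diag$ess <= nrow(fx$fit$species[[1]]$draws) + 1e-8, na.rm = TRUE))
  # identical stationary chains: R-hat near 1
  x <- rep(rnorm(400), 2)
  chain <- rep(1:2, each = 400)
  expect_equal(siteuse:::rhat_split(x, chain), 1, tolerance = 0.02)
  # offset chains: flagged
  x2 <- c(rnorm(400), rnorm(400) + 5)
  expect_gt(siteuse:::rhat_split(x2, chain), 1.1)
  # single chain errors
  f1 <- fx$fit; f1$mcmc$chains <- 1L
  expect_error(convergence_diagnostics(f1), "2 chains")
})

test_that("tidy and glance summarise the fit", {
  fx <- small_fitted()
  td <- tidy(fx$fit)
  expect_true(all(c("species", "term", "estimate", "conf.low", "conf.high",
                    "rhat", "ess") %in% names(td)))
  expect_true(all(td$estimate[td$term == "pmax"] > 0 &
                    td$estimate[td$term == "pmax"] <= 1))
  gl <- glance(fx$fit)
  expect_equal(nrow(gl), 3)
  expect_true(all(gl$n_draws == 600))
})

test_that("posterior predictive checks are bounded and detect misfit", {
  fx <- small_fitted()
  ppc <- posterior_predictive_check(fx$fit, fx$histories, n_rep = 200, seed = 5)
  expect_true(all(ppc$p_value >= 0 & ppc$p_value <= 1))
  # data simulated from the model itself: mostly unflagged
  expect_gt(mean(ppc$p_value > 0.05 & ppc$p_value < 0.95), 0.8)

  # misspecified data: detection probability *decreasing* in SLL cannot be
  # reconciled with the saturating form; SLL-class statistics should flag it
  cfg <- small_sim_config()
  sim <- simulate_dataset(cfg, seed = 41)
  sch <- sim$schedule
  p_dec <- 0.9 * exp(-0.8 * (sch$sll_target - 1)) + 0.02
  truth <- sim$truth
  key <- paste(truth$site, truth$year, truth$day)
  recs <- lapply(sim$params$species, function(sp) {
    us <- truth[truth$species == sp, ]
    u <- us$u[match(paste(sch$site, sch$year, sch$day), paste(us$site, us$year, us$day))]
    hit <- withr::with_seed(42 + match(sp, sim$params$species),
                            rbinom(nrow(sch), 1, u * p_dec)) == 1
    tibble::tibble(species = sp, site = sch$site[hit], year = sch$year[hit],
                   day = sch$day[hit], observer = sch$observer[hit])
  })
  obs_mis <- dplyr::bind_rows(recs)
  vc <- cap_visits(assemble_visits(obs_mis))
  eff <- compute_effort_covariates(vc, n_days = cfg$n_days)
  h <- build_detection_histories(vc)
  fit_mis <- fit_siteuse(h, eff, mcmc = mcmc_config(chains = 2, warmup = 300,
                                                    samples = 300),
                         seed = 43, quiet = TRUE)
  ppc_mis <- posterior_predictive_check(fit_mis, h, n_rep = 200, seed = 44)
  flagged <- ppc_mis$p_value < 0.05 | ppc_mis$p_value > 0.95
  expect_gt(sum(flagged[ppc_mis$statistic == "sll_class"]), 0)
})
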