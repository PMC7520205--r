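test_that("the generator is deterministic given the seed", {
  cfg <- small_sim_config()
  a <- simulate_dataset(cfg, seed = 9)
  b <- simulate_dataset(cfg, seed = 9)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  expect_identical(a$schedule, b$schedule)
  c <- simulate_dataset(cfg, seed = 10)
  expect_false(identical(a$observations, c$observations))
})

test_that("species parameters respect configured ranges", {
  cfg <- small_sim_config(ranges = list(pmax = c(0.4, 0.4)))
  p <- draw_species_params(cfg, seed = 1)
  expect_true(all(p$pmax == 0.4))
  expect_true(all(p$b0 >= cfg$ranges$b0[1] & p$b0 <= cfg$ranges$b0[2]))
  expect_true(all(p$c0 >= cfg$ranges$c0[1] & p$c0 <= cfg$ranges$c0[2]))
  expect_error(sim_config(ranges = list(pmax = c(0.9, 0.1))), "lo <= hi")
  expect_error(sim_config(ranges = list(nope = c(0, 1))), "unknown")
})

test_that("occupancy dynamics honour degenerate transition limits", {
  cfg <- sim_config(n_species = 2, n_sites = 4, n_days = 12)
  p <- draw_species_params(cfg, seed = 3)
  # phi = 1, gamma = 0: trajectories frozen at the initial state
  p_frozen <- p
  p_frozen$b0 <- 40; p_frozen$b1 <- p_frozen$b2 <- 0
  p_frozen$c0 <- -40; p_frozen$c1 <- p_frozen$c2 <- 0
  for (i in seq_len(nrow(p_frozen))) {
    p_frozen$phi_site[[i]][] <- 0; p_frozen$gamma_site[[i]][] <- 0
    p_frozen$phi_year[[i]][] <- 0; p_frozen$gamma_year[[i]][] <- 0
  }
  u <- simulate_occupancy(p_frozen, cfg, seed = 3)
  byu <- dplyr::summarise(dplyr::group_by(u, species, site),
                          const = length(unique(u)) == 1)
  expect_true(all(byu$const))
  # psi1 = 1 and phi = 1: all ones
  p_ones <- p_frozen
  p_ones$psi1 <- 1
  u1 <- simulate_occupancy(p_ones, cfg, seed = 3)
  expect_true(all(u1$u == 1))
})

test_that("a symmetric fair chain yields ~50% long-run daily occupancy", {
  # psi1 = 0.5, phi = gamma = 0.5 -> stationary occupancy 0.5
  cfg <- sim_config(n_species = 1, n_sites = 60, n_days = 60)
  p <- draw_species_params(cfg, seed = 8)
  p$psi1 <- 0.5; p$b0 <- 0; p$b1 <- p$b2 <- 0; p$c0 <- 0; p$c1 <- p$c2 <- 0
  p$phi_site[[1]][] <- 0; p$gamma_site[[1]][] <- 0
  p$phi_year[[1]][] <- 0; p$gamma_year[[1]][] <- 0
  u <- simulate_occupancy(p, cfg, seed = 8)
  n <- nrow(u)
  se <- 0.5 / sqrt(n)   # conservative: treats days as independent
  expect_lt(abs(mean(u$u) - 0.5), 3 * se * sqrt(2))
})

test_that("visit schedule matches the effort model", {
  cfg <- sim_config(n_species = 1, n_sites = 20, n_days = 60,
                    visit_mean = 5, visit_trend = 0)
  sch <- simulate_visit_schedule(cfg, seed = 2)
  n_cells <- 20 * 60
  mean_visits <- nrow(sch) / n_cells
  # negative binomial: var = mu + mu^2/size
  se <- sqrt((5 + 25 / cfg$visit_dispersion) / n_cells)
  expect_lt(abs(mean_visits - 5), 3 * se)
  # singleton fraction of the target SLL ~ 0.6
  frac1 <- mean(sch$sll_target == 1)
  expect_lt(abs(frac1 - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(sch)))
  # truncation at 40 visits per site-day
  counts <- dplyr::count(sch, site, year, day)
  expect_true(all(counts$n <= 40))
  # declining effort when trend < 0
  cfg2 <- sim_config(n_species = 1, n_sites = 30, n_days = 60,
                     visit_mean = 5, visit_trend = -1)
  sch2 <- simulate_visit_schedule(cfg2, seed = 2)
  first <- sum(sch2$day <= 30) / (30 * 30)
  second <- sum(sch2$day > 30) / (30 * 30)
  expect_gt(first, second)
})

test_that("detections require presence and respect the detection model", {
  # closed focal community (no background reporters)
  cfg <- sim_config(n_species = 2, n_sites = 5, n_days = 20, n_background = 0)
  p <- draw_species_params(cfg, seed = 6)
  sch <- simulate_visit_schedule(cfg, seed = 6)
  # u = 0 everywhere -> no records at all
  u0 <- tidyr::expand_grid(species = p$species,
                           site = sprintf("site%02d", 1:5),
                           year = 2014L, day = 1:20) |>
    dplyr::mutate(u = 0L)
  rec0 <- simulate_detections(u0, sch, p, cfg, seed = 6)
  expect_equal(nrow(rec0), 0)
  # perfect detection: every present species is on every visit's list
  p_perf <- p
  p_perf$pmax <- 1; p_perf$alpha <- 20; p_perf$eta2 <- 0; p_perf$delta <- 0
  for (i in 1:2) p_perf$alpha_site[[i]][] <- 0
  u1 <- dplyr::mutate(u0, u = 1L)
  rec1 <- simulate_detections(u1, sch, p_perf, cfg, seed = 6)
  expect_equal(nrow(rec1), 2 * nrow(sch))
  # detection frequency at occupied site-days ~ mean detection probability
  p_half <- p_perf
  p_half$pmax <- 0.5; p_half$alpha <- 20    # saturated: p = pmax exactly
  rec <- simulate_detections(u1, sch, p_half, cfg, seed = 7)
  rate <- nrow(rec) / (2 * nrow(sch))
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / (2 * nrow(sch))))
})

test_that("simulated records pass validation and close the richness loop", {
  # perfect detection + guaranteed daily visits: observed daily richness
  # equals true daily richness
  cfg <- sim_config(n_species = 4, n_sites = 6, n_days = 15, visit_mean = 6,
                    visit_trend = 0, n_background = 0)
  p <- draw_species_params(cfg, seed = 12)
  p$pmax <- 1; p$alpha <- 20; p$eta2 <- 0; p$delta <- 0
  for (i in seq_len(nrow(p))) p$alpha_site[[i]][] <- 0
  truth <- simulate_occupancy(p, cfg, seed = 12)
  sch <- simulate_visit_schedule(cfg, seed = 12)
  # force at least one visit per site-day
  missing <- dplyr::anti_join(
    tidyr::expand_grid(site = sprintf("site%02d", 1:6), year = 2014L, day = 1:15),
    sch, by = c("site", "year", "day"))
  if (nrow(missing) > 0) {
    missing$observer <- "extra"; missing$sll_target <- 1L
    sch <- dplyr::bind_rows(sch, missing)
  }
  rec <- simulate_detections(truth, sch, p, cfg, seed = 12)
  expect_silent(validate_obs <- assemble_visits(rec))
  obs_daily <- observed_daily_richness(rec, 2014L, 15,
                                       sites = sprintf("site%02d", 1:6))
  true_daily <- truth |>
    dplyr::group_by(site, day) |>
    dplyr::summarise(S_true = sum(u), .groups = "drop")
  j <- dplyr::left_join(obs_daily, true_daily, by = c("site", "day"))
  expect_equal(j$S_day_obs, as.integer(j$S_true))
})
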