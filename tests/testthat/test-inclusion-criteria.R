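test_that("trajectory statistics count total days and longest runs", {
  expect_equal(trajectory_statistics(c(1, 0, 1, 1, 0)),
               list(total_days = 3L, longest_run = 2L))
  expect_equal(trajectory_statistics(rep(0, 10)),
               list(total_days = 0L, longest_run = 0L))
  expect_equal(trajectory_statistics(rep(1, 90)),
               list(total_days = 90L, longest_run = 90L))
  expect_error(trajectory_statistics(c(0, 2, 1)), "0 and 1")
  expect_error(trajectory_statistics(numeric(0)), "non-empty")
})

test_that("the criterion set collapses the modes at k = 1", {
  crit <- inclusion_criteria()
  expect_equal(sum(crit$k == 1), 1)
  expect_equal(nrow(crit), 9)   # {1,5,10,20,30} x modes, one row at k = 1
  crit2 <- inclusion_criteria(k = c(1, 10, 20, 30))
  expect_equal(nrow(crit2), 7)  # the seven-criterion variant
})

test_that("exact DP inclusion probabilities match enumeration", {
  # analytic fair-coin cases
  expect_equal(exact_inclusion_probability(0.5, c(.5, .5), c(.5, .5), 2,
                                           "nonconsecutive"), 0.5)
  expect_equal(exact_inclusion_probability(0.5, c(.5, .5), c(.5, .5), 2,
                                           "consecutive"), 0.375)
  expect_equal(exact_inclusion_probability(1, c(.3, .3), c(.1, .1), 1,
                                           "nonconsecutive"), 1)
  set.seed(55)
  for (r in 1:25) {
    D <- sample(2:9, 1)
    psi1 <- runif(1); phi <- runif(D - 1); gamma <- runif(D - 1)
    k <- sample(1:D, 1)
    for (mode in c("nonconsecutive", "consecutive")) {
      expect_equal(exact_inclusion_probability(psi1, phi, gamma, k, mode),
                   enum_inclusion(psi1, phi, gamma, D, k, mode),
                   tolerance = 1e-12)
    }
  }
  # monotone and nested in k; consecutive never exceeds nonconsecutive
  psi1 <- 0.6; phi <- rep(0.7, 7); gamma <- rep(0.2, 7)
  pn <- sapply(1:8, exact_inclusion_probability, psi1 = psi1, phi = phi,
               gamma = gamma, mode = "nonconsecutive")
  pc <- sapply(1:8, exact_inclusion_probability, psi1 = psi1, phi = phi,
               gamma = gamma, mode = "consecutive")
  expect_true(all(diff(pn) <= 1e-12) && all(diff(pc) <= 1e-12))
  expect_true(all(pc <= pn + 1e-12))
  expect_equal(pn[1], pc[1])
})

test_that("draw-based inclusion probabilities converge to the DP oracle", {
  # prior draws through the package's own FFBS, vs exact DP
  set.seed(66)
  n <- 20000
  for (r in 1:5) {
    D <- sample(4:12, 1)
    psi1 <- runif(1, 0.2, 0.8)
    phi <- runif(D - 1, 0.3, 0.9); gamma <- runif(D - 1, 0.05, 0.4)
    tr <- ffbs_trajectory(integer(0), integer(0), numeric(0), psi1, phi,
                          gamma, D, n_draws = n)
    stats <- matrix(0L, n, 2)
    stats[, 1] <- rowSums(tr)
    stats[, 2] <- apply(tr, 1, function(u) {
      rl <- rle(u); max(c(0, rl$lengths[rl$values == 1]))
    })
    for (k in 1:3) {
      for (mode in c("nonconsecutive", "consecutive")) {
        exact <- exact_inclusion_probability(psi1, phi, gamma, k, mode)
        est <- if (mode == "nonconsecutive") mean(stats[, 1] >= k)
               else mean(stats[, 2] >= k)
        se <- sqrt(exact * (1 - exact) / n)
        expect_lt(abs(est - exact), 3 * se + 1e-9)
      }
    }
  }
})

test_that("fit-based inclusion tables satisfy the ordering invariants", {
  fx <- small_fitted()
  crit <- inclusion_criteria(k = c(1, 3, 5, 10))
  incl <- inclusion_probability(fx$fit, crit)
  wide <- tidyr::pivot_wider(incl, names_from = c(mode, k),
                             values_from = prob, id_cols = c(species, site))
  # nonincreasing in k within each mode
  expect_true(all(wide$nonconsecutive_1 >= wide$nonconsecutive_3 - 1e-12))
  expect_true(all(wide$nonconsecutive_3 >= wide$nonconsecutive_5 - 1e-12))
  expect_true(all(wide$consecutive_3 >= wide$consecutive_5 - 1e-12))
  # consecutive <= nonconsecutive at equal k
  expect_true(all(wide$consecutive_5 <= wide$nonconsecutive_5 + 1e-12))
  expect_error(inclusion_probability(fx$fit, crit, species = "nope"),
               "unknown")
})

test_that("estimated richness sums inclusion probabilities, with draw-based CIs", {
  # summation identity on a toy table
  tab <- tibble::tibble(species = c("a", "b", "c"), site = "s1",
                        k = 1L, mode = "nonconsecutive",
                        prob = c(1, 0.5, 0.25), n_draws = 100)
  expect_equal(estimated_richness(tab)$S, 1.75)
  tab0 <- dplyr::mutate(tab, prob = 0)
  expect_equal(estimated_richness(tab0)$S, 0)
  expect_error(estimated_richness(tab, species_pool = c("a", "b", "c", "d")),
               "pool")
  # fit-based: per-draw mean equals the probability sum
  fx <- small_fitted()
  crit <- inclusion_criteria(k = c(1, 5))
  rt <- richness_table(fx$fit, crit)
  er <- estimated_richness(inclusion_probability(fx$fit, crit))
  j <- dplyr::inner_join(rt, er, by = c("site", "k", "mode"))
  expect_equal(j$S.x, j$S.y, tolerance = 1e-10)
  expect_true(all(j$lower <= j$upper))
  expect_true(all(j$lower >= 0 & j$upper <= length(fx$fit$species)))
  # richness at k = 1 dominates any stricter criterion
  w <- tidyr::pivot_wider(rt, id_cols = site, names_from = c(mode, k),
                          values_from = S)
  expect_true(all(w$nonconsecutive_1 >= w$nonconsecutive_5 - 1e-9))
  expect_true(all(w$nonconsecutive_1 >= w$consecutive_5 - 1e-9))
})

test_that("observed richness counts distinct observation days", {
  obs <- tibble::tibble(
    species = c("A", "A", "A", "B", "B", "C"),
    site = "w1", year = 2014L,
    day = c(3L, 7L, 50L, 10L, 10L, 2L),
    observer = c("o1", "o1", "o1", "o1", "o2", "o1")
  )
  expect_equal(observed_richness(obs, 3, 2014)$observed_S, 1L)  # A only
  # B seen twice on the same day: one distinct day
  expect_equal(observed_richness(obs, 2, 2014)$observed_S, 1L)
  expect_equal(observed_richness(obs, 1, 2014)$observed_S, 3L)
  expect_error(observed_richness(obs, 2, 2014, mode = "consecutive"),
               "nonconsecutive")
})

test_that("daily richness sums posterior mean occupancy over species", {
  fx <- small_fitted()
  dr <- daily_richness(fx$fit)
  expect_equal(nrow(dr), length(fx$fit$sites) * fx$fit$n_days)
  expect_true(all(dr$S_day >= 0 & dr$S_day <= length(fx$fit$species)))
  # manual check for one site/day
  sp <- names(fx$fit$species)
  manual <- sum(vapply(sp, function(s)
    mean(fx$fit$species[[s]]$traj[, 1, 1]), numeric(1)))
  expect_equal(dr$S_day[dr$site == fx$fit$sites[1] & dr$day == 1], manual)
})
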