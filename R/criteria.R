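#' Define a set of inclusion criteria
#'
#' An inclusion criterion admits a species to a site's seasonal list when it
#' was present on at least `k` days, counted either over any days of the
#' season (nonconsecutive) or as an unbroken run (consecutive). At `k = 1`
#' the two modes coincide, so only the nonconsecutive labelling is kept.
#'
#' @param k Integer vector of day thresholds (default `c(1, 5, 10, 20, 30)`).
#' @param modes Modes to cross with `k`.
#' @return A tibble `k`, `mode` of distinct criteria.
#' @export
inclusion_criteria <- function(k = c(1L, 5L, 10L, 20L, 30L),
                               modes = c("nonconsecutive", "consecutive")) {
  if (any(k < 1) || any(k != as.integer(k))) abort("`k` must be integers >= 1")
  modes <- match.arg(modes, several.ok = TRUE)
  tidyr::expand_grid(k = sort(unique(as.integer(k))), mode = modes) |>
    filter(!(.data$k == 1 & .data$mode == "consecutive")) |>
    arrange(.data$mode, .data$k)
}

#' Run statistics of a binary occupancy trajectory
#'
#' @param u Binary vector (a daily occupancy trajectory).
#' @return A named list: `total_days` (number of presence days) and
#'   `longest_run` (length of the longest unbroken presence run).
#' @examples
#' trajectory_statistics(c(1, 0, 1, 1, 0))
#' @export
trajectory_statistics <- function(u) {
  u <- assert_binary(u)
  st <- run_stats_cpp(matrix(u, nrow = 1))
  list(total_days = st[1, 1], longest_run = st[1, 2])
}

criterion_met <- function(stats, k, mode) {
  if (mode == "nonconsecutive") stats[, 1] >= k else stats[, 2] >= k
}

#' Posterior inclusion probabilities under the criteria
#'
#' For every species, site and criterion, computes the fraction of posterior
#' trajectory draws (target year) in which the species was present for at
#' least `k` days, nonconsecutive or consecutive. Evaluating criteria on
#' whole trajectory draws (not daily marginals) accounts for within-season
#' dependence and makes consecutive-run criteria possible at all.
#'
#' @param fit A `siteuse_fit`.
#' @param criteria Tibble from [inclusion_criteria()].
#' @param species,sites Optional subsets; unknown names are an error.
#' @return A tibble `species`, `site`, `k`, `mode`, `prob`, `n_draws`, with
#'   `prob` nonincreasing in `k` and consecutive `prob` never exceeding the
#'   nonconsecutive one at equal `k`.
#' @export
inclusion_probability <- function(fit, criteria = inclusion_criteria(),
                                  species = NULL, sites = NULL) {
  stopifnot(inherits(fit, "siteuse_fit"))
  species <- species %||% names(fit$species)
  sites <- sites %||% fit$sites
  if (!all(species %in% names(fit$species))) abort("unknown species")
  if (!all(sites %in% fit$sites)) abort("unknown sites")
  out <- lapply(species, function(sp) {
    traj <- fit$species[[sp]]$traj
    nd <- dim(traj)[1]
    per_site <- lapply(sites, function(si) {
      stats <- run_stats_cpp(traj[, si, , drop = TRUE])
      res <- criteria
      res$prob <- vapply(seq_len(nrow(criteria)), function(i) {
        mean(criterion_met(stats, criteria$k[i], criteria$mode[i]))
      }, numeric(1))
      res$site <- si
      res
    })
    res <- bind_rows(per_site)
    res$species <- sp
    res
  })
  bind_rows(out) |>
    mutate(n_draws = vapply(.data$species,
                            function(sp) dim(fit$species[[sp]]$traj)[1],
                            numeric(1))) |>
    select("species", "site", "k", "mode", "prob", "n_draws")
}

#' Exact inclusion probability under a known occupancy chain
#'
#' Dynamic-programming evaluation of the probability that a two-state daily
#' occupancy chain with given initial occupancy, persistence and colonization
#' sequences is occupied on at least `k` days (total, or in a row). Serves as
#' the exact oracle the draw-based estimator converges to in the no-data
#' limit.
#'
#' @param psi1 Day-1 occupancy probability.
#' @param phi,gamma Numeric vectors of length `D - 1`: daily persistence and
#'   colonization probabilities.
#' @param k Day threshold (>= 1, <= D).
#' @param mode `"nonconsecutive"` or `"consecutive"`.
#' @return The exact probability.
#' @examples
#' # fair-coin days: P(run of 2 in 3 days) = 3/8
#' exact_inclusion_probability(0.5, c(0.5, 0.5), c(0.5, 0.5), 2, "consecutive")
#' @export
exact_inclusion_probability <- function(psi1, phi, gamma, k,
                                        mode = c("nonconsecutive", "consecutive")) {
  mode <- match.arg(mode)
  D <- length(phi) + 1L
  stopifnot(length(gamma) == D - 1L)
  k <- assert_scalar_int(k, "k")
  if (k > D) return(0)
  if (psi1 < 0 || psi1 > 1 || any(phi < 0 | phi > 1) || any(gamma < 0 | gamma > 1))
    abort("probabilities must lie in [0, 1]")
  if (mode == "nonconsecutive") {
    # state: (u, m = presence days so far, capped at k)
    M <- matrix(0, 2, k + 1)   # rows u = 0, 1; cols m = 0..k
    M[2, min(1, k) + 1] <- psi1
    M[1, 1] <- 1 - psi1
    for (d in seq_len(D - 1)) {
      N <- matrix(0, 2, k + 1)
      for (m in 0:k) {
        p0 <- M[1, m + 1]; p1 <- M[2, m + 1]
        if (p0 == 0 && p1 == 0) next
        to1 <- p1 * phi[d] + p0 * gamma[d]
        to0 <- p1 * (1 - phi[d]) + p0 * (1 - gamma[d])
        N[2, min(m + 1, k) + 1] <- N[2, min(m + 1, k) + 1] + to1
        N[1, m + 1] <- N[1, m + 1] + to0
      }
      M <- N
    }
    sum(M[, k + 1])
  } else {
    # states: satisfied (absorbing); (u = 1, run r in 1..k-1); (u = 0)
    sat <- 0
    run <- rep(0, max(k - 1, 1))  # P(u = 1, current run = r)
    p0 <- 1 - psi1
    if (k == 1) { sat <- psi1 } else { run[1] <- psi1 }
    for (d in seq_len(D - 1)) {
      new_run <- rep(0, max(k - 1, 1))
      new_p0 <- p0 * (1 - gamma[d])
      new_sat <- sat
      from0_to1 <- p0 * gamma[d]
      if (k == 1) new_sat <- new_sat + from0_to1 else new_run[1] <- from0_to1
      if (k > 1) {
        for (r in seq_len(k - 1)) {
          pr <- run[r]
          if (pr == 0) next
          stay <- pr * phi[d]
          if (r + 1 >= k) new_sat <- new_sat + stay
          else new_run[r + 1] <- new_run[r + 1] + stay
          new_p0 <- new_p0 + pr * (1 - phi[d])
        }
      }
      sat <- new_sat; run <- new_run; p0 <- new_p0
    }
    sat
  }
}
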