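#' Beta-diversity partition for every criterion
#'
#' Binarizes an inclusion-probability table at the threshold and computes
#' the pairwise partition per criterion.
#'
#' @inheritParams binarize
#' @param quiet Suppress degenerate-pair messages.
#' @return A tibble `k`, `mode`, `beta` (list-column of [beta_pair()]
#'   objects).
#' @export
beta_by_criterion <- function(inclusion_table, threshold = 0.5, quiet = FALSE) {
  lists <- binarize(inclusion_table, threshold)
  lists |>
    group_by(.data$k, .data$mode) |>
    summarise(beta = list(beta_pair(setNames(.data$species, .data$site),
                                    quiet = quiet)),
              .groups = "drop")
}

#' Sensitivity of alpha- and beta-diversity to the inclusion criterion
#'
#' Summarises, per criterion, the mean and SD of site richness and of the
#' pairwise dissimilarity indices, the percent change of both relative to
#' the 1-day criterion, the turnover share of total dissimilarity
#' (`beta_SIM / beta_SOR` on the means), and the Spearman rank correlation
#' of site richness with the 1-day ranking (does the criterion re-rank
#' sites?).
#'
#' @param richness Tibble from [richness_table()] or [estimated_richness()]
#'   (columns `site`, `k`, `mode`, `S`).
#' @param beta Tibble from [beta_by_criterion()].
#' @return A tibble with one row per criterion.
#' @export
criterion_sensitivity_summary <- function(richness, beta) {
  site_sets <- richness |>
    group_by(.data$k, .data$mode) |>
    summarise(sites = list(sort(unique(.data$site))), .groups = "drop")
  if (length(unique(vapply(site_sets$sites, paste, "", collapse = "|"))) != 1)
    abort("criteria cover different site sets")
  base <- filter(richness, .data$k == 1)
  if (nrow(base) == 0) abort("richness table lacks the 1-day baseline criterion")
  base <- base |> arrange(.data$site)
  per_crit <- richness |>
    group_by(.data$k, .data$mode) |>
    summarise(S_mean = mean(.data$S), S_sd = sd(.data$S),
              rank_cor_vs_1d = cor(.data$S[order(.data$site)], base$S,
                                   method = "spearman"),
              .groups = "drop")
  beta_sum <- beta |>
    mutate(summary = lapply(.data$beta, function(bp) {
      lt <- lower.tri(bp$sor)
      tibble(beta_sor_mean = mean(bp$sor[lt]), beta_sor_sd = sd(bp$sor[lt]),
             beta_sim_mean = mean(bp$sim[lt]), beta_nes_mean = mean(bp$nes[lt]))
    })) |>
    select("k", "mode", "summary") |>
    tidyr::unnest("summary")
  out <- left_join(per_crit, beta_sum, by = c("k", "mode"))
  s_base <- out$S_mean[out$k == 1][1]
  b_base <- out$beta_sor_mean[out$k == 1][1]
  out |>
    mutate(
      S_pct_change = 100 * (.data$S_mean - s_base) / s_base,
      beta_sor_pct_change = if (is.na(b_base) || b_base == 0) NA_real_
        else 100 * (.data$beta_sor_mean - b_base) / b_base,
      sim_sor_ratio = ifelse(.data$beta_sor_mean > 0,
                             .data$beta_sim_mean / .data$beta_sor_mean, NA_real_)
    ) |>
    arrange(.data$mode, .data$k)
}
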