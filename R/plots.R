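#' Plot daily estimated (and observed) species richness
#'
#' @param daily Tibble from [daily_richness()].
#' @param observed Optional tibble from [observed_daily_richness()].
#' @return A ggplot: per-day distribution of site richness across sites,
#'   estimated vs observed.
#' @export
plot_daily_richness <- function(daily, observed = NULL) {
  df <- daily |> mutate(kind = "estimated") |> rename(value = "S_day")
  if (!is.null(observed)) {
    df <- bind_rows(df, observed |> mutate(kind = "observed") |>
                      rename(value = "S_day_obs"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                   colour = .data$kind,
                                   group = interaction(.data$site, .data$kind))) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::labs(x = "day of season", y = "daily species richness",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot richness as a function of the inclusion criterion
#'
#' @param richness Tibble from [richness_table()], optionally carrying an
#'   `observed_S` column to overlay raw-data richness.
#' @return A ggplot: site richness distributions per criterion and mode.
#' @export
plot_richness_sensitivity <- function(richness) {
  p <- ggplot2::ggplot(richness,
                       ggplot2::aes(x = factor(.data$k), y = .data$S,
                                    fill = .data$mode)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          outlier.size = 0.6) +
    ggplot2::labs(x = "days required for inclusion", y = "species richness",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("observed_S" %in% names(richness)) {
    p <- p + ggplot2::geom_boxplot(
      ggplot2::aes(y = .data$observed_S, fill = NULL),
      data = distinct(richness, .data$k, .data$site, .data$observed_S),
      colour = "grey40", width = 0.2, outlier.size = 0.6
    )
  }
  p
}

#' Plot the beta-diversity partition across criteria
#'
#' @param sensitivity Tibble from [criterion_sensitivity_summary()].
#' @return A ggplot: mean pairwise Sorensen, Simpson and nestedness
#'   dissimilarity as a function of the criterion, by mode.
#' @export
plot_beta_sensitivity <- function(sensitivity) {
  df <- sensitivity |>
    select("k", "mode", sor = "beta_sor_mean", sim = "beta_sim_mean",
           nes = "beta_nes_mean") |>
    tidyr::pivot_longer(c("sor", "sim", "nes"), names_to = "index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$index,
                                   linetype = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "days required for inclusion",
                  y = "mean pairwise dissimilarity",
                  colour = "index", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_siteuse Posterior mean daily occupancy per species,
#'   averaged over sites (one line per species), for the target year.
#' @method autoplot siteuse_fit
#' @export
autoplot.siteuse_fit <- function(object, ...) {
  df <- bind_rows(lapply(names(object$species), function(sp) {
    m <- apply(object$species[[sp]]$traj, 3, mean)
    tibble(species = sp, day = seq_along(m), occupancy = m)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$occupancy,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day of season",
                  y = "posterior mean occupancy (site average)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
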