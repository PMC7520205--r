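#' Configuration of the synthetic citizen-science data generator
#'
#' The generator emulates the statistical structure the site-use analysis
#' assumes: daily colonization--extinction occupancy dynamics per species and
#' site, visit counts per site-day that vary widely and decline towards the
#' end of the season (truncated negative binomial, at most `visit_max`),
#' highly skewed observer thoroughness (by default 60% of visits have a
#' single-species target list), and presence-only reporting: a visit that
#' detects nothing produces no record.
#'
#' @param n_species,n_sites,n_years Community and design dimensions for the
#'   modelled (focal) species.
#' @param n_background Number of background species: ubiquitous, unmodelled
#'   taxa whose reports carry the bulk of each visit's species list, as in
#'   real multi-taxon reporting where any focal subset is embedded in a much
#'   richer reported community. With the default, full lists can reach
#'   `n_species + n_background` = 45 species. Set to 0 for a closed
#'   focal-only community.
#' @param n_days Season length `D` in days.
#' @param visit_mean Mean number of visits per site-day at mid-season.
#' @param visit_trend Log-scale change in mean visit count across the season
#'   (negative values model declining effort; the default halves-to-thirds
#'   effort by the season's end).
#' @param visit_dispersion Negative-binomial size parameter of the visit
#'   count (smaller = more day-to-day variation).
#' @param visit_max Hard cap on visits per site-day (default 40).
#' @param sll_p1 Probability that a visit's target list length is 1.
#' @param sll_tail_mu,sll_tail_size Mean and size of the shifted
#'   negative-binomial tail (values 2 and up) of the target list length.
#' @param sll_max Maximum target list length.
#' @param ranges Named list of length-2 numeric ranges for the species-level
#'   parameters `pmax`, `psi1`, `alpha` (log detection steepness), `eta2`,
#'   `delta`, `b0`, `b1`, `b2` (persistence), `c0`, `c1`, `c2` (colonization).
#' @param sigma Named list of random-effect standard deviations
#'   (`alpha_site`, `phi_site`, `phi_year`, `gamma_site`, `gamma_year`).
#' @param pll_range Range of the true annual proportion-of-long-lists
#'   covariate entering detection steepness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 10L, n_sites = 15L, n_years = 1L,
                       n_background = 35L, n_days = 90L,
                       visit_mean = 5, visit_trend = -1, visit_dispersion = 1.5,
                       visit_max = 40L,
                       sll_p1 = 0.6, sll_tail_mu = 5, sll_tail_size = 1.5,
                       sll_max = 45L,
                       ranges = list(), sigma = list(),
                       pll_range = c(0.05, 0.2)) {
  default_ranges <- list(
    pmax = c(0.4, 0.95), psi1 = c(0.1, 0.6),
    alpha = c(-0.5, 0.5), eta2 = c(-0.5, 0.5), delta = c(0, 1),
    b0 = c(0.5, 3.5), b1 = c(-0.5, 0.5), b2 = c(-0.5, 0.25),
    c0 = c(-4, -1), c1 = c(-0.5, 0.5), c2 = c(-0.5, 0.25)
  )
  default_sigma <- list(alpha_site = 0.3, phi_site = 0.5, phi_year = 0.2,
                        gamma_site = 0.5, gamma_year = 0.2)
  unknown <- setdiff(names(ranges), names(default_ranges))
  if (length(unknown) > 0)
    abort(sprintf("unknown parameter range(s): %s", paste(unknown, collapse = ", ")))
  ranges <- utils::modifyList(default_ranges, ranges)
  sigma <- utils::modifyList(default_sigma, sigma)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || anyNA(r) || r[1] > r[2])
      abort(sprintf("range `%s` must be c(lo, hi) with lo <= hi", nm))
  }
  cfg <- list(
    n_species = assert_scalar_int(n_species, "n_species"),
    n_background = assert_scalar_int(n_background, "n_background", min = 0L),
    n_sites = assert_scalar_int(n_sites, "n_sites"),
    n_years = assert_scalar_int(n_years, "n_years"),
    n_days = assert_scalar_int(n_days, "n_days", min = 2L),
    visit_mean = visit_mean, visit_trend = visit_trend,
    visit_dispersion = visit_dispersion,
    visit_max = assert_scalar_int(visit_max, "visit_max"),
    sll_p1 = sll_p1, sll_tail_mu = sll_tail_mu, sll_tail_size = sll_tail_size,
    sll_max = assert_scalar_int(sll_max, "sll_max"),
    ranges = ranges, sigma = sigma, pll_range = pll_range
  )
  if (cfg$sll_p1 < 0 || cfg$sll_p1 > 1) abort("`sll_p1` must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

sim_species_names <- function(cfg) sprintf("sp%02d", seq_len(cfg$n_species))
sim_background_names <- function(cfg) {
  if (cfg$n_background == 0) character(0)
  else sprintf("bg%02d", seq_len(cfg$n_background))
}
sim_site_names <- function(cfg) sprintf("site%02d", seq_len(cfg$n_sites))
sim_years <- function(cfg) seq(2014L - cfg$n_years + 1L, 2014L)
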