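#' Detection probability as a saturating function of species list length
#'
#' The probability that a present species makes it onto a visit's species
#' list rises with the list length (SLL, the effort proxy) and saturates at a
#' species-level ceiling `pmax`:
#' \deqn{p = p_{max} (1 - e^{-\lambda \cdot SLL}), \quad
#'   \log \lambda = \alpha + \eta + \delta \cdot PLL,}
#' where `alpha` carries the site-level steepness, `eta` the season-half
#' offset (0 in the first half by convention) and `delta` the slope on the
#' annual proportion of long lists.
#'
#' @param sll Integer vector of species list lengths (>= 1).
#' @param pmax Maximum expected detection probability, in (0, 1].
#' @param alpha Site-level log-steepness intercept.
#' @param eta Season-half offset on the log-steepness (default 0).
#' @param delta Slope of log-steepness on PLL (default 0).
#' @param pll Annual proportion of long lists, in \[0, 1\] (default 0).
#' @return Numeric vector of detection probabilities, strictly increasing in
#'   `sll` and bounded by `pmax`.
#' @examples
#' detection_probability(1:5, pmax = 0.8, alpha = log(0.5))
#' @export
detection_probability <- function(sll, pmax, alpha, eta = 0, delta = 0, pll = 0) {
  if (any(sll < 1) || any(sll != as.integer(sll)))
    abort("`sll` must be integers >= 1")
  if (any(pmax <= 0) || any(pmax > 1)) abort("`pmax` must be in (0, 1]")
  if (any(pll < 0) || any(pll > 1)) abort("`pll` must be in [0, 1]")
  lambda <- exp(alpha + eta + delta * pll)
  pmax * (1 - exp(-lambda * sll))
}

# day standardization shared by model and simulator: z spans about [-2, 2]
standardize_day <- function(day, n_days) {
  (day - (n_days + 1) / 2) / (n_days / 4)
}

#' Daily persistence and colonization probabilities
#'
#' The latent occupancy status follows a daily colonization--extinction
#' process: an occupied site stays occupied the next day with persistence
#' probability `phi`, an unoccupied site becomes occupied with colonization
#' probability `gamma`. Both are quadratic in the standardized day of year
#' (so they can rise, fall, or peak within the season) with additive site and
#' year random effects on the logit scale:
#' \deqn{logit(\phi_d) = b_0 + b_1 z_d + b_2 z_d^2 + \epsilon_{site} +
#'   \epsilon_{year}, \quad z_d = \frac{d - (D+1)/2}{D/4}.}
#'
#' @param day Integer vector of departure days, in `[1, D - 1]` (the
#'   transition applies from day `d` to `d + 1`).
#' @param n_days Season length `D`.
#' @param b Numeric length-3 vector `(b0, b1, b2)`: persistence coefficients.
#' @param c Numeric length-3 vector `(c0, c1, c2)`: colonization coefficients.
#' @param phi_site,phi_year,gamma_site,gamma_year Random-effect values added
#'   on the logit scale (defaults 0).
#' @return A tibble with columns `day`, `phi`, `gamma`, both in (0, 1).
#' @examples
#' transition_probabilities(1:89, 90, b = c(2, 0, -0.5), c = c(-3, 0, 0))
#' @export
transition_probabilities <- function(day, n_days, b, c,
                                     phi_site = 0, phi_year = 0,
                                     gamma_site = 0, gamma_year = 0) {
  n_days <- assert_scalar_int(n_days, "n_days", min = 2L)
  if (any(day < 1) || any(day > n_days - 1))
    abort(sprintf("`day` must lie in [1, %d]", n_days - 1))
  stopifnot(length(b) == 3, length(c) == 3)
  z <- standardize_day(day, n_days)
  tibble(
    day = as.integer(day),
    phi = plogis(b[1] + b[2] * z + b[3] * z^2 + phi_site + phi_year),
    gamma = plogis(c[1] + c[2] * z + c[3] * z^2 + gamma_site + gamma_year)
  )
}
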