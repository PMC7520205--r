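#' Marginal log-likelihood of one site-year detection history
#'
#' Computes the log-likelihood of a binary detection history for a single
#' site and year, with the latent daily occupancy trajectory summed out by
#' the two-state forward recursion. Emissions on a day are the product of
#' per-visit Bernoulli terms `y_j ~ Bernoulli(u_d * p_j)`; days without
#' visits are uninformative, and a day with any detection is incompatible
#' with absence.
#'
#' @param day Integer vector: day index (1-based) of each visit.
#' @param y Integer vector (0/1): detection outcome of each visit.
#' @param p Numeric vector: detection probability of each visit given
#'   presence (see [detection_probability()]).
#' @param psi1 Initial occupancy probability on day 1.
#' @param phi,gamma Numeric vectors of length `n_days - 1`: daily persistence
#'   and colonization probabilities (see [transition_probabilities()]).
#' @param n_days Season length `D`.
#' @return The log marginal likelihood (may be `-Inf` for data impossible
#'   under the parameters, e.g. a detection when `psi1 = 0` and `gamma = 0`).
#' @examples
#' forward_loglik(day = integer(0), y = integer(0), p = numeric(0),
#'                psi1 = 0, phi = rep(0.5, 3), gamma = rep(0, 3), n_days = 4)
#' @export
forward_loglik <- function(day, y, p, psi1, phi, gamma, n_days) {
  n_days <- assert_scalar_int(n_days, "n_days", min = 1L)
  check_hmm_args(day, y, p, psi1, phi, gamma, n_days)
  ll <- fw_loglik_cpp(as.integer(day), as.integer(y), as.numeric(p),
                      psi1, as.numeric(phi), as.numeric(gamma), n_days)
  if (is.nan(ll)) abort("non-finite likelihood: check parameter values")
  ll
}

#' Draw latent occupancy trajectories by forward-filtering backward-sampling
#'
#' Produces exact draws from the conditional distribution of the daily
#' occupancy trajectory `u` given the detection history and fixed parameters.
#' Any day with an observed detection necessarily has `u = 1` in every draw.
#' With no visits at all, draws follow the prior occupancy chain.
#'
#' @inheritParams forward_loglik
#' @param n_draws Number of trajectories to draw.
#' @param seed Optional seed for reproducibility.
#' @return An integer matrix with `n_draws` rows and `n_days` columns.
#' @export
ffbs_trajectory <- function(day, y, p, psi1, phi, gamma, n_days,
                            n_draws = 1L, seed = NULL) {
  n_days <- assert_scalar_int(n_days, "n_days", min = 1L)
  n_draws <- assert_scalar_int(n_draws, "n_draws")
  check_hmm_args(day, y, p, psi1, phi, gamma, n_days)
  draw <- function() {
    ffbs_cpp(as.integer(day), as.integer(y), as.numeric(p),
             psi1, as.numeric(phi), as.numeric(gamma), n_days, n_draws)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

check_hmm_args <- function(day, y, p, psi1, phi, gamma, n_days) {
  if (length(day) != length(y) || length(day) != length(p))
    abort("`day`, `y` and `p` must have equal length")
  if (length(day) > 0) {
    if (any(day < 1) || any(day > n_days)) abort("visit `day` outside [1, n_days]")
    assert_binary(y, "y")
    if (any(p < 0) || any(p > 1) || anyNA(p)) abort("`p` must lie in [0, 1]")
  }
  if (psi1 < 0 || psi1 > 1 || is.na(psi1)) abort("`psi1` must lie in [0, 1]")
  if (length(phi) != n_days - 1 || length(gamma) != n_days - 1)
    abort("`phi` and `gamma` must have length `n_days - 1`")
  if (any(phi < 0) || any(phi > 1) || any(gamma < 0) || any(gamma > 1))
    abort("`phi` and `gamma` must lie in [0, 1]")
  invisible(TRUE)
}
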