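# split R-hat and effective sample size (Gelman et al. style), computed on a
# draws matrix with a chain index

split_chains <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n <- length(v)
    h <- n %/% 2
    out <- c(out, list(v[seq_len(h)], v[(n - h + 1):n]))
  }
  out
}

rhat_split <- function(x, chain) {
  halves <- split_chains(x, chain)
  n <- min(lengths(halves))
  if (n < 2) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) {
    # all-constant chains: identical constants are converged by definition
    return(if (isTRUE(all.equal(B, 0))) 1 else NA_real_)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x, chain) {
  chains <- lapply(unique(chain), function(ch) x[chain == ch])
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4) return(NA_real_)
  chains <- lapply(chains, function(v) v[seq_len(n)])
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(m * n)
  means <- vapply(chains, mean, numeric(1))
  B_over_n <- if (m > 1) var(means) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  # mean within-chain autocovariance at each lag
  max_lag <- min(n - 2, 1000L)
  acov <- sapply(chains, function(v) {
    a <- stats::acf(v, lag.max = max_lag, plot = FALSE, type = "covariance")
    as.numeric(a$acf)
  })
  acov <- rowMeans(matrix(acov, ncol = m))
  rho <- 1 - (W - acov[-1]) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  if (npair >= 1) {
    psum <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
    keep <- which(psum <= 0)
    stop_at <- if (length(keep)) keep[1] - 1 else npair
    psum <- psum[seq_len(stop_at)]
    if (length(psum) > 1) psum <- cummin(psum)
    tau <- 1 + 2 * sum(pmax(psum, 0))
  } else tau <- 1
  min(m * n, max(m * n / tau, 1))
}

#' Convergence diagnostics for a site-use fit
#'
#' Computes split R-hat and an autocorrelation-based effective sample size
#' for every parameter of every fitted species, flagging parameters with
#' R-hat above the threshold. Requires at least two chains.
#'
#' @param fit A `siteuse_fit` from [fit_siteuse()].
#' @param rhat_threshold Flagging threshold (default 1.1).
#' @return A tibble `species`, `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence_diagnostics <- function(fit, rhat_threshold = 1.1) {
  stopifnot(inherits(fit, "siteuse_fit"))
  if (fit$mcmc$chains < 2)
    abort("convergence diagnostics require at least 2 chains")
  out <- lapply(names(fit$species), function(sp) {
    draws <- fit$species[[sp]]$draws
    chain <- fit$species[[sp]]$chain
    tibble(
      species = sp,
      parameter = natural_name(fit$param_names),
      rhat = apply(draws, 2, rhat_split, chain = chain),
      ess = apply(draws, 2, ess_basic, chain = chain)
    )
  })
  bind_rows(out) |>
    mutate(flagged = !is.na(.data$rhat) & .data$rhat > rhat_threshold)
}

#' @describeIn fit_siteuse Tidy per-parameter posterior summaries (mean, SD,
#'   central 95% interval, split R-hat, ESS) for every species.
#' @param x,object A `siteuse_fit`.
#' @param ... Unused.
#' @method tidy siteuse_fit
#' @export
tidy.siteuse_fit <- function(x, ...) {
  diag <- convergence_diagnostics_safe(x)
  out <- lapply(names(x$species), function(sp) {
    nat <- natural_transform(x$species[[sp]]$draws, x$param_names)
    tibble(
      species = sp,
      term = colnames(nat),
      estimate = colMeans(nat),
      std.error = apply(nat, 2, sd),
      conf.low = apply(nat, 2, quantile, 0.025, names = FALSE),
      conf.high = apply(nat, 2, quantile, 0.975, names = FALSE)
    )
  })
  out <- bind_rows(out)
  if (!is.null(diag)) {
    out <- left_join(out, select(diag, "species", term = "parameter",
                                 "rhat", "ess"),
                     by = c("species", "term"))
  }
  out
}

convergence_diagnostics_safe <- function(fit) {
  if (fit$mcmc$chains < 2) return(NULL)
  convergence_diagnostics(fit)
}

#' @describeIn fit_siteuse One-row-per-species fit overview: draw counts,
#'   worst R-hat, smallest ESS, number of flagged parameters, mean
#'   Metropolis acceptance rate.
#' @method glance siteuse_fit
#' @export
glance.siteuse_fit <- function(x, ...) {
  diag <- convergence_diagnostics_safe(x)
  out <- lapply(names(x$species), function(sp) {
    spf <- x$species[[sp]]
    d <- if (is.null(diag)) NULL else filter(diag, .data$species == sp)
    tibble(
      species = sp,
      n_draws = nrow(spf$draws),
      n_chains = x$mcmc$chains,
      max_rhat = if (is.null(d)) NA_real_ else max(d$rhat, na.rm = TRUE),
      min_ess = if (is.null(d)) NA_real_ else min(d$ess, na.rm = TRUE),
      n_flagged = if (is.null(d)) NA_integer_ else sum(d$flagged),
      mean_accept = mean(spf$accept_rate)
    )
  })
  bind_rows(out)
}
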