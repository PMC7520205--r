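# Brute-force oracles, independent of the package's forward/FFBS/DP code.

# enumerate all 2^D latent trajectories; returns a list of trajectories with
# their joint probability P(u) * P(y | u)
enumerate_chain <- function(day, y, p, psi1, phi, gamma, D) {
  trajs <- as.matrix(expand.grid(rep(list(0:1), D)))[, D:1, drop = FALSE]
  w <- apply(trajs, 1, function(u) {
    pu <- if (u[1] == 1) psi1 else 1 - psi1
    if (D > 1) {
      for (d in 1:(D - 1)) {
        pu <- pu * if (u[d] == 1) {
          if (u[d + 1] == 1) phi[d] else 1 - phi[d]
        } else {
          if (u[d + 1] == 1) gamma[d] else 1 - gamma[d]
        }
      }
    }
    py <- 1
    if (length(day) > 0) {
      for (v in seq_along(day)) {
        pv <- u[day[v]] * p[v]
        py <- py * if (y[v] == 1) pv else 1 - pv
      }
    }
    pu * py
  })
  list(trajs = trajs, weight = w)
}

enum_loglik <- function(day, y, p, psi1, phi, gamma, D) {
  log(sum(enumerate_chain(day, y, p, psi1, phi, gamma, D)$weight))
}

# exact conditional P(u | y) over all trajectories
enum_conditional <- function(day, y, p, psi1, phi, gamma, D) {
  e <- enumerate_chain(day, y, p, psi1, phi, gamma, D)
  e$weight <- e$weight / sum(e$weight)
  e
}

# exact prior probability that a criterion holds, by enumeration
enum_inclusion <- function(psi1, phi, gamma, D, k, mode) {
  e <- enumerate_chain(integer(0), integer(0), numeric(0), psi1, phi, gamma, D)
  ok <- apply(e$trajs, 1, function(u) {
    if (mode == "nonconsecutive") sum(u) >= k
    else {
      r <- rle(u)
      any(r$values == 1 & r$lengths >= k)
    }
  })
  sum(e$weight[ok])
}

# a random small chain instance with data simulated from the model itself
random_instance <- function(D = sample(2:10, 1), max_visits_per_day = 3) {
  nv_day <- sample(0:max_visits_per_day, D, replace = TRUE)
  day <- rep(seq_len(D), nv_day)
  psi1 <- runif(1)
  phi <- runif(D - 1)
  gamma <- runif(D - 1)
  p <- runif(length(day), 0.05, 0.95)
  u <- numeric(D)
  u[1] <- rbinom(1, 1, psi1)
  if (D > 1) for (d in 1:(D - 1))
    u[d + 1] <- rbinom(1, 1, if (u[d] == 1) phi[d] else gamma[d])
  y <- if (length(day) > 0) rbinom(length(day), 1, u[day] * p) else integer(0)
  list(D = D, day = day, y = y, p = p, psi1 = psi1, phi = phi, gamma = gamma,
       u = u)
}
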