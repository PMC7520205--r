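#' Binarize inclusion probabilities into local species lists
#'
#' The pairwise dissimilarity partition needs binary community data, so each
#' species enters a site's seasonal list only if its posterior inclusion
#' probability under the criterion is strictly above the threshold (a
#' probability of exactly 0.5 is excluded).
#'
#' @param inclusion_table Tibble from [inclusion_probability()].
#' @param threshold Inclusion cut-off (default 0.5, strict).
#' @return A tibble with one row per site and criterion: `site`, `k`,
#'   `mode`, `species` (list-column, possibly empty), `n_species`.
#' @export
binarize <- function(inclusion_table, threshold = 0.5) {
  if (any(inclusion_table$prob < 0) || any(inclusion_table$prob > 1))
    abort("inclusion probabilities must lie in [0, 1]")
  inclusion_table |>
    group_by(.data$site, .data$k, .data$mode) |>
    summarise(
      species = list(sort(.data$species[.data$prob > threshold])),
      .groups = "drop"
    ) |>
    mutate(n_species = vapply(.data$species, length, integer(1)))
}

#' Incidence components of a pair of species lists
#'
#' @param list_a,list_b Character vectors (species sets of two sites).
#' @return Named integer vector `a` (shared), `b` (only in `list_a`),
#'   `c` (only in `list_b`).
#' @examples
#' pairwise_components(c("s1", "s2", "s3"), c("s2", "s3", "s4", "s5"))
#' @export
pairwise_components <- function(list_a, list_b) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  a <- length(intersect(list_a, list_b))
  c(a = a, b = length(list_a) - a, c = length(list_b) - a)
}

beta_indices <- function(a, b, c) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  if (a + b + c == 0) {                      # both lists empty
    return(c(sor = 0, sim = 0, nes = 0))
  }
  if (a == 0 && (b == 0 || c == 0)) {        # one empty, one not
    return(c(sor = 1, sim = 0, nes = 1))
  }
  m <- min(b, c)
  sor <- (b + c) / (2 * a + b + c)
  sim <- if (a + m == 0) 0 else m / (a + m)
  c(sor = sor, sim = sim, nes = sor - sim)
}

#' Pairwise beta-diversity partition (Sorensen / Simpson / nestedness)
#'
#' Computes the three pairwise dissimilarity matrices of the Baselga
#' partition from binary species lists: total dissimilarity
#' \eqn{\beta_{SOR} = (b+c)/(2a+b+c)}, turnover
#' \eqn{\beta_{SIM} = \min(b,c)/(a+\min(b,c))} and the nestedness component
#' \eqn{\beta_{NES} = \beta_{SOR} - \beta_{SIM}}, where `a`, `b`, `c` are the
#' shared and unshared species counts of a site pair. Degenerate pairs are
#' finite by convention: two empty lists give 0 on all three indices; an
#' empty against a non-empty list gives pure nestedness (`sor = 1`,
#' `sim = 0`, `nes = 1`), with a log message when triggered.
#'
#' @param lists Either a named list of character vectors (names = sites) or
#'   a single-criterion tibble from [binarize()].
#' @param quiet Suppress the degenerate-pair message.
#' @return An object of class `beta_pair`: list of symmetric matrices
#'   `sor`, `sim`, `nes` with zero diagonals. Use [tidy()] for a long
#'   per-pair tibble.
#' @examples
#' beta_pair(list(A = c("s1", "s2", "s3"), B = c("s2", "s3", "s4", "s5")))
#' @export
beta_pair <- function(lists, quiet = FALSE) {
  if (is.data.frame(lists)) {
    if (length(unique(paste(lists$k, lists$mode))) > 1)
      abort("`lists` holds several criteria; filter to one before beta_pair()")
    lists <- setNames(lists$species, lists$site)
  }
  n <- length(lists)
  if (n < 2) abort("beta_pair() needs at least 2 sites")
  sites <- names(lists) %||% as.character(seq_len(n))
  sor <- sim <- nes <- matrix(0, n, n, dimnames = list(sites, sites))
  degenerate <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmp <- pairwise_components(lists[[i]], lists[[j]])
      if (cmp["a"] == 0 && (cmp["b"] == 0 || cmp["c"] == 0)) degenerate <- degenerate + 1L
      idx <- beta_indices(cmp["a"], cmp["b"], cmp["c"])
      sor[i, j] <- sor[j, i] <- idx["sor"]
      sim[i, j] <- sim[j, i] <- idx["sim"]
      nes[i, j] <- nes[j, i] <- idx["nes"]
    }
  }
  if (degenerate > 0)
    su_inform("beta_pair: %d degenerate pair(s) with an empty species list",
              degenerate, quiet = quiet)
  structure(list(sor = sor, sim = sim, nes = nes, sites = sites),
            class = "beta_pair")
}

#' @export
print.beta_pair <- function(x, ...) {
  cat(sprintf("<beta_pair> %d sites; mean beta_SOR = %.3f, beta_SIM = %.3f, beta_NES = %.3f\n",
              length(x$sites), mean(x$sor[lower.tri(x$sor)]),
              mean(x$sim[lower.tri(x$sim)]), mean(x$nes[lower.tri(x$nes)])))
  invisible(x)
}

#' @describeIn beta_pair Long tibble of the pairwise indices (one row per
#'   unordered site pair).
#' @param x A `beta_pair`.
#' @param ... Unused.
#' @method tidy beta_pair
#' @export
tidy.beta_pair <- function(x, ...) {
  n <- length(x$sites)
  idx <- which(lower.tri(x$sor), arr.ind = TRUE)
  tibble(
    site_a = x$sites[idx[, 2]], site_b = x$sites[idx[, 1]],
    beta_sor = x$sor[idx], beta_sim = x$sim[idx], beta_nes = x$nes[idx]
  )
}

#' Mean dissimilarity of each site to all others
#'
#' @param x A `beta_pair` object or a single symmetric dissimilarity matrix.
#' @return For a matrix, a tibble `site`, `mean_dissimilarity`; for a
#'   `beta_pair`, a tibble `site`, `beta_sor`, `beta_sim`, `beta_nes` of
#'   per-site means over all other sites.
#' @export
site_mean_dissimilarity <- function(x) {
  one <- function(m) {
    if (nrow(m) < 2) abort("site means need at least 2 sites")
    unname(rowSums(m) / (nrow(m) - 1))
  }
  if (inherits(x, "beta_pair")) {
    tibble(site = x$sites, beta_sor = one(x$sor), beta_sim = one(x$sim),
           beta_nes = one(x$nes))
  } else {
    if (!is.matrix(x) || nrow(x) != ncol(x)) abort("`x` must be a square matrix")
    tibble(site = rownames(x) %||% as.character(seq_len(nrow(x))),
           mean_dissimilarity = one(x))
  }
}
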