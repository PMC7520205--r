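# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one RNG stream per operation: derive a sub-seed from (master seed, op name)
op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op))) %% 99991L
  as.integer((abs(as.integer(seed)) %% 20000L) * 100000L + h)
}

assert_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) || x < min)
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

assert_binary <- function(u, name = "u") {
  if (length(u) == 0) abort(sprintf("`%s` must be non-empty", name))
  if (anyNA(u) || !all(u %in% c(0, 1)))
    abort(sprintf("`%s` must contain only 0 and 1", name))
  as.integer(u)
}

su_inform <- function(..., quiet = FALSE) {
  if (!quiet) inform(sprintf(...), class = "siteuse_log")
}
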