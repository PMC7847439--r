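# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package functions do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Deterministic child seeds (kept under 2^31) derived from a parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_gf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) all(x %in% c(0, 1) | is.na(x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Percentile quantiles with the inverse-ECDF convention (type 1), so that with
# B = 2 replicates the 2.5/97.5 bounds are the min and max.
pct_ci <- function(x, probs = c(0.025, 0.975)) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(c(NA_real_, NA_real_))
  unname(stats::quantile(x, probs = probs, type = 1, names = FALSE))
}
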