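#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' package functions never clobber the global random stream. All stochastic
#' operations in the package take an explicit `seed` and route through this.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for component k of a run seeded with `seed`.
# Keeps results < 2^31 so they remain valid R integers.
sub_seed <- function(seed, k) {
  v <- (as.double(seed) %% 65011) * 31627 + 2654435 * (k %% 700)
  as.integer(v %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

# lower-triangle vectorization used by the permutation statistics
lower_vec <- function(m) m[lower.tri(m)]
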