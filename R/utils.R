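# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never perturb the global random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic integer seed derived from a master seed plus arbitrary integer
# tags. Plain modular arithmetic (exact in doubles, < 2^53) so derived corpora
# are bit-reproducible across platforms; result fits a 32-bit R integer.
derive_seed <- function(master, ...) {
  ks <- c(as.numeric(master), vapply(list(...), as.numeric, 0))
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + abs(k) + 1) %% 2147483629
  }
  as.integer(h)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_invalid("`%s` must be a single finite number in [%g, %g]", name, lower, upper)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
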