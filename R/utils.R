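#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic stream of derived seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(index) * 100003) %%
               2147483629) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
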