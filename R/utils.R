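#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic function takes an explicit integer seed and
## restores the caller's RNG state on exit, so there is no global random state.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic seed splitting: child seed for unit `index` of stage
## `stage` under a base seed.  Kept below 2^31 - 1; arithmetic is exact in
## doubles (< 2^53).  The scheme is documented so any molecule or window can
## be regenerated in isolation.
child_seed <- function(seed, stage, index = 0L) {
  m <- 2147483587
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + as.numeric(stage) * 1000003 + as.numeric(index)) %% m) + 1L
}

stage_index <- function(stage) {
  stages <- c(simulate = 1, segment = 2, lifetimes = 3, globalfit = 4,
              distances = 5, wham = 6, contacts = 7)
  i <- stages[[stage]]
  if (is.null(i)) stop("unknown stage: ", stage)
  i
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

## FNV-1a hash of a deparsed object; used to stamp run reports so a rerun
## with an identical configuration is recognisable.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
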