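#' @keywords internal
"_PACKAGE"

## Seed plumbing -------------------------------------------------------------

# 2^31 - 1; all derived seeds stay below this so they remain valid R integers.
.SEED_MOD <- 2147483647

#' Derive a named RNG substream seed from a global seed
#'
#' A single pipeline seed is expanded into per-stage substreams so that any
#' stage can be re-run in isolation and reproduce its output exactly.
#'
#' @param seed Global integer seed.
#' @param ... Character or integer labels identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% .SEED_MOD
  for (p in parts) {
    if (is.character(p)) {
      for (b in utf8ToInt(paste(p, collapse = "|"))) {
        h <- (h * 131 + b) %% .SEED_MOD
      }
    } else {
      h <- (h * 131 + (as.numeric(p) %% .SEED_MOD)) %% .SEED_MOD
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Small shared helpers ------------------------------------------------------

NUCS <- c("A", "T", "C", "G")
SYNC_COLS <- c("A", "T", "C", "G", "N", "del")

geomean <- function(x) exp(mean(log(x)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
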