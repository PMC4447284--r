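# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; restore afterwards.
# seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus a stage identifier (and an
#' optional replicate index) to a 31-bit integer seed, so that every stage and
#' replicate of a pipeline run has its own independent, reproducible RNG
#' stream.
#'
#' @param master integer master seed.
#' @param stage integer stage identifier.
#' @param i optional replicate index within the stage.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, i = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.double(master) %% m)
  x <- (x * 48271 + 7919 * as.double(stage) + as.double(i) + 1) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(x %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
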