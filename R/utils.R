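# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Generators advertise themselves as pure functions of (config, seed);
# this is what makes that true without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Structured condition helpers: "usage" errors map to CLI exit 2,
# "data" errors to exit 1.
usage_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("goconsensus_usage_error", "goconsensus_error")))
}

data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("goconsensus_data_error", "goconsensus_error")))
}

log_msg <- function(stage, msg, ..., verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(msg, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))
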