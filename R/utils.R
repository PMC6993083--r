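# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Format p-values in scientific notation with 4 significant digits
# (>= 3 required by the report contract).
format_pval <- function(p) {
  formatC(p, format = "e", digits = 3)
}

format_num <- function(x) {
  formatC(x, format = "g", digits = 6)
}
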