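## Internal helpers shared across modules.

## Exponential with the argument clipped to +-700 so that optimizers can
## traverse pathological parameter regions without generating Inf/NaN.
## Clipping is reported once per call via a warning.
clipped_exp <- function(x, warn = TRUE) {
  bad <- !is.na(x) & abs(x) > 700
  if (any(bad)) {
    x[bad] <- sign(x[bad]) * 700
    if (warn) {
      warning("exponent clipped at +-700 for ", sum(bad), " value(s)",
              call. = FALSE)
    }
  }
  exp(x)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
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

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(name, " must be finite and strictly positive")
  }
  invisible(x)
}
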