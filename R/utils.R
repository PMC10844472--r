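# Internal helpers: condition constructors and seeded evaluation.

mrm_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mrmediate_error"), call = call))
}

validation_error <- function(msg) mrm_error(msg, "mrmediate_validation_error")
format_error     <- function(msg) mrm_error(msg, "mrmediate_format_error")
config_error     <- function(msg) mrm_error(msg, "mrmediate_config_error")

empty_instrument_error <- function(msg) {
  mrm_error(msg, "mrmediate_empty_instruments")
}

insufficient_instruments_error <- function(needed, got, method) {
  mrm_error(
    sprintf("%s requires at least %d instruments, got %d", method, needed, got),
    "mrmediate_insufficient_instruments"
  )
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# 95% two-sided normal multiplier used throughout for confidence bounds
Z975 <- stats::qnorm(0.975)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x <= 1
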