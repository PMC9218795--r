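# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field `%s` %s", field, msg),
        class = "hapblup_config_error")
}

check_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_prob <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_config(field, "must be a single number in [0, 1]")
  }
  invisible(as.numeric(x))
}
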