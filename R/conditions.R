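# Condition classes used across the package.  Every user-facing failure is
# signalled with one of these so callers (and the CLI) can map them to exit
# codes without string-matching messages.

grn_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "grnlink_error", "error", "condition")))
}

#' @noRd
stop_parse <- function(msg) grn_error(msg, "grnlink_parse_error")
#' @noRd
stop_structural <- function(msg) grn_error(msg, "grnlink_structural_error")
#' @noRd
stop_usage <- function(msg) grn_error(msg, "grnlink_usage_error")
#' @noRd
stop_config <- function(msg) grn_error(msg, "grnlink_config_error")
#' @noRd
stop_training <- function(msg) grn_error(msg, "grnlink_training_error")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded internals never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_config(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_prob <- function(x, name, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (upper_open) x >= 1 else x > 1))
    stop_config(sprintf("'%s' must be a probability in [0,%s", name,
                        if (upper_open) "1)" else "1]"))
  as.numeric(x)
}
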