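# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Derive a per-subject seed from a master seed; stays below 2^31
#' @noRd
derive_seed <- function(master, index, salt = 0) {
  as.integer((as.double(master) * 1000003 + index * 7919 + salt * 104729) %%
               2147483629)
}

stop_bc <- function(...) stop(..., call. = FALSE)

is_binary <- function(x) all(x %in% c(0L, 1L, 0, 1, TRUE, FALSE))

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_bc(sprintf("'%s' must contain probabilities in [0, 1]", name))
}
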