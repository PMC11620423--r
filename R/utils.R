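`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed
#'
#' Deterministic 32-bit linear-congruential mix used to hand independent seeds
#' to replicates, CV repeats and grid-search arms, so every stochastic unit is
#' reproducible from one master seed regardless of execution order.
#'
#' @param seed master seed (integer-valued scalar).
#' @param index non-negative integer offset distinguishing the child.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, keeps the multiply below 2^53 so doubles stay exact
  s <- (as.numeric(seed) %% m) * 69069 + as.numeric(index) + 1
  as.integer(s %% m)
}

abort_ramanglu <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ramanglu_error"), ...)
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort_ramanglu(
      sprintf("`%s` must be a single integer >= %d, got %s", name, min,
              paste(format(x), collapse = ", ")),
      class = "ramanglu_invalid_params"
    )
  }
  invisible(as.integer(x))
}
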