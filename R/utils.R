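#' @keywords internal
"_PACKAGE"

# Run code under a given RNG seed, restoring the caller's RNG state after.
# All randomness in the package flows through this so that equal seeds give
# bit-identical results without clobbering the user's stream.
with_seed <- function(seed, code) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_sdcae <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sdcae_error")))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_sdcae(sprintf("`%s` must be a single finite number", name),
               "sdcae_validation_error")
  }
  if (positive && x <= 0) {
    stop_sdcae(sprintf("`%s` must be > 0", name), "sdcae_validation_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
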