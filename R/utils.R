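# internal helpers shared across modules

# Run `code` under a fixed seed without disturbing the caller's RNG stream;
# a NULL seed means "use the current stream".
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pf <- function(..., call. = FALSE) stop(..., call. = call.)
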