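#' @keywords internal
"_PACKAGE"

# Internal assertion helpers ------------------------------------------------

stop_dect <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dectbmd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_dect(sprintf("invalid input: '%s' must be finite numeric", what),
              "dectbmd_invalid_input")
  }
  invisible(x)
}

#' Derive a per-stream random seed from one global seed
#'
#' Expands a single global seed into independent substream seeds, one per
#' named stream, so that adding a new stream to a generator never perturbs
#' the draws of existing streams. The mapping is a fixed affine hash into
#' the 32-bit positive integer range.
#'
#' @param seed Integer global seed.
#' @param stream Character stream label (e.g. "bmd", "age").
#' @return A positive integer seed, deterministic in `(seed, stream)`.
#' @export
stream_seed <- function(seed, stream) {
  assert_finite(seed, "seed")
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629 + 1)
}

# Run an expression with a local RNG state so generators are pure functions
# of (params, seed) and never disturb the caller's RNG.
with_stream_seed <- function(seed, stream, expr) {
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
  })
  set.seed(stream_seed(seed, stream))
  expr
}
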