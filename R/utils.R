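#' @keywords internal
"_PACKAGE"

# Classed condition for bad user input: the CLI maps it to exit code 2,
# everything else to 1.
stop_input <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  cond <- structure(
    class = c("mnp_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream; all generators are pure functions of (design, seed) through this.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stop_input("seed must be a single nonnegative integer")
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
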