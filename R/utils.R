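# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "bnpcp_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_input  <- function(msg) abort(msg, "bnpcp_input_error")
abort_format <- function(msg) abort(msg, "bnpcp_format_error")
abort_value  <- function(msg) abort(msg, "bnpcp_value_error")
abort_range  <- function(msg) abort(msg, "bnpcp_range_error")
abort_io     <- function(msg) abort(msg, "bnpcp_io_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# round() in R rounds half to even; overlap percentages are reported half-up.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}
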