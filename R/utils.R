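# Internal helpers shared across modules.

#' @noRd
abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# Derive a reproducible sub-seed for a named simulator stream from the single
# global seed, so that adding one simulator never perturbs the draws of
# another.  Kept well below 2^31.
#' @noRd
stream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((as.integer(seed) %% 1000003L) * 1009L + h)
}

# Evaluate `code` under the stream's seed, restoring the caller's RNG state.
#' @noRd
with_stream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Median of a possibly empty vector, NA rather than error.
#' @noRd
safe_median <- function(x) if (length(x) == 0L) NA_real_ else stats::median(x)
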