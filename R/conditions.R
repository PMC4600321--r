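# Structured error conditions so callers (and the command-line front end) can
# map failure modes to exit codes.

rnq_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rnq_error")))
}

abort_validation <- function(msg) rnq_abort(msg, "rnq_validation_error")
abort_parse <- function(msg) rnq_abort(msg, "rnq_parse_error")
abort_io <- function(msg) rnq_abort(msg, "rnq_io_error")
abort_size <- function(msg) rnq_abort(msg, "rnq_size_error")
abort_null_model <- function(msg) rnq_abort(msg, "rnq_null_model_error")
abort_stale_index <- function(msg) rnq_abort(msg, "rnq_stale_index_error")
abort_build <- function(msg) rnq_abort(msg, "rnq_build_error")
abort_config <- function(msg) rnq_abort(msg, "rnq_config_error")

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
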