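# Internal helpers: classed errors for the CLI exit-code contract and
# seed scoping that does not disturb the caller's RNG state.

stop_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("episurv_input_error", "error"),
                      call = call))
}

stop_stat <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("episurv_stat_error", "error"),
                      call = call))
}

# Evaluate `expr` under `seed` (if non-NULL), restoring the global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fixed 6-significant-digit formatting used by all TSV writers so that
# repeated writes of the same object are byte-identical.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
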