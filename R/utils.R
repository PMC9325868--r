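# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls do not perturb user RNG.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# classed conditions so callers can distinguish structural failures
archie_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "archie_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# explicit empty-matrix condition: filters that leave nothing must not
# silently succeed
abort_empty <- function(msg) archie_abort(msg, "archie_empty")

# chromosome labels compared as normalized strings: strip any "chr" prefix,
# case-insensitive
normalize_chrom <- function(x) {
  toupper(sub("^[Cc][Hh][Rr]", "", trimws(as.character(x))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_scalar <- function(x, what) {
  if (!is_scalar_number(x)) {
    archie_abort(sprintf("`%s` must be a single finite number", what),
                 "archie_bad_argument")
  }
  invisible(x)
}

# p-values of 0 under a plain M-resample estimator mean "< 1/M"
format_resampled_p <- function(p, M) {
  ifelse(p == 0, sprintf("< %.3g", 1 / M), sprintf("%.4g", p))
}
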