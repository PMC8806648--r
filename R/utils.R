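# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_itaemt <- function(msg, class = "itaemt_error") {
  rlang::abort(msg, class = c(class, "itaemt_error"))
}

# scoped seeding: derive a stream from (seed, offset) without letting callers'
# RNG state leak in or out; offsets keep sub-generators independent so e.g.
# adding genes never perturbs the clinical draws
with_stream <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  set.seed((as.double(seed) + offset) %% 2147483647)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort_itaemt(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(lower), format(upper)))
  }
  invisible(x)
}
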