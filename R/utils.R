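# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Check a single value is a finite numeric scalar in [lo, hi].
#' @noRd
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         strict_lo = FALSE, strict_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("'%s' must be a finite numeric scalar", name)
  }
  ok_lo <- if (strict_lo) x > lo else x >= lo
  ok_hi <- if (strict_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop_config("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                if (strict_lo) "(" else "[", lo, hi,
                if (strict_hi) ")" else "]")
  }
  invisible(x)
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  check_scalar(x, name, lo = min)
  if (x != round(x)) stop_config("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# Deterministic sub-stream seed: one seeded generator per call, with
# per-unit (gene/protein) sub-streams so adding units never perturbs the
# draws of existing ones.  Arithmetic kept in doubles below 2^31.
#' @noRd
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483646 + 1)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
#' @noRd
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}
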