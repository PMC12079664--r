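# Internal validation helpers shared across modules.

stop_not <- function(ok, msg, ...) {
  if (!isTRUE(ok)) rlang::abort(sprintf(msg, ...), class = "medsift_error")
  invisible(TRUE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  stop_not(is.numeric(x) && length(x) == 1L && is.finite(x),
           "`%s` must be a single finite number", name)
  if (strict_lower) {
    stop_not(x > lower, "`%s` must be > %g", name, lower)
  } else {
    stop_not(x >= lower, "`%s` must be >= %g", name, lower)
  }
  stop_not(x <= upper, "`%s` must be <= %g", name, upper)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  stop_not(is.numeric(x) && length(x) == 1L && is.finite(x) &&
             x == round(x) && x >= min,
           "`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

# Local RNG scope: runs `expr` under `seed` without disturbing the caller's
# RNG stream. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stop_not(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
           "`seed` must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Benjamini-Hochberg via stats::p.adjust, kept in one place.
bh_adjust <- function(p) p.adjust(p, method = "BH")
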