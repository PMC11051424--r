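#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic generators in the package go
# through this so that cohort simulation is reproducible without clobbering the
# user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a root seed and a stage/participant label.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  raw <- utf8ToInt(labels)
  h <- 0
  for (v in raw) h <- (h * 31 + v) %% 2147483629
  as.integer(h + 1)
}

ppg_log <- function(..., verbose = getOption("ppghrv.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[ppghrv] ", ...)
  invisible(NULL)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# linear trapezoid integral of y(x)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
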