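#' @importFrom stats rnorm sd
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so simulations never leak into user sessions.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multiplicative noise factors: normal around 1 with the requested
# coefficient of variation, redrawn until strictly positive so intensities
# stay > 0. At realistic CVs (< 0.3) truncation is a < 2e-4 tail event and
# the sample CV is not measurably biased.
rPositiveFactor <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  f <- rnorm(n, mean = 1, sd = cv)
  bad <- which(f <= 0)
  while (length(bad) > 0L) {
    f[bad] <- rnorm(length(bad), mean = 1, sd = cv)
    bad <- bad[f[bad] <= 0]
  }
  f
}

assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

assertColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
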