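BASES <- c("A", "C", "G", "T")

#' Complement of a DNA base vector
#' @param x character vector of bases (A/C/G/T)
#' @return complemented character vector
#' @keywords internal
complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

# Deterministic per-module substream seed derived from one master seed.
# Kept strictly below 2^31 so set.seed() always accepts it.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587 + 1)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
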