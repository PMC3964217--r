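# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# Sliding-window sum of an integer/numeric vector x: out[i] = sum of x over
# indices [i - before, i + after - 1] clipped to the vector. Used for the
# 100-bp spacing windows and the 145-bp peak windows.
window_sum <- function(x, before, after) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after - 1L, n)
  cs[hi + 1L] - cs[lo]
}

# Restore-safe RNG scoping: evaluate expr under set.seed(seed) when seed is
# non-NULL, leaving the caller's RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count1 <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

# Character-level reverse complement (IUPAC-aware); avoids S4 dispatch in
# hot loops.
revcomp_chr <- function(s) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s)
  vapply(comp, function(z)
    paste(rev(strsplit(z, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}
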