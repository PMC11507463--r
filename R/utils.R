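# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded helpers compose deterministically.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and stream offsets; stays < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 7919 + p + 1) %% 2147483629
  as.integer(s + 1)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row ranges of each chromosome in a sorted marker panel; cached on the panel.
chrom_bounds <- function(panel) {
  cb <- attr(panel, "chrom_bounds")
  if (!is.null(cb)) return(cb)
  r <- rle(panel$chrom)
  hi <- cumsum(r$lengths)
  data.frame(chrom = r$values, lo = hi - r$lengths + 1L, hi = hi)
}

# Maximal runs of markers within [lo, hi] delimited by `breaks` (indices of
# sites excluded from any run).  Returns a 2-column matrix (start, end).
runs_between <- function(breaks, lo, hi) {
  b <- c(lo - 1L, breaks, hi + 1L)
  starts <- b[-length(b)] + 1L
  ends <- b[-1L] - 1L
  keep <- ends >= starts
  cbind(start = starts[keep], end = ends[keep])
}
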