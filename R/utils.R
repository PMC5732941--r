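# shared internal helpers: classed conditions, argument recycling, logging

c3d_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "c3d_error", "error", "condition")))
}

# recycle a scalar to a per-axis (z, y, x) triple
as_triple <- function(x, what) {
  if (length(x) == 1L) x <- rep(as.numeric(x), 3L)
  if (length(x) != 3L || !is.numeric(x) || anyNA(x))
    c3d_stop("c3d_error_config", "'%s' must be a scalar or a length-3 (z, y, x) vector", what)
  as.numeric(x)
}

c3d_log <- function(quiet, msg, ...) {
  if (!isTRUE(quiet)) message(sprintf(msg, ...))
}

# smallest integer >= n with no prime factor larger than 5 (fast FFT length)
next_fast_size <- function(n) {
  n <- as.integer(n)
  if (n <= 2L) return(2L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}
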