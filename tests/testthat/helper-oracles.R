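# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# deterministic random volume
rand_vol <- function(dims, seed, lo = 0, hi = 100) {
  set.seed(seed)
  volume(array(runif(prod(dims), lo, hi), dim = dims))
}

# random smooth volume: white noise blurred by a separable moving average
# (reflected ends), rescaled to [0, 100]; smooth enough to have far fewer
# maxima than voxels
blur_axis <- function(x, axis, k) {
  d <- dim(x)
  w <- rep(1 / k, k)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  m <- apply(m, 2, function(v) {
    ext <- c(rev(v[seq_len(k)]), v, rev(v)[seq_len(k)])
    as.numeric(stats::filter(ext, w, sides = 2))[(k + 1):(k + length(v))]
  })
  aperm(array(m, dim = d[perm]), order(perm))
}

smooth_vol <- function(dims, seed, k = 5) {
  set.seed(seed)
  x <- array(rnorm(prod(dims)), dim = dims)
  for (ax in 1:3) x <- blur_axis(x, ax, k)
  x <- x - min(x)
  volume(100 * x / max(x))
}

# brute-force count of 6-connected regional maxima of the positive support.
# Assumes no tied neighboring values (true for continuous random volumes);
# plateau semantics are exercised by dedicated small fixtures instead.
brute_maxima_count <- function(x) {
  if (inherits(x, "volume3d")) x <- x$data
  d <- dim(x)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- x
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  shift <- function(dz, dy, dx)
    pad[2:(d[1] + 1) + dz, 2:(d[2] + 1) + dy, 2:(d[3] + 1) + dx]
  is_max <- ctr > 0 &
    ctr > shift(-1, 0, 0) & ctr > shift(1, 0, 0) &
    ctr > shift(0, -1, 0) & ctr > shift(0, 1, 0) &
    ctr > shift(0, 0, -1) & ctr > shift(0, 0, 1)
  sum(is_max)
}

# exhaustive maximum-cardinality one-to-one matching (small point sets)
brute_match_count <- function(det, tru, tol) {
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0L)
  d2 <- outer(det[, 1], tru[, 1], "-")^2 + outer(det[, 2], tru[, 2], "-")^2 +
    outer(det[, 3], tru[, 3], "-")^2
  ok <- d2 <= tol^2
  best <- 0L
  rec <- function(i, used, cnt) {
    if (cnt + (nd - i + 1L) <= best) return()
    if (i > nd) { best <<- max(best, cnt); return() }
    rec(i + 1L, used, cnt)
    for (t in which(ok[i, ] & !used)) {
      used[t] <- TRUE
      rec(i + 1L, used, cnt + 1L)
      used[t] <- FALSE
    }
  }
  rec(1L, logical(nt), 0L)
  best
}

# sampled, sum-normalized difference-of-Gaussians kernel on a centered grid
# (the band-pass filter's definition, built independently)
dog_kernel <- function(n, sigma_low, sigma_high) {
  g1 <- function(s) {
    off <- seq_len(n) - (n %/% 2 + 1)
    w <- exp(-off^2 / (2 * s^2))
    w / sum(w)
  }
  k3 <- function(s) outer(outer(g1(s[1]), g1(s[2])), g1(s[3]))
  k3(rep(sigma_low, 3)) - k3(rep(sigma_high, 3))
}

# noise-free samples of a 3D Gaussian blob on integer offsets within a ball
gauss_samples <- function(sigma, amplitude = 100, radius = 7) {
  g <- seq(-radius, radius)
  off <- as.matrix(expand.grid(z = g, y = g, x = g))
  off <- off[rowSums(off^2) <= radius^2, ]
  Ainv <- if (is.matrix(sigma)) solve(sigma) else diag(1 / sigma^2)
  q <- rowSums((off %*% Ainv) * off)
  list(offsets = off, intensity = amplitude * exp(-q / 2))
}

# a tiny hand-built segment object (bypasses watershed)
make_segment <- function(voxels, peak, label = 1L, dims) {
  lin <- voxels[, 1] + dims[1] * (voxels[, 2] - 1 + dims[2] * (voxels[, 3] - 1))
  structure(list(label = label, peak = peak, size = nrow(voxels),
                 voxels = voxels, lin = lin), class = "segment3d")
}
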