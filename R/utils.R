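# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
# two-pass lower-envelope algorithm). `inside` is a logical matrix; returns,
# for every pixel, the squared distance to the nearest pixel OUTSIDE the
# region, with everything beyond the image border counted as outside.
edt_sq <- function(inside) {
  nx <- nrow(inside)
  ny <- ncol(inside)
  big <- (nx + ny + 2)^2
  # 1-D squared EDT of a sampled function f (distance to minima of f)
  edt1d <- function(f) {
    n <- length(f)
    d <- numeric(n)
    v <- integer(n)
    z <- numeric(n + 1L)
    k <- 1L
    v[1L] <- 1L
    z[1L] <- -Inf
    z[2L] <- Inf
    for (q in 2:n) {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      while (s <= z[k]) {
        k <- k - 1L
        s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1L] < q) k <- k + 1L
      d[q] <- (q - v[k])^2 + f[v[k]]
    }
    d
  }
  # stage 1: per column, distance to outside along rows, with virtual
  # outside pixels just beyond both borders
  g <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    f <- c(0, ifelse(inside[, j], big, 0), 0)
    g[, j] <- edt1d(f)[2:(nx + 1L)]
  }
  d <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    f <- c(0, g[i, ], 0)
    d[i, ] <- edt1d(f)[2:(ny + 1L)]
  }
  d
}

# Generate a zero-mean band-limited series on the volume time grid as a sum
# of random-phase sinusoids on the DFT frequency bins inside [band1, band2].
# Power is exactly confined to those bins when sampled at t = (0:(n-1))*tr.
band_limited_series <- function(n, tr, band, n_draw = 1L) {
  df <- 1 / (n * tr)
  j <- seq_len(floor(n / 2) - 1L)
  f <- j * df
  keep <- f >= band[1] - 1e-12 & f <= band[2] + 1e-12
  if (!any(keep)) {
    stopf("signal band [%g, %g] Hz contains no resolvable frequency", band[1], band[2])
  }
  f <- f[keep]
  t <- (seq_len(n) - 1) * tr
  out <- matrix(0, n, n_draw)
  for (k in seq_len(n_draw)) {
    phi <- runif(length(f), 0, 2 * pi)
    x <- rowSums(cos(outer(t, 2 * pi * f) + matrix(phi, n, length(f), byrow = TRUE)))
    out[, k] <- x
  }
  out
}

# Gram-Schmidt orthonormalisation with respect to the sample (centred) inner
# product: columns come back demeaned, pairwise orthogonal, unit sample sd.
orthonormalize_series <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  n <- nrow(x)
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    if (k > 1L) {
      prev <- x[, seq_len(k - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v) / (n - 1)
    }
    s <- sd(v)
    if (s < 1e-12) stopf("degenerate component basis (column %d)", k)
    x[, k] <- v / s
  }
  x
}

# round-half-up to integer (matches how percentages are reported)
round_half_up <- function(x) floor(x + 0.5)

# lag-1 sample autocorrelation
lag1_autocor <- function(x) {
  x <- x - mean(x)
  den <- sum(x * x)
  if (den <= 0) return(0)
  sum(x[-length(x)] * x[-1L]) / den
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
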