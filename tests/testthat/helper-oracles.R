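# Shared fixtures and brute-force oracles. All fixtures are generated in
# code; oracles are deliberately naive implementations kept independent of
# the package's algorithms.

# a small, fast phantom configuration for unit tests (any field can be
# overridden)
tiny_config <- function(...) {
  args <- list(grid = 32L, n_slices = 1L, n_volumes = 60L, seed = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

# brute-force binary erosion: a pixel survives iff the whole discrete disk
# around it fits inside the mask (image border counts as background)
erode_oracle <- function(mask, radius) {
  nx <- nrow(mask)
  ny <- ncol(mask)
  off <- expand.grid(i = -floor(radius):floor(radius),
                     j = -floor(radius):floor(radius))
  off <- off[off$i^2 + off$j^2 <= radius^2, ]
  out <- matrix(FALSE, nx, ny)
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!mask[x, y]) next
      ok <- TRUE
      for (k in seq_len(nrow(off))) {
        xi <- x + off$i[k]
        yj <- y + off$j[k]
        if (xi < 1 || xi > nx || yj < 1 || yj > ny || !mask[xi, yj]) {
          ok <- FALSE
          break
        }
      }
      out[x, y] <- ok
    }
  }
  out
}

# recursive flood-fill connected-component labelling (depth-first),
# independent of the package's breadth-first implementation
floodfill_oracle <- function(mask, connectivity = "face3d") {
  dm <- dim(mask)
  offs <- if (connectivity == "face3d") {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, 0))[-5, ]
  }
  labels <- array(0L, dm)
  lab <- 0L
  fill <- function(x, y, z) {
    stack <- list(c(x, y, z))
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (v[1] < 1 || v[1] > dm[1] || v[2] < 1 || v[2] > dm[2] ||
          v[3] < 1 || v[3] > dm[3]) next
      if (!mask[v[1], v[2], v[3]] || labels[v[1], v[2], v[3]] != 0L) next
      labels[v[1], v[2], v[3]] <<- lab
      for (o in seq_len(nrow(offs))) {
        stack[[length(stack) + 1L]] <- v + offs[o, ]
      }
    }
  }
  for (z in seq_len(dm[3])) {
    for (y in seq_len(dm[2])) {
      for (x in seq_len(dm[1])) {
        if (mask[x, y, z] && labels[x, y, z] == 0L) {
          lab <- lab + 1L
          fill(x, y, z)
        }
      }
    }
  }
  labels
}

# exhaustive signed-rank two-sided p-value over all 2^n sign assignments
signed_rank_oracle <- function(values, tails = 2) {
  v <- values[values != 0]
  n <- length(v)
  rk <- rank(abs(v))
  w_obs <- sum(rk[v > 0])
  mu <- sum(rk) / 2
  count <- 0L
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code))[seq_len(n)]
    w <- sum(rk[signs == 1L])
    hit <- if (tails == 2) {
      abs(w - mu) >= abs(w_obs - mu) - 1e-9
    } else {
      w >= w_obs - 1e-9
    }
    if (hit) count <- count + 1L
  }
  count / 2^n
}

# running-median oracle with nearest replication
median_filter_oracle <- function(x, window) {
  n <- length(x)
  h <- (window - 1) %/% 2
  sapply(seq_len(n), function(i) {
    idx <- pmin(pmax((i - h):(i + h), 1), n)
    median(x[idx])
  })
}

# do two label arrays describe the same partition (up to renaming)?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  pos <- which(a > 0)
  if (!length(pos)) return(TRUE)
  key <- paste(a[pos], b[pos])
  length(unique(key)) == length(unique(a[pos])) &&
    length(unique(key)) == length(unique(b[pos]))
}
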