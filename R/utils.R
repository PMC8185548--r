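# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards: all generator randomness flows through an
# explicit per-call seed and never touches global random state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
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
  expr
}

# population standard deviation (divisor n, not n-1)
popSd <- function(x) sqrt(mean((x - mean(x))^2))

# offsets (dr, dc) of a Euclidean disk of radius r (pixel centres at
# distance <= r); r = 1 gives the 5-pixel plus shape
discOffsets <- function(r) {
  r <- as.integer(ceiling(r))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

# 8-connectivity labelling of a logical matrix by iterative minimum-label
# propagation (vectorised; converges in O(component diameter) sweeps)
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (d in list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1),
                   c(0,1), c(1,-1), c(1,0), c(1,1))) {
      s <- shift(lab, d[1], d[2])
      take <- mask & s > 0L & (new == 0L | s < new)
      new[take] <- s[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compress to 1..n
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) {
    lut <- integer(max(u)); lut[u] <- seq_along(u)
    lab[lab > 0L] <- lut[lab[lab > 0L]]
  }
  lab
}

# Greedy non-maximum suppression: keep candidate pixels (linear indices,
# with heights) at pairwise Euclidean distance >= minDist; strongest first,
# ties broken by linear index for determinism.
suppressMaxima <- function(idx, height, nr, minDist) {
  o <- order(-height, idx)
  idx <- idx[o]
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  keep <- logical(length(idx))
  for (i in seq_along(idx)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (r[i] - r[keep])^2 + (c[i] - c[keep])^2
    if (all(d2 >= minDist^2)) keep[i] <- TRUE
  }
  sort(idx[keep])
}
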