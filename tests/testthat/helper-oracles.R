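# Independent oracles: deliberately naive implementations (brute-force
# loops, exhaustive enumeration) kept separate from the code paths they
# check.

# Brute-force per-cell quantifier: builds each cell's dense weight matrix
# from its own disc-dilation and cover counting, then loops over pixels.
oracleQuantify <- function(I, labels, ringRadiusPx, b) {
  nr <- nrow(I); nc <- ncol(I)
  n <- max(labels)
  terr <- vector("list", n)
  off <- expand.grid(dr = -ceiling(ringRadiusPx):ceiling(ringRadiusPx),
                     dc = -ceiling(ringRadiusPx):ceiling(ringRadiusPx))
  off <- off[off$dr^2 + off$dc^2 <= ringRadiusPx^2 + 1e-9, ]
  for (k in seq_len(n)) {
    t_k <- matrix(FALSE, nr, nc)
    idx <- which(labels == k)
    for (i in idx) {
      r0 <- (i - 1L) %% nr + 1L
      c0 <- (i - 1L) %/% nr + 1L
      rr <- r0 + off$dr; cc <- c0 + off$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      t_k[cbind(rr[ok], cc[ok])] <- TRUE
    }
    terr[[k]] <- t_k
  }
  cover <- Reduce(`+`, lapply(terr, function(m) m * 1L), matrix(0L, nr, nc))
  raw <- corrected <- area <- numeric(n)
  for (k in seq_len(n)) {
    for (i in which(terr[[k]])) {
      w <- 1 / cover[i]
      raw[k] <- raw[k] + w * I[i]
      corrected[k] <- corrected[k] + w * (I[i] - b)
      area[k] <- area[k] + w
    }
  }
  list(raw = raw, corrected = corrected, area = area, cover = cover)
}

# Exhaustive hypergeometric enumeration of the probability-mass two-sided
# Fisher p-value (same 1e-7 relative slack on the <= comparison).
oracleFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(support, r1, r2, c1)
  pobs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Exhaustive enumeration over all C(m+n, m) group assignments of the
# pooled sample: exact two-sided Mann-Whitney p as twice the smaller tail.
oracleMWP <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  u <- sum(rank(pool)[seq_len(m)]) - m * (m + 1) / 2
  picks <- utils::combn(m + n, m)
  Uall <- apply(picks, 2L, function(ix) {
    sum(rank(pool)[ix]) - m * (m + 1) / 2
  })
  min(1, 2 * min(mean(Uall <= u), mean(Uall >= u)))
}

# Hand ECDF walk for the two-sample KS statistic.
oracleKSD <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  dmax <- 0
  for (t in grid) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > dmax) dmax <- d
  }
  dmax
}

# Convenience: run segmentation + territories + quantification on a scene
# with the scene's own ring width.
quantifyScene <- function(sc, ringRadiusPx = 17, background = NULL) {
  lm <- segmentNuclei(sc$hoechst)
  if (nCells(lm) == 0L) return(NULL)
  ts <- buildTerritories(lm, ringRadiusPx = ringRadiusPx)
  b <- if (is.null(background)) estimateBackground(sc$pla, ts) else background
  list(labels = lm, territories = ts, b = b,
       cells = quantifyCells(sc$pla, ts, b))
}
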