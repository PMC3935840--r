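# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Brute-force flood fill over a 3-D integer grid (0 = background) with a
# queue-based BFS in pure R. Returns data.frame(level, size), one row per
# zone, unordered.
floodFillOracle <- function(levels, offsets) {
  d <- dim(levels)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (levels[i, j, k] == 0L || seen[i, j, k]) next
    lev <- levels[i, j, k]
    queue <- matrix(c(i, j, k), ncol = 3)
    seen[i, j, k] <- TRUE
    size <- 0L
    while (nrow(queue) > 0) {
      v <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (o in seq_len(nrow(offsets))) {
        w <- v + offsets[o, ]
        if (any(w < 1) || any(w > d)) next
        if (!seen[w[1], w[2], w[3]] && levels[w[1], w[2], w[3]] == lev) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue <- rbind(queue, w)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  z <- do.call(rbind, zones)
  data.frame(level = z[, 1], size = z[, 2])
}

offsets26 <- {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}
offsets6 <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                  c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

# GLSZM as a plain matrix from an oracle zone list
glszmOracle <- function(zones, L) {
  smax <- max(zones$size)
  M <- matrix(0, L, smax)
  for (r in seq_len(nrow(zones)))
    M[zones$level[r], zones$size[r]] <- M[zones$level[r], zones$size[r]] + 1
  M
}

# Mann-Whitney two-sided p by full enumeration of group assignments,
# counting pairwise wins directly (no rank formula).
mwEnumOracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  N <- length(pooled)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  uObs <- uStat(x, y)
  devObs <- abs(2 * uObs - m * (N - m))
  idx <- utils::combn(N, m)
  hits <- 0L
  for (c in seq_len(ncol(idx))) {
    a <- pooled[idx[, c]]
    b <- pooled[-idx[, c]]
    if (abs(2 * uStat(a, b) - m * (N - m)) >= devObs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(idx)
}

# Fisher two-sided p by explicit hypergeometric enumeration over all tables
# with the observed margins.
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  aRange <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(aRange, c1, N - c1, r1)
  pObs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# AUC as brute-force pairwise concordance (ties count one half).
aucBruteOracle <- function(scores, responder, direction) {
  s <- if (direction == "lower") -scores else scores
  sr <- s[responder]; sn <- s[!responder]
  cmp <- outer(sr, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct-moment oracle for standardized moments (explicit loops, no reuse
# of package helpers).
momentOracle <- function(x, k) {
  mu <- sum(x) / length(x)
  tot <- 0
  for (v in x) tot <- tot + (v - mu)^k
  tot / length(x)
}
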