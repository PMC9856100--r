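# Shared fixtures, all generated in code.

# compact phantom for unit tests (fast); geometry scaled down from the
# default 256 x 256 spec
smallSpec <- function(noiseSd = 0, seed = 1L, jitter = 0) {
  phantomSpec(dim = c(96L, 96L), outerSemiAxes = c(14, 20),
              notchSemiAxes = c(8, 7), notchOffset = c(-14, 0),
              noiseSd = noiseSd, semiAxisJitter = jitter, seed = seed)
}

smallPrior <- function(n = 10, seed = 5L) {
  spec <- smallSpec(jitter = 0.1, seed = seed)
  buildShapePrior(lapply(generateTrainingCohort(n, spec), function(m) m * 1))
}

# analytically smooth fields on an n x n grid for gradient-oracle tests:
# everything C^1 so the only discretization left is the interpolation
smoothCase <- function(n = 64) {
  cx <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), n), n, n)
  r <- sqrt((x - cx)^2 + (y - cx)^2)
  PK <- 0.02 + 0.96 / (1 + exp((r - 14) / 3))
  prior <- methods::new("ShapePriorModel", PK = PK, PB = 1 - PK,
                        phiPK = 14 - sqrt((x - cx)^2 + (y - cx)^2 + 9),
                        N = 30L, beta = 1)
  phi <- pmin(pmax(12 - sqrt((x - cx - 2)^2 + (y - cx + 1)^2 + 4),
                   -1.4), 1.4)
  img <- 100 / (1 + exp((r - 13) / 2.5)) + 50
  mem <- updateMemberships(img, 145, 55)
  list(n = n, center = c(cx, cx), prior = prior, phi = phi,
       mK = mem$mK, mB = mem$mB)
}

# brute-force 95th-percentile boundary distance (independent of the
# distance-transform implementation)
bruteHd95 <- function(a, b) {
  bnd <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    idx <- which(m, arr.ind = TRUE)
    keep <- apply(idx, 1, function(p) {
      i <- p[1]; j <- p[2]
      i == 1 || i == nr || j == 1 || j == nc ||
        !(m[i - 1, j] && m[i + 1, j] && m[i, j - 1] && m[i, j + 1])
    })
    idx[keep, , drop = FALSE]
  }
  pa <- bnd(a); pb <- bnd(b)
  dmin <- function(p, q) {
    apply(p, 1, function(v) sqrt(min((q[, 1] - v[1])^2 + (q[, 2] - v[2])^2)))
  }
  stats::quantile(c(dmin(pa, pb), dmin(pb, pa)), 0.95, names = FALSE)
}
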