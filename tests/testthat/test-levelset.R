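test_that("smeared Heaviside matches its closed form and is monotone", {
  eps <- 1.5
  expect_equal(smearedHeaviside(2 * eps, eps), 1)
  expect_equal(smearedHeaviside(-2 * eps, eps), 0)
  expect_equal(smearedHeaviside(0, eps), 0.5)
  # middle branch at phi = eps/2: 1/2 + 1/4 + sin(pi/2)/(2 pi)
  expect_equal(smearedHeaviside(eps / 2, eps), 0.75 + 1 / (2 * pi))
  expect_equal(smearedHeaviside(-eps / 2, eps), 0.25 - 1 / (2 * pi))
  # continuity at the band edges
  expect_equal(smearedHeaviside(eps, eps), 1, tolerance = 1e-12)
  expect_equal(smearedHeaviside(-eps, eps), 0, tolerance = 1e-12)
  # monotone nondecreasing
  phi <- seq(-4, 4, by = 0.001)
  expect_true(all(diff(smearedHeaviside(phi, eps)) >= -1e-14))
  expect_error(smearedHeaviside(0, -1), "positive")
})

test_that("smeared Dirac is the derivative of the Heaviside and integrates to 1", {
  eps <- 1.5
  expect_equal(smearedDirac(2 * eps, eps), 0)
  expect_equal(smearedDirac(0, eps), 1 / eps)
  h <- 1e-3
  phi <- seq(-2.5, 2.5, by = h)
  num <- diff(smearedHeaviside(phi, eps)) / h
  mid <- phi[-1] - h / 2
  expect_equal(smearedDirac(mid, eps), num, tolerance = 1e-5)
  # quadrature over the band
  expect_equal(sum(smearedDirac(phi, eps)) * h, 1, tolerance = 1e-3)
  expect_error(smearedDirac(0, 0), "positive")
})

test_that("curvature is zero for planes/constants and 1/r on a circle", {
  g <- expand.grid(y = 1:41, x = 1:41)
  plane <- matrix(0.3 * g$x + 0.7 * g$y, 41, 41)
  k <- curvatureField(plane)
  expect_lt(max(abs(k[3:39, 3:39])), 1e-8)
  expect_equal(curvatureField(matrix(5, 10, 10)), matrix(0, 10, 10))
  r0 <- 12
  phi <- matrix(r0 - sqrt((g$x - 21)^2 + (g$y - 21)^2), 41, 41)
  k <- curvatureField(phi)
  near <- abs(phi) < 1 & abs(phi) > 0.2
  # analytic curvature of the level sets of a signed distance to a circle
  expect_equal(mean(-k[near]), 1 / r0, tolerance = 0.1)
  expect_error(curvatureField(matrix(0, 2, 2)), "3 x 3")
})

test_that("level-set initialization produces the requested geometry", {
  phi <- initializeLevelSet(c(48L, 48L), "disk", center = c(24, 24),
                            radius = 10)
  g <- expand.grid(y = 1:48, x = 1:48)
  r <- matrix(sqrt((g$x - 24)^2 + (g$y - 24)^2), 48, 48)
  expect_true(all(phi[r < 9] > 0))
  expect_true(all(phi[r > 11] < 0))
  phi <- initializeLevelSet(c(48L, 48L), "border", margin = 4)
  expect_true(all(phi[c(1:4, 45:48), ] <= 0))
  expect_true(all(phi[20:28, 20:28] > 0))
  r1 <- initializeLevelSet(c(32L, 32L), "random", seed = 7L)
  r2 <- initializeLevelSet(c(32L, 32L), "random", seed = 7L)
  expect_identical(r1, r2)
  expect_true(any(r1 > 0) && any(r1 < 0))
  expect_error(initializeLevelSet(c(8L, 8L), "spiral"), "unknown")
})

test_that("one evolution step equals the sum of its three forces", {
  set.seed(42)
  n <- 8
  eps <- 1.5
  phi <- matrix(runif(n * n, -1.4, 1.4), n, n)
  mK <- matrix(runif(n * n), n, n); mB <- 1 - mK
  PK <- matrix(runif(n * n, 0.05, 0.95), n, n); PB <- 1 - PK
  phiPK <- matrix(runif(n * n, -3, 3), n, n)
  lambda <- c(6, 6, 0.1); g1 <- 0.8
  out <- evolveStep(phi, mK, mB, PK, PB, phiPK, lambda, g1, eps,
                    clamp = FALSE)
  # scalar-arithmetic oracle, pixel by pixel
  curv <- curvatureField(phi)
  oracle <- phi
  for (i in 1:n) for (j in 1:n) {
    p <- phi[i, j]
    del <- if (abs(p) > eps) 0 else (1 + cos(pi * p / eps)) / (2 * eps)
    V <- if (p > eps) 1 else if (p < -eps) 0 else
      0.5 + p / (2 * eps) + sin(pi * p / eps) / (2 * pi)
    q <- phiPK[i, j]
    Vq <- if (q > eps) 1 else if (q < -eps) 0 else
      0.5 + q / (2 * eps) + sin(pi * q / eps) / (2 * pi)
    f <- lambda[1] * curv[i, j] +
      lambda[2] * (mK[i, j] * PK[i, j] - mB[i, j] * PB[i, j]) -
      2 * lambda[3] * (V - Vq)
    oracle[i, j] <- p + g1 * del * f
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("pixels outside the active band never move", {
  n <- 10
  phi <- matrix(seq(-8, 8, length.out = n * n), n, n)
  mK <- matrix(1, n, n); mB <- matrix(0, n, n)
  PK <- matrix(0.9, n, n); PB <- 1 - PK
  phiPK <- matrix(-2, n, n)
  out <- evolveStep(phi, mK, mB, PK, PB, phiPK, c(6, 6, 0.1), 0.8, 1.5)
  frozen <- abs(phi) > 1.5
  expect_identical(out[frozen], phi[frozen])
  # on-contour pixel with mK PK > mB PB rises when only the data term acts
  phi2 <- matrix(0, 5, 5)
  out2 <- evolveStep(phi2, mK[1:5, 1:5], mB[1:5, 1:5], PK[1:5, 1:5],
                     PB[1:5, 1:5], phiPK[1:5, 1:5], c(0, 6, 0), 0.8, 1.5)
  expect_true(all(out2 > 0))
  expect_error(
    evolveStep(phi, mK[1:5, 1:5], mB, PK, PB, phiPK, c(6, 6, 0.1), 0.8, 1.5),
    "dimensions")
})

test_that("pure curvature flow shrinks the contour of a noisy blob", {
  set.seed(11)
  n <- 64
  g <- expand.grid(y = 1:n, x = 1:n)
  r <- sqrt((g$x - 32)^2 + (g$y - 32)^2)
  wob <- 18 + 4 * sin(6 * atan2(g$y - 32, g$x - 32))
  phi <- matrix(pmin(pmax(wob - r, -1.4), 1.4), n, n)
  zeros <- matrix(0, n, n)
  len <- function(p) {
    px <- (p[, c(2:n, n)] - p[, c(1, 1:(n - 1))]) / 2
    py <- (p[c(2:n, n), ] - p[c(1, 1:(n - 1)), ]) / 2
    sum(smearedDirac(p, 1.5) * sqrt(px^2 + py^2))
  }
  l0 <- len(phi)
  for (i in 1:40)
    phi <- evolveStep(phi, zeros, zeros, zeros, zeros, zeros,
                      c(6, 0, 0), 0.8, 1.5)
  expect_lt(len(phi), l0)
})
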