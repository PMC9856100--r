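test_that("the affine matrix composes as rotation %*% shear %*% scale", {
  id <- composeAffine(affineParams())
  expect_equal(id$A, diag(2))
  expect_equal(id$T, c(0, 0))
  q <- composeAffine(affineParams(theta = pi / 2))
  expect_equal(q$A, matrix(c(0, 1, -1, 0), 2, 2), tolerance = 1e-12)
  # explicit matrix-product oracle, ordering R %*% H %*% S
  p <- affineParams(theta = 0.3, sx = 1.2, sy = 0.8, hx = 0.1, hy = -0.05,
                    tx = 3, ty = -2)
  R <- rbind(c(cos(0.3), -sin(0.3)), c(sin(0.3), cos(0.3)))
  H <- rbind(c(1, 0.1), c(-0.05, 1))
  S <- diag(c(1.2, 0.8))
  expect_equal(composeAffine(p)$A, R %*% H %*% S, tolerance = 1e-14)
  ho <- composeAffine(affineParams(hx = 0.1))
  expect_equal(ho$A, rbind(c(1, 0.1), c(0, 1)))
  expect_error(affineParams(sx = -1), "positive")
})

test_that("coordinate transforms act about the stated centre", {
  p <- affineParams()
  out <- transformCoords(5, 7, p, center = c(3, 3))
  expect_equal(c(out$x, out$y), c(5, 7))
  out <- transformCoords(5, 7, affineParams(tx = 2, ty = -1))
  expect_equal(c(out$x, out$y), c(7, 6))
  # half-turn about the centre reflects through it
  out <- transformCoords(10, 12, affineParams(theta = pi), center = c(8, 8))
  expect_equal(c(out$x, out$y), c(6, 4), tolerance = 1e-12)
  # exact invertibility whenever det A != 0
  p <- affineParams(theta = 0.2, sx = 1.1, sy = 0.9, hx = 0.3, hy = 0.2,
                    tx = 4, ty = -3)
  A <- composeAffine(p)$A
  expect_gt(abs(det(A)), 0)
  fwd <- transformCoords(2, 9, p, center = c(5, 5))
  back <- solve(A, c(fwd$x - 5 - p@tx, fwd$y - 5 - p@ty)) + c(5, 5)
  expect_equal(back, c(2, 9), tolerance = 1e-12)
})

test_that("parameter Jacobians match finite differences of the transform", {
  p <- affineParams(theta = 0.15, sx = 1.05, sy = 0.93, hx = 0.08,
                    hy = -0.04, tx = 1.5, ty = -2.5)
  ctr <- c(10, 12)
  x <- c(3, 17, 10); y <- c(5, 9, 25)
  J <- paramJacobians(x, y, p, ctr)
  expect_equal(J$tx$x, c(1, 1, 1))
  expect_equal(J$ty$y, c(1, 1, 1))
  J0 <- paramJacobians(x, y, affineParams(), c(0, 0))
  expect_equal(J0$theta$x, -y)
  expect_equal(J0$theta$y, x)
  pv <- affineVector(p)
  mk <- function(v) affineParams(v["theta"], v["sx"], v["sy"], v["hx"],
                                 v["hy"], v["tx"], v["ty"])
  h <- 1e-6
  for (nm in names(pv)) {
    up <- pv; up[nm] <- up[nm] + h
    dn <- pv; dn[nm] <- dn[nm] - h
    fu <- transformCoords(x, y, mk(up), ctr)
    fd <- transformCoords(x, y, mk(dn), ctr)
    expect_equal(J[[nm]]$x, (fu$x - fd$x) / (2 * h), tolerance = 1e-6)
    expect_equal(J[[nm]]$y, (fu$y - fd$y) / (2 * h), tolerance = 1e-6)
  }
})

test_that("registration gradients vanish in the degenerate cases", {
  sc <- smoothCase(48)
  # lambda2 = lambda3 = 0 kills every term exactly
  g <- registrationGradients(sc$phi, sc$mK, sc$mB, sc$prior,
                             affineParams(), c(6, 0, 0), 1.5, sc$center)
  expect_identical(unname(g), rep(0, 7))
  # V(phi) == V(phiPK(X-hat)): the shape-mismatch gradient is exactly zero
  prior <- sc$prior
  g <- registrationGradients(prior@phiPK, sc$mK, sc$mB, prior,
                             affineParams(), c(6, 0, 0.1), 1.5, sc$center)
  expect_equal(unname(g), rep(0, 7))
  # reflection-symmetric case at identity: translation gradient ~ 0
  n <- 48; cx <- (n + 1) / 2
  x <- matrix(rep(1:n, each = n), n, n); y <- matrix(rep(1:n, n), n, n)
  r2 <- (x - cx)^2 + (y - cx)^2
  PK <- 0.02 + 0.96 / (1 + exp((sqrt(r2) - 12) / 2))
  prior2 <- methods::new("ShapePriorModel", PK = PK, PB = 1 - PK,
                         phiPK = 12 - sqrt(r2 + 4), N = 10L, beta = 1)
  phi2 <- pmin(pmax(12 - sqrt(r2 + 4), -1.4), 1.4)
  mem <- updateMemberships(100 / (1 + exp((sqrt(r2) - 12) / 2)) + 50, 145, 55)
  g2 <- registrationGradients(phi2, mem$mK, mem$mB, prior2, affineParams(),
                              c(6, 6, 0.1), 1.5, c(cx, cx))
  expect_lt(abs(g2[["tx"]]) / sum(abs(g2)), 1e-10)
  expect_lt(abs(g2[["ty"]]) / sum(abs(g2)), 1e-10)
})

test_that("parameter updates descend with per-group steps", {
  p <- affineParams(theta = 0.1, sx = 1.1, sy = 0.9, hx = 0.05, hy = 0.02,
                    tx = 1, ty = -1)
  g0 <- c(theta = 0, sx = 0, sy = 0, hx = 0, hy = 0, tx = 0, ty = 0)
  gamma <- c(0.8, 1e-14, 1e-10, 1e-10, 1e-9)
  expect_equal(affineVector(updateParams(p, g0, gamma)), affineVector(p))
  g <- c(theta = 2, sx = 1, sy = -1, hx = 3, hy = -3, tx = 10, ty = -10)
  v <- affineVector(updateParams(p, g, gamma))
  expect_equal(v[["theta"]], 0.1 - 1e-9 * 2)
  expect_equal(v[["sx"]], 1.1 - 1e-14 * 1)
  expect_equal(v[["hx"]], 0.05 - 1e-10 * 3)
  expect_equal(v[["tx"]], 1 - 1e-10 * 10)
  # scales stay strictly positive under a huge gradient
  v <- affineVector(updateParams(p, c(theta = 0, sx = 1e20, sy = 1e20,
                                      hx = 0, hy = 0, tx = 0, ty = 0),
                                 gamma))
  expect_gt(v[["sx"]], 0)
  # normalized mode caps the per-iteration motion
  v <- affineVector(updateParams(affineParams(),
                                 c(theta = 1e9, sx = 0, sy = 0, hx = 0,
                                   hy = 0, tx = 1e9, ty = 0),
                                 gamma, normalize = TRUE, gradScale = 1))
  expect_equal(v[["theta"]], -0.004)
  expect_equal(v[["tx"]], -0.15)
  expect_error(updateParams(p, g, c(0, 1, 1, 1, 1)), "positive")
})
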