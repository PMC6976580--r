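## PAS extraction -----------------------------------------------------------

makeRingFrames <- function(n = 3, rot = NULL) {
  ## N at origin, O along +x, ring carbons in the xy plane
  base <- rbind(N = c(0, 0, 0), O = c(1.3, 0, 0),
                C1 = c(-0.7, 1.2, 0), C2 = c(-0.7, -1.2, 0))
  frames <- array(NA_real_, c(n, 4, 3))
  for (k in seq_len(n)) {
    coords <- base
    if (!is.null(rot)) coords <- t(quatToMatrix(rot) %*% t(coords))
    frames[k, , ] <- coords
  }
  frames
}

test_that("PAS extraction of an aligned ring gives the identity", {
  traj <- extractPas(makeRingFrames())
  expect_equal(trajectoryQuaternions(traj)[1, ],
               c(w = 1, x = 0, y = 0, z = 0), tolerance = 1e-12)
})

test_that("rigidly rotated frames give the rotation quaternion", {
  qStar <- as.numeric(quatFromAxisAngle(c(0.3, -0.5, 0.9)))
  traj <- extractPas(makeRingFrames(rot = qStar))
  q <- trajectoryQuaternions(traj)[1, ]
  ## extracted = qStar composed with the frame-0 (identity) result
  expect_equal(abs(sum(q * qStar)), 1, tolerance = 1e-10)
})

test_that("colinear ring atoms raise an error naming the frame", {
  frames <- makeRingFrames()
  frames[2, 3, ] <- c(-1, 0, 0)   # C1 on the N-O axis
  frames[2, 4, ] <- c(-2, 0, 0)   # C2 colinear too
  expect_error(extractPas(frames), "frame 2")
})

## decomposition ------------------------------------------------------------

test_that("rigid-body trajectory decomposes into pure global motion", {
  set.seed(31)
  nF <- 20
  atoms <- matrix(rnorm(15), 5, 3)
  Q <- randomQuats(nF, seed = 32)
  Q <- quatAlignSigns(Q)
  frames <- array(NA_real_, c(nF, 5, 3))
  for (k in seq_len(nF)) frames[k, , ] <- t(quatToMatrix(Q[k, ]) %*% t(atoms))
  full <- orientationTrajectory(Q, 1, normalize = TRUE)
  dec <- decomposeTrajectory(full, atoms, frames)
  rq <- trajectoryQuaternions(internalPart(dec))
  ## internal part constant (identity up to global sign)
  expect_true(all(abs(abs(rq[, 1]) - 1) < 1e-8))
  ## composition reproduces the input per frame
  recomposed <- trajectoryQuaternions(fullTrajectory(dec))
  dots <- abs(rowSums(recomposed * trajectoryQuaternions(full)))
  expect_true(all(dots > 1 - 1e-9))
})

test_that("internal-only trajectory yields identity global part", {
  atoms <- matrix(rnorm(15, sd = 2), 5, 3)
  nF <- 10
  frames <- array(rep(atoms, each = nF), c(nF, 5, 3))
  r <- simulateMotion(motionModel("isotropic_diffusion", tauRotNs = 0.5,
                                  seed = 4), nF)
  dec <- decomposeTrajectory(r, atoms, frames)
  gq <- trajectoryQuaternions(globalPart(dec))
  expect_true(all(abs(abs(gq[, 1]) - 1) < 1e-8))
})

test_that("decompose rejects degenerate fit-atom sets", {
  atoms <- cbind(1:5, 2 * (1:5), -1 * (1:5))  # colinear
  frames <- array(rep(atoms, each = 4), c(4, 5, 3))
  traj <- simulateMotion(motionModel("isotropic_diffusion", tauRotNs = 1,
                                     seed = 1), 4)
  expect_error(decomposeTrajectory(traj, atoms, frames), "colinear")
  expect_error(decomposeTrajectory(traj, atoms[1:2, ], frames[, 1:2, ]),
               "3")
})

test_that("compose/decompose round trip and synthetic ground truth", {
  g <- brownianRotation(500, tauRotNs = 1, seed = 5)
  r <- simulateMotion(motionModel("cone_diffusion", halfAngleDeg = 40,
                                  dNsInv = 1.5, seed = 6), 500)
  dec <- composeTrajectory(g, r)
  full <- fullTrajectory(dec)
  expected <- quatMultiply(trajectoryQuaternions(g),
                           trajectoryQuaternions(r))
  dots <- abs(rowSums(trajectoryQuaternions(full) * expected))
  expect_true(all(dots > 1 - 1e-9))
  expect_error(composeTrajectory(g,
    simulateMotion(motionModel("isotropic_diffusion", tauRotNs = 1,
                               seed = 2), 400)), "length")
})

## tumbling rescaling -------------------------------------------------------

test_that("lambda = 1 rescaling is bit-stable; lambda = 0 freezes", {
  g <- brownianRotation(2000, tauRotNs = 1, seed = 8)
  ident <- orientationTrajectory(
    matrix(rep(c(1, 0, 0, 0), 2000), ncol = 4, byrow = TRUE), 1)
  dec <- composeTrajectory(g, ident)
  same <- rescaleTumbling(dec, 1)
  dev <- max(abs(trajectoryQuaternions(globalPart(same)) -
                   trajectoryQuaternions(g)))
  expect_lt(dev, 1e-9)
  frozen <- rescaleTumbling(dec, 0)
  fq <- trajectoryQuaternions(globalPart(frozen))
  expect_true(all(abs(fq[, 1] - fq[1, 1]) < 1e-12))
  expect_error(rescaleTumbling(dec, -1), "non-negative")
})

test_that("rescaling scales tau_rot by lambda^-2 and keeps internal part", {
  g <- brownianRotation(2e5, tauRotNs = 0.3, deltaPs = 1, seed = 10)
  ident <- orientationTrajectory(
    matrix(rep(c(1, 0, 0, 0), 2e5), ncol = 4, byrow = TRUE), 1)
  dec <- composeTrajectory(g, ident)
  sc <- rescaleTumbling(dec, 2)
  expect_identical(trajectoryQuaternions(internalPart(sc)),
                   trajectoryQuaternions(ident))
  tau0 <- estimateTauRot(g, maxLagPs = 2500)$tauRotNs
  tau2 <- estimateTauRot(globalPart(sc), maxLagPs = 800)$tauRotNs
  expect_equal(tau2 / tau0, 0.25, tolerance = 0.2)
})

test_that("rescaling preserves axially anisotropic axis statistics", {
  ## Dpar/Dperp = 1.4: body-z P2 correlation decays with 6*Dperp while the
  ## transverse axes mix Dpar; the rescaled trajectory must keep the
  ## distinction (anisotropy of tumbling preserved in the molecular frame)
  g <- brownianRotation(3e5, tauRotNs = 0.3, anisotropy = 1.4, seed = 11)
  dec <- composeTrajectory(g, orientationTrajectory(
    matrix(rep(c(1, 0, 0, 0), 3e5), ncol = 4, byrow = TRUE), 1))
  axisTau <- function(traj, col) {
    R <- spinESR:::.rotationElements(trajectoryQuaternions(traj))
    u <- R[, col, drop = FALSE]
    cf <- p2Correlation(R[, col], 1500)
    fit <- minpack.lm::nlsLM(v ~ exp(-l / tau),
                             data = data.frame(l = cf@lagPs, v = cf@values),
                             start = list(tau = 300))
    coef(fit)[["tau"]]
  }
  zCols <- c("R13", "R23", "R33"); xCols <- c("R11", "R21", "R31")
  ratio0 <- axisTau(g, zCols) / axisTau(g, xCols)
  sc <- globalPart(rescaleTumbling(dec, 0.7))
  ratio1 <- axisTau(sc, zCols) / axisTau(sc, xCols)
  expect_equal(ratio1, ratio0, tolerance = 0.15)
})

## correlation functions ----------------------------------------------------

test_that("P2 correlation: static, Brownian and memoryless limits", {
  v <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  cf <- p2Correlation(v, 20)
  expect_equal(cf@values, rep(1, 21), tolerance = 1e-12)

  tau <- 0.2
  g <- brownianRotation(2e5, tauRotNs = tau, seed = 13)
  R <- spinESR:::.rotationElements(trajectoryQuaternions(g))
  cf <- p2Correlation(R[, c("R13", "R23", "R33")], 600)
  expect_equal(cf@values[1], 1, tolerance = 1e-9)
  expect_equal(cf@values[201], exp(-1), tolerance = 0.08)  # lag = tau

  set.seed(14)
  u <- matrix(rnorm(3 * 4000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  cf <- p2Correlation(u, 50)
  expect_lt(max(abs(cf@values[-1])), 0.06)
  expect_error(p2Correlation(matrix(0, 0, 3), 5))
})

test_that("tau_rot estimation recovers the generator parameter", {
  g <- brownianRotation(4e5, tauRotNs = 0.4, seed = 15)
  est <- estimateTauRot(g, maxLagPs = 4000)
  expect_equal(est$tauRotNs, 0.4, tolerance = 0.1)
  expect_lt(est$residual, 0.05)
  frozen <- orientationTrajectory(
    matrix(rep(c(1, 0, 0, 0), 100), ncol = 4, byrow = TRUE), 1)
  expect_error(estimateTauRot(frozen), "static")
})

test_that("dihedral gamma: constant, decorrelated and two-site exchange", {
  const <- angleSeries(rep(55, 300))
  expect_equal(dihedralGamma(const, 100)@values, rep(1, 101),
               tolerance = 1e-12)

  set.seed(16)
  unif <- angleSeries(runif(6000, -180, 180))
  g <- dihedralGamma(unif, 30)
  expect_lt(max(abs(g@values[-1])), 0.06)

  ## symmetric two-site jump chi <-> chi + delta at rate k each way:
  ## gamma(inf) = mean_ij cos(chi_i - chi_j) = (1 + cos(delta)) / 2
  deltaJump <- 70
  k <- 0.02   # per frame
  set.seed(17)
  n <- 4e4
  flips <- cumsum(runif(n) < k) %% 2
  chi <- ifelse(flips == 0, -35, -35 + deltaJump)
  g <- dihedralGamma(angleSeries(chi), 1500)
  plateau <- mean(g@values[1000:1501])
  expect_equal(plateau, (1 + cos(deltaJump * pi / 180)) / 2,
               tolerance = 0.05)
})

test_that("correlation plateau estimator uses the final decade", {
  cf <- correlationFunction(0:100, c(rep(1, 5), rep(0.4, 96)),
                            normalized = TRUE)
  expect_equal(correlationPlateau(cf), 0.4, tolerance = 1e-12)
})
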