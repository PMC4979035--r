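# Superposition, RMSD and RMSF against closed forms, rigid-motion
# invariance, and Monte-Carlo oracles.

test_that("Kabsch superposition handles identity, rigid motion, degeneracy", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  fit <- kabschSuperpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  R <- rotationMatrix(c(0, 0, 1), pi / 2)
  moved <- applyRigid(X, R, c(3, -2, 7))
  fit2 <- kabschSuperpose(moved, X)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)

  expect_error(kabschSuperpose(X[1:2, ], X[1:2, ]), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line + 0), "collinear")
})

test_that("Kabsch matches an independent rotation-space minimization", {
  # 4-point tetrahedron, one vertex displaced 1 A; oracle minimizes RMSD
  # over Euler angles numerically, independent of the SVD route
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  mob <- tet
  mob[1, ] <- mob[1, ] + c(1, 0, 0)
  rmsdAt <- function(p) {
    R <- rotationMatrix(c(1, 0, 0), p[1]) %*%
         rotationMatrix(c(0, 1, 0), p[2]) %*%
         rotationMatrix(c(0, 0, 1), p[3])
    A <- scale(mob, scale = FALSE) %*% t(R)
    B <- scale(tet, scale = FALSE)
    sqrt(mean(rowSums((A - B)^2)))
  }
  best <- Inf
  for (s in 1:20) {
    set.seed(s)
    o <- stats::optim(runif(3, -pi, pi), rmsdAt,
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  fit <- kabschSuperpose(mob, tet)
  expect_equal(fit$rmsd, best, tolerance = 1e-3)
})

test_that("RMSD series is zero for static and rigid-motion trajectories", {
  fx <- cachedFixture("mini_helix", nres = 8)
  static <- makeTrajectory(fx, 5, sigma = 0, seed = 1)
  sel <- atomSelect(fx$topology, "backbone")
  s <- rmsdSeries(static, fx$native, sel)
  expect_equal(s$rmsd, rep(0, 5), tolerance = 1e-12)

  frames <- lapply(1:5, function(i)
    applyRigid(fx$native, rotationMatrix(c(1, 2, 3), i / 3), c(i, -i, 2 * i)))
  rigid <- Trajectory(fx$topology, frames)
  s2 <- rmsdSeries(rigid, fx$native, sel)
  expect_lt(max(s2$rmsd), 1e-9)

  expect_error(rmsdSeries(static, fx$native, integer()), "empty")
})

test_that("jittered RMSD matches a Monte-Carlo estimate within 5%", {
  fx <- cachedFixture("mini_helix", nres = 6)
  sel <- atomSelect(fx$topology, "backbone")
  sigma <- 0.3
  traj <- makeTrajectory(fx, 400, sigma = sigma, seed = 7)
  measured <- mean(rmsdSeries(traj, fx$native, sel)$rmsd)

  # independent oracle: direct simulation of the same statistic without the
  # package's trajectory/Kabsch machinery beyond base linear algebra
  idx <- sel@indices
  ref <- fx$native[idx, ]
  refc <- scale(ref, scale = FALSE)
  mc <- withr::with_seed(99, {
    mean(replicate(400, {
      pert <- ref + matrix(rnorm(length(ref), sd = sigma), ncol = 3)
      A <- scale(pert, scale = FALSE)
      H <- t(A) %*% refc
      s <- svd(H)
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      sqrt(mean(rowSums((A %*% t(R) - refc)^2)))
    }))
  })
  expect_equal(measured, mc, tolerance = 0.05)
})

test_that("RMSD histograms normalize and locate the mode", {
  expect_error(rmsdDistribution(numeric(0)), "empty")
  expect_error(rmsdDistribution(c(1, 2), binWidth = 0), "bin width")

  h0 <- rmsdDistribution(rep(0, 50), binWidth = 0.1)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$density * 0.1, 1)

  set.seed(3)
  u <- runif(20000)
  hu <- rmsdDistribution(u, binWidth = 0.1)
  inRange <- hu$center > 0.05 & hu$center < 0.95
  expect_equal(hu$density[inRange], rep(1, sum(inRange)), tolerance = 0.06)
  expect_equal(sum(hu$density) * 0.1, 1, tolerance = 1e-10)

  x <- c(rnorm(5000, 1.1, 0.15))
  hx <- rmsdDistribution(x, binWidth = 0.1)
  # direct-count oracle for the modal bin
  counts <- table(cut(x, breaks = seq(floor(min(x) / 0.1) * 0.1,
                                      max(x) + 0.1, by = 0.1)))
  expect_equal(which.max(hx$density), unname(which.max(counts)))
})

test_that("RMSF: static zero, constructed two-frame case, MC oracle, invariance", {
  fx <- cachedFixture("mini_helix", nres = 6)
  static <- makeTrajectory(fx, 4, sigma = 0, seed = 1)
  sel <- atomSelect(fx$topology, "backbone")
  expect_equal(rmsf(static, sel)$rmsf, rep(0, 24), tolerance = 1e-10)
  expect_error(rmsf(extractSnapshots(static, 1), sel), "2 frames")

  # one atom oscillating +/- d along x in a rigid body: superpose on the
  # others, measure the mover
  d <- 0.7
  f1 <- fx$native; f2 <- fx$native
  f1[1, 1] <- f1[1, 1] + d
  f2[1, 1] <- f2[1, 1] - d
  osc <- Trajectory(fx$topology, list(f1, f2))
  stationary <- 2:nAtoms(fx$topology)
  out <- rmsf(osc, c(1L, stationary), weights = c(0, rep(1, length(stationary))))
  expect_equal(out$rmsf[1], d, tolerance = 1e-10)
  expect_lt(max(out$rmsf[-1]), 1e-10)

  sigma <- 0.2
  jit <- makeTrajectory(fx, 3000, sigma = sigma, seed = 21)
  vals <- rmsf(jit, sel)$rmsf
  # MC oracle for E[sqrt(chi2_3)] * sigma
  mc <- withr::with_seed(5, mean(sqrt(rowSums(matrix(rnorm(3 * 2e5), ncol = 3)^2))))
  expect_equal(mean(vals), sigma * mc, tolerance = 0.05)

  # invariance under a global rigid motion of every frame
  R <- rotationMatrix(c(1, 1, 0), 1.1)
  rot <- Trajectory(fx$topology, lapply(seq_len(50), function(i)
    applyRigid(frameCoords(jit, i), R, c(5, 6, 7))))
  sub <- Trajectory(fx$topology, lapply(seq_len(50), function(i)
    frameCoords(jit, i)))
  expect_equal(rmsf(rot, sel)$rmsf, rmsf(sub, sel)$rmsf, tolerance = 1e-8)

  byRes <- rmsf(jit, atomSelect(fx$topology, "calpha"), byResidue = TRUE)
  expect_equal(nrow(byRes), 6L)
  expect_true(all(byRes$rmsf > 0))
})
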