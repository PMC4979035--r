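# Hydrogen-bond candidate enumeration, geometric detection, occupancy and
# the four-atom Coulomb energy statistic.

test_that("candidate enumeration follows topology connectivity and scope", {
  two <- cachedFixture("mini_helix", nres = 2)
  expect_equal(nrow(hbondCandidates(two$topology, "backbone")), 0L)

  hx <- cachedFixture("mini_helix", nres = 10)
  cand <- hbondCandidates(hx$topology, "backbone")
  expect_true(all(abs(atoms(hx$topology)$resid[cand$donor] -
                      atoms(hx$topology)$resid[cand$acceptor]) >= 2L))
  expect_false(any(duplicated(cand[, c("donor", "acceptor")])))
  # the n-4 helical i -> i+4 pairs are all among the candidates
  key <- paste(cand$donor, cand$acceptor)
  expect_true(all(paste(hx$hbonds$donor, hx$hbonds$acceptor) %in% key))

  tc <- cachedFixture("toy_complex")
  pl <- hbondCandidates(tc$topology, "protein_ligand")
  designed <- paste(tc$hbonds$donor, tc$hbonds$acceptor)
  expect_true(all(designed %in% paste(pl$donor, pl$acceptor)))
  # and detection in the native frame finds exactly the three designed ones
  present <- pl[hbondDetect(tc$native, pl, hbondCriteria()), ]
  expect_equal(sort(paste(present$donor, present$acceptor)), sort(designed))
})

test_that("detection applies inclusive distance and angle cutoffs", {
  # hand-built N-H...O=C geometry with tunable distance/angle
  geom <- function(dNO, angleDeg) {
    N <- c(0, 0, 0)
    H <- c(1.0, 0, 0)
    # acceptor placed so that angle(N,H,O) = angleDeg and |N-O| = dNO:
    # solve for O on the x-y plane
    th <- angleDeg * pi / 180
    # O = H + r*(cos(pi - th_x)...): direction from H making angle th with H->N
    dirHN <- c(-1, 0, 0)
    rot <- rotationMatrix(c(0, 0, 1), th)
    dirHO <- as.numeric(rot %*% dirHN)
    # choose |H-O| so that |N-O| = dNO
    # |N - (H + s*dirHO)|^2 = dNO^2, solve quadratic in s
    b <- 2 * sum((H - N) * dirHO)
    cc <- sum((H - N)^2) - dNO^2
    s <- (-b + sqrt(b^2 - 4 * cc)) / 2
    O <- H + s * dirHO
    C <- O + c(0, 1.23, 0)
    rbind(C, O, N, H)
  }
  cand <- data.frame(donor = 3L, hydrogen = 4L, acceptor = 2L, antecedent = 1L)
  crit <- hbondCriteria()
  expect_true(hbondDetect(geom(2.9, 180), cand, crit))
  expect_false(hbondDetect(geom(3.6, 180), cand, crit))
  expect_false(hbondDetect(geom(2.9, 119), cand, crit))
  expect_true(hbondDetect(geom(2.9, 120), cand, crit))   # boundary inclusive
  expect_true(hbondDetect(geom(3.5, 180), cand, crit))   # boundary inclusive

  expect_length(hbondDetect(geom(2.9, 180), cand[0, ], crit), 0L)
  expect_error(hbondCriteria(distance = -1), "> 0")
  expect_error(hbondCriteria(angle = 200), "180")
})

test_that("four-atom Coulomb energy matches a hand summation and is even in q", {
  coords <- rbind(c(0, 1.23, 0),   # C
                  c(0, 0, 0),      # O
                  c(2.9, 0, 0),    # N
                  c(1.9, 0, 0))    # H
  hb <- data.frame(donor = 3L, hydrogen = 4L, acceptor = 2L, antecedent = 1L)
  q <- c(0.5, -0.5, -0.3, 0.3)
  # independent direct summation over the four pairs
  k <- 332.0636
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  expected <- k * (q[1] * q[3] / d(1, 3) + q[1] * q[4] / d(1, 4) +
                   q[2] * q[3] / d(2, 3) + q[2] * q[4] / d(2, 4))
  expect_equal(hbondCoulombEnergy(coords, hb, q), expected, tolerance = 1e-6)

  expect_equal(hbondCoulombEnergy(coords, hb, rep(0, 4)), 0)
  expect_equal(hbondCoulombEnergy(coords, hb, 2 * q), 4 * expected,
               tolerance = 1e-10)
  expect_equal(hbondCoulombEnergy(coords, hb, -q),
               hbondCoulombEnergy(coords, hb, q), tolerance = 1e-12)

  clash <- coords; clash[4, ] <- coords[2, ] + c(0.01, 0, 0)
  expect_error(hbondCoulombEnergy(clash, hb, q), "clash")

  # rigid-motion invariance
  moved <- applyRigid(coords, rotationMatrix(c(1, 2, 0), 0.7), c(3, 1, -2))
  expect_equal(hbondCoulombEnergy(moved, hb, q),
               hbondCoulombEnergy(coords, hb, q), tolerance = 1e-9)
})

test_that("occupancy is the mean presence flag", {
  expect_equal(occupancy(rep(TRUE, 10)), 1.0)
  expect_equal(occupancy(c(rep(TRUE, 34), rep(FALSE, 66))), 0.34)
  expect_error(occupancy(logical(0)), "empty")
})

test_that("scripted rupture drives occupancy and native-fraction blocks", {
  fx <- cachedFixture("toy_complex")
  traj <- makeTrajectory(fx, 100, sigma = 0.1,
                         rupture = data.frame(bond = 1L, frame = 50L),
                         seed = 13)
  ser <- hbondSeries(traj, fx$hbonds[1, ], chargeSource = fx$chargeSets$base)
  expect_equal(attr(ser, "occupancy"), 0.49)
  expect_true(all(ser$distance[50:100] > 3.5))
  expect_equal(occupancy(ser), 0.49)

  # native-fraction over the three designed protein-ligand bonds:
  # blocks before the rupture 1.0, after it 2/3
  nf <- nativeFractionSeries(traj, fx$native, block = 25L,
                             candidates = fx$hbonds)
  expect_equal(nf$fraction[1], 1.0)
  expect_equal(nf$fraction[3:4], rep(2 / 3, 2), tolerance = 1e-12)
  expect_true(all(nf$fraction >= 0 & nf$fraction <= 1))

  # block averaging of a constant series returns the constant
  static <- makeTrajectory(fx, 30, sigma = 0, seed = 1)
  nfs <- nativeFractionSeries(static, fx$native, block = 7L,
                              candidates = fx$hbonds)
  expect_equal(nfs$fraction, rep(1, nrow(nfs)))

  expect_error(makeTrajectory(fx, 10, rupture = data.frame(bond = 9L, frame = 2L)),
               "unknown")
  expect_error(nativeFractionSeries(static, fx$native * 10,
                                    candidates = fx$hbonds),
               "zero native")
})

test_that("helix backbone network is detected and fractions respond to rupture", {
  hx <- cachedFixture("mini_helix", nres = 10)
  cand <- hbondCandidates(hx$topology, "backbone")
  nat <- cand[hbondDetect(hx$native, cand, hbondCriteria()), ]
  expect_equal(nrow(nat), 6L)  # the i -> i+4 network

  traj <- makeTrajectory(hx, 40, sigma = 0.05,
                         rupture = data.frame(bond = 2L, frame = 21L),
                         seed = 3)
  nf <- nativeFractionSeries(traj, hx$native, block = 20L, scope = "backbone")
  expect_equal(nf$fraction[1], 1.0, tolerance = 0.02)
  expect_equal(nf$fraction[2], 5 / 6, tolerance = 0.02)
})

test_that("mean bond energy averages over all frames", {
  fx <- cachedFixture("toy_complex")
  static <- makeTrajectory(fx, 5, sigma = 0, seed = 1)
  e1 <- hbondCoulombEnergy(fx$native, fx$hbonds, fx$chargeSets$base)
  expect_equal(meanHBondEnergy(static, fx$hbonds, fx$chargeSets$base), e1,
               tolerance = 1e-10)
})
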