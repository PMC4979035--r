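# Intergroup Coulomb/Lennard-Jones energies, per-residue spectra, and the
# toy bonded force field with its analytic gradient.

test_that("group interactions reproduce closed forms and brute-force sums", {
  # two uncharged, epsilon-free atoms -> (0, 0)
  atomsDf <- data.frame(serial = 1:2, name = c("X1", "X2"), element = "C",
                        resname = "XXX", resid = 1:2, segment = "protein",
                        x = c(0, 3), y = 0, z = 0, charge = 0,
                        rmin_half = 1, epsilon = 0, mass = 12, pb_radius = 1.7)
  topo <- Topology(atomsDf)
  e <- groupInteraction(refCoords(topo), topo, topo, 1L, 2L)
  expect_equal(unname(e), c(0, 0))

  # single LJ pair at r = rmin_ij gives exactly -eps_ij
  atomsDf$epsilon <- c(0.2, 0.45)
  atomsDf$rmin_half <- c(1.4, 1.6)
  atomsDf$x <- c(0, 3.0)  # rmin_ij = 3.0
  topo2 <- Topology(atomsDf)
  e2 <- groupInteraction(refCoords(topo2), topo2, topo2, 1L, 2L)
  expect_equal(unname(e2["vdw"]), -sqrt(0.2 * 0.45), tolerance = 1e-12)

  # random 3x3 groups against an independent double loop
  set.seed(42)
  n <- 6
  adf <- data.frame(serial = 1:n, name = paste0("C", 1:n), element = "C",
                    resname = "RND", resid = rep(1:2, each = 3),
                    segment = "protein",
                    x = runif(n, 0, 8), y = runif(n, 0, 8), z = runif(n, 0, 8),
                    charge = round(runif(n, -0.5, 0.5), 3),
                    rmin_half = runif(n, 1, 2), epsilon = runif(n, 0.05, 0.3),
                    mass = 12, pb_radius = 1.7)
  adf$charge <- adf$charge - sum(adf$charge) / n  # integer (zero) total
  topo3 <- Topology(adf)
  X <- refCoords(topo3)
  A <- 1:3; B <- 4:6
  brute <- c(0, 0)
  for (i in A) for (j in B) {
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    rmin <- adf$rmin_half[i] + adf$rmin_half[j]
    epsij <- sqrt(adf$epsilon[i] * adf$epsilon[j])
    brute <- brute + c(332.0636 * adf$charge[i] * adf$charge[j] / r,
                       epsij * ((rmin / r)^12 - 2 * (rmin / r)^6))
  }
  got <- groupInteraction(X, topo3, topo3, A, B)
  expect_equal(unname(got), brute, tolerance = 1e-8)

  # symmetry and bilinearity
  expect_equal(groupInteraction(X, topo3, topo3, B, A), got, tolerance = 1e-12)
  q2 <- adf$charge; q2[A] <- 3 * q2[A]
  got2 <- groupInteraction(X, topo3, q2, A, B)
  expect_equal(unname(got2["ele"]), unname(3 * got["ele"]), tolerance = 1e-10)
  expect_identical(unname(got2["vdw"]), unname(got["vdw"]))

  # rigid-motion and ordering invariance
  Xm <- applyRigid(X, rotationMatrix(c(0, 1, 1), 0.9), c(-4, 2, 0))
  expect_equal(groupInteraction(Xm, topo3, topo3, A, B), got, tolerance = 1e-9)
  expect_equal(groupInteraction(X, topo3, topo3, c(3, 1, 2), c(6, 5, 4)), got,
               tolerance = 1e-12)

  expect_error(groupInteraction(X, topo3, topo3, 1:3, 3:5), "overlap")
  Xc <- X; Xc[4, ] <- X[1, ] + 0.01
  expect_error(groupInteraction(Xc, topo3, topo3, A, B), "clash")
})

test_that("per-residue spectrum is additive and localized", {
  fx <- cachedFixture("toy_complex")
  topo <- fx$topology
  lig <- atomSelect(topo, "ligand")
  rec <- atomSelect(topo, "protein")
  spec <- perResidueSpectrum(fx$native, topo, fx$chargeSets$base, lig)
  whole <- groupInteraction(fx$native, topo, fx$chargeSets$base, rec, lig)
  expect_equal(sum(spec$ele), unname(whole["ele"]), tolerance = 1e-6)
  expect_equal(sum(spec$vdw), unname(whole["vdw"]), tolerance = 1e-6)

  # designed hydrogen-bonding residues dominate the electrostatic spectrum
  a <- atoms(topo)
  hbRes <- unique(a$resid[c(fx$hbonds$donor, fx$hbonds$acceptor)[
    a$segment[c(fx$hbonds$donor, fx$hbonds$acceptor)] == "protein"]])
  top2 <- spec$resid[order(spec$ele)][1:2]
  expect_true(all(top2 %in% hbRes))

  # a single-residue protein equals the whole-protein interaction
  hx <- cachedFixture("mini_helix", nres = 2)
  a2 <- atoms(hx$topology)
  a2$segment[a2$resid == 2] <- "ligand"
  mono <- Topology(a2, hx$topology@bonds, hx$topology@angles)
  l2 <- which(a2$segment == "ligand")
  s2 <- perResidueSpectrum(hx$native, mono, a2$charge, l2)
  w2 <- groupInteraction(hx$native, mono, a2$charge, which(a2$segment == "protein"), l2)
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$ele, s2$vdw), unname(w2), tolerance = 1e-10)
})

test_that("toy bonded energy: closed forms and finite-difference gradient", {
  fx <- cachedFixture("mini_helix", nres = 5)
  topo <- fx$topology
  # native geometry parameterizes the equilibrium values -> zero energy
  expect_equal(as.numeric(toyBondedEnergy(fx$native, topo)), 0, tolerance = 1e-18)

  di <- cachedFixture("dimer")
  x <- di$native
  x[2, 1] <- x[2, 1] + 0.15
  expect_equal(as.numeric(toyBondedEnergy(x, di$topology)), 350 * 0.15^2,
               tolerance = 1e-10)

  # analytic gradient vs central finite differences at a random geometry
  set.seed(8)
  xr <- fx$native + matrix(rnorm(length(fx$native), sd = 0.05), ncol = 3)
  E <- toyBondedEnergy(xr, topo, gradient = TRUE)
  G <- attr(E, "gradient")
  h <- 1e-6
  for (d in sample(length(xr), 15)) {
    at <- (d - 1) %% nrow(xr) + 1
    cc <- (d - 1) %/% nrow(xr) + 1
    xp <- xr; xp[at, cc] <- xp[at, cc] + h
    xm <- xr; xm[at, cc] <- xm[at, cc] - h
    fd <- (as.numeric(toyBondedEnergy(xp, topo)) -
           as.numeric(toyBondedEnergy(xm, topo))) / (2 * h)
    expect_equal(G[at, cc], fd, tolerance = 1e-5)
  }

  badTopo <- topo
  badTopo@bonds$k[1] <- NA
  expect_error(toyBondedEnergy(fx$native, badTopo), "parameters")
})
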