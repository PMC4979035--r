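# Snapshot extraction, component assembly, condition runs, differences and
# per-residue decomposition. PB settings are coarse (2 grids/A, small
# padding) to keep grid solves at test scale; the structural identities
# tested here are exact regardless of grid resolution.

test_that("snapshot extraction is deterministic with an even stride", {
  fx <- cachedFixture("mini_helix", nres = 4)
  traj <- makeTrajectory(fx, 100, sigma = 0, seed = 1)
  all100 <- extractSnapshots(traj, 100, c(1L, 100L))
  expect_equal(all100@frameIndex, 1:100)

  two <- extractSnapshots(traj, 2, c(1L, 100L))
  expect_equal(two@frameIndex, c(1L, 100L))  # first and last window frames

  one <- extractSnapshots(traj, 1, c(1L, 100L))
  expect_equal(one@frameIndex, 100L)

  s200 <- extractSnapshots(makeTrajectory(fx, 1000, sigma = 0, seed = 1),
                           200, c(1L, 1000L))
  expect_equal(nFrames(s200), 200L)
  expect_equal(s200@frameIndex[1], 1L)
  expect_equal(s200@frameIndex[200], 1000L)
  expect_true(all(diff(s200@frameIndex) %in% 4:6))

  # default window is the final half
  expect_equal(extractSnapshots(traj, 2)@frameIndex, c(51L, 100L))
  expect_error(extractSnapshots(traj, 101, c(1L, 100L)), "extract")
})

test_that("total assembly follows the five-component sum", {
  expect_equal(assembleTotal(c(ele = 0, vdw = 0, pol = 0, nonpol = 0, TdS = 0)), 0)
  expect_equal(assembleTotal(list(ele = -1.5, vdw = -2, pol = 3, nonpol = -0.5,
                                  TdS = 2)), 1)
  expect_error(assembleTotal(c(ele = 1, vdw = 2)), "missing")
})

test_that("snapshot components vanish for a non-interacting, distant ligand", {
  # receptor: the two-atom dimer; ligand: a chargeless, epsilon-free atom
  # far away -> every component is zero up to grid tolerance
  di <- cachedFixture("dimer")
  a <- rbind(atoms(di$topology),
             data.frame(serial = 3L, name = "X", element = "C",
                        resname = "LIG", resid = 1L, segment = "ligand",
                        x = 18, y = 0, z = 0, charge = 0, rmin_half = 1.7,
                        epsilon = 0, mass = 12, pb_radius = 1.7))
  topo <- Topology(a, di$topology@bonds)
  cfg <- pipelineConfig(snapshots = 1L, entropySnapshots = 1L,
                        pb = testPB(gridDensity = 2, padding = 5))
  sc <- snapshotComponents(refCoords(topo), topo, a$charge,
                           receptor = 1:2, ligand = 3L, config = cfg)
  expect_equal(unname(sc["ele"]), 0)
  expect_equal(unname(sc["vdw"]), 0)
  expect_lt(abs(sc["pol"]), 0.3)      # separated cavities on a shared grid
  expect_lt(abs(sc["nonpol"]), 1e-6)  # disjoint surfaces: SASA adds exactly
  expect_equal(unname(sc["sub_total"]),
               unname(sc["ele"] + sc["vdw"] + sc["pol"] + sc["nonpol"]),
               tolerance = 1e-9)
})

test_that("gas-phase component equals the brute-force Coulomb oracle", {
  tc <- cachedFixture("toy_complex")
  topo <- tc$topology
  rec <- which(atoms(topo)$segment == "protein")
  lig <- which(atoms(topo)$segment == "ligand")
  cfg <- pipelineConfig(snapshots = 1L, entropySnapshots = 1L,
                        pb = testPB(gridDensity = 1.5, padding = 4))
  sc <- snapshotComponents(tc$native, topo, tc$chargeSets$base, rec, lig, cfg)
  q <- charges(tc$chargeSets$base)
  brute <- 0
  for (i in rec) for (j in lig)
    brute <- brute + 332.0636 * q[i] * q[j] /
      sqrt(sum((tc$native[i, ] - tc$native[j, ])^2))
  expect_equal(unname(sc["ele"]), brute, tolerance = 1e-8)
})

test_that("condition runs average snapshots and respect the charge-swap structure", {
  tc <- cachedFixture("toy_complex")
  topo <- tc$topology
  traj <- makeTrajectory(tc, 4, sigma = 0.06, seed = 17)
  registry <- list(
    chargeSets = list(base = tc$chargeSets$base,
                      polarized = tc$chargeSets$polarized),
    trajectories = list(jitter = traj,
                        xray = makeTrajectory(tc, 1, sigma = 0, seed = 1)),
    receptor = atomSelect(topo, "protein"),
    ligand = atomSelect(topo, "ligand"))
  cfg <- pipelineConfig(snapshots = 2L, entropySnapshots = 1L,
                        pb = testPB(gridDensity = 1.5, padding = 4))

  rb <- runCondition(condition("base", "jitter"), registry, cfg, entropy = FALSE)
  expect_equal(nrow(rb$perSnapshot), 2L)
  expect_equal(unname(rb$mean["sub_total"]),
               unname(sum(rb$mean[c("ele", "vdw", "pol", "nonpol")])),
               tolerance = 1e-9)
  expect_equal(unname(rb$mean["total"]),
               unname(rb$mean["sub_total"] + rb$mean["TdS"]), tolerance = 1e-9)

  # constant trajectory: standard deviations vanish
  rx <- runCondition(condition("base", "xray"), registry, cfg, entropy = FALSE)
  expect_equal(unname(rx$sd[c("ele", "vdw", "pol", "nonpol")]), rep(0, 4))

  # swap of the charge set changes ele/pol, leaves vdw/nonpol bit-identical
  rp <- runCondition(condition("polarized", "jitter"), registry, cfg,
                     entropy = FALSE)
  expect_identical(rp$perSnapshot$vdw, rb$perSnapshot$vdw)
  expect_identical(rp$perSnapshot$nonpol, rb$perSnapshot$nonpol)
  expect_false(any(rp$perSnapshot$ele == rb$perSnapshot$ele))
  expect_false(any(rp$perSnapshot$pol == rb$perSnapshot$pol))

  d <- conditionDifference(rp, rb)
  expect_equal(d$vdw, rep(0, 2))
  expect_equal(mean(d$ele), unname(rp$mean["ele"] - rb$mean["ele"]),
               tolerance = 1e-9)
  dz <- conditionDifference(rb, rb)
  expect_true(all(as.matrix(dz[, c("ele", "vdw", "pol", "nonpol")]) == 0))

  tab <- runConditionMatrix(list(condition("base", "jitter"),
                                 condition("polarized", "jitter")),
                            registry, cfg, entropy = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$vdw[1], tab$vdw[2])
  expect_identical(tab$nonpol[1], tab$nonpol[2])

  expect_error(runCondition(condition("nope", "jitter"), registry, cfg),
               "unregistered")
})

test_that("per-residue decomposition sums back to the whole-system components", {
  tc <- cachedFixture("toy_complex")
  topo <- tc$topology
  rec <- atomSelect(topo, "protein")
  lig <- atomSelect(topo, "ligand")
  cfg <- pipelineConfig(snapshots = 1L, entropySnapshots = 1L,
                        pb = testPB(gridDensity = 1.5, padding = 4))
  snap <- makeTrajectory(tc, 1, sigma = 0, seed = 1)
  dec <- perResidueDecomposition(snap, topo, tc$chargeSets$base, rec, lig, cfg)
  sc <- snapshotComponents(tc$native, topo, tc$chargeSets$base,
                           rec, lig, cfg)
  expect_equal(sum(dec$ele), unname(sc["ele"]), tolerance = 1e-6)
  expect_equal(sum(dec$vdw), unname(sc["vdw"]), tolerance = 1e-6)
  expect_equal(sum(dec$pol), unname(sc["pol"]),
               tolerance = 0.02 * max(1, abs(sc["pol"])))
  expect_equal(sum(dec$nonpol), unname(sc["nonpol"]),
               tolerance = 0.02 * max(1, abs(sc["nonpol"])))
  expect_equal(dec$total, rowSums(dec[, c("ele", "vdw", "pol", "nonpol")]),
               tolerance = 1e-9)

  # the designed hydrogen-bonding residues dominate: rank-1 overall, and
  # both leading electrostatic contributions
  a <- atoms(topo)
  protAnchor <- c(tc$hbonds$donor, tc$hbonds$acceptor)
  hbRes <- unique(a$resid[protAnchor[a$segment[protAnchor] == "protein"]])
  resRows <- dec[dec$resname != "LIG", ]
  expect_true(resRows$resid[which.max(abs(resRows$total))] %in% hbRes)
  topEle <- resRows$resid[order(resRows$ele)][1:2]
  expect_true(all(topEle %in% hbRes))
})
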