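# Structure/topology/charge-set I/O and the selection language.

test_that("PDB reading counts atoms and models and flags bad records", {
  onePdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "HETATM    5  C1  LIG A   2       5.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(onePdb, f)
  res <- readStructure(f)
  expect_equal(nAtoms(res$topology), 5L)
  expect_equal(nFrames(res$trajectory), 1L)
  expect_equal(atoms(res$topology)$segment, c(rep("protein", 4), "ligand"))

  multi <- c("MODEL        1", onePdb[1:5], "ENDMDL",
             "MODEL        2", onePdb[1:5], "ENDMDL",
             "MODEL        3", onePdb[1:5], "ENDMDL", "END")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(multi, f2)
  res2 <- readStructure(f2)
  expect_equal(nFrames(res2$trajectory), 3L)
  expect_equal(res2$trajectory@frameIndex, 1:3)

  bad <- onePdb
  bad[2] <- "ATOM      2  CA  ALA A   1       1.4x8   0.000   0.000  1.00  0.00           C"
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f3)
  expect_error(readStructure(f3), "line 2")

  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK empty", "END"), f4)
  expect_error(readStructure(f4), "no ATOM")
})

test_that("waters and ions parse as segment 'other'", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  O   HOH A   2       9.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3 CL    CL A   3      12.000   0.000   0.000  1.00  0.00          CL",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  seg <- atoms(readStructure(f)$topology)$segment
  expect_equal(seg, c("protein", "other", "other"))
})

test_that("structure write/read round-trips coordinates to PDB precision", {
  fx <- cachedFixture("toy_complex")
  traj <- makeTrajectory(fx, 3, sigma = 0.2, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(traj, f)
  back <- readStructure(f)
  expect_equal(nFrames(back$trajectory), 3L)
  expect_lt(max(abs(back$trajectory@coords - traj@coords)), 1e-3)
  expect_equal(atoms(back$topology)$name, atoms(traj)$name)
  expect_equal(atoms(back$topology)$resid, atoms(traj)$resid)
})

test_that("XYZ dialect reads whitespace frames", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1", "C 0 0 0", "O 1.1 0 0",
               "2", "frame 2", "C 0 0 0", "O 1.2 0 0"), f)
  res <- readStructure(f, dialect = "xyz")
  expect_equal(nAtoms(res$topology), 2L)
  expect_equal(nFrames(res$trajectory), 2L)
  expect_equal(frameCoords(res$trajectory, 2)[2, 1], 1.2)
})

test_that("topology JSON round-trips and validates invariants", {
  fx <- cachedFixture("mini_helix", nres = 6)
  f <- withr::local_tempfile(fileext = ".json")
  writeTopology(fx$topology, f)
  back <- readTopology(f)
  expect_equal(back@atoms$charge, fx$topology@atoms$charge)
  expect_equal(back@bonds$r0, fx$topology@bonds$r0)
  expect_equal(nrow(residueTable(back)), 6L)

  # diatomic fixture counts
  di <- cachedFixture("dimer")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeTopology(di$topology, f2)
  d2 <- readTopology(f2)
  expect_equal(nAtoms(d2), 2L)
  expect_equal(nrow(d2@bonds), 1L)

  # non-integer total charge is rejected
  badAtoms <- atoms(di$topology)
  badAtoms$charge <- c(0.4, 0.0)
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(atoms = badAtoms), f3, digits = NA,
                       dataframe = "columns")
  expect_error(readTopology(f3), "integer")

  # missing column is a schema error
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(atoms = badAtoms[, 1:5]), f4, dataframe = "columns")
  expect_error(readTopology(f4), "schema")
})

test_that("charge sets apply, overwrite, and leave other parameters alone", {
  fx <- cachedFixture("toy_complex")
  topo <- fx$topology
  same <- applyChargeSet(topo, fx$chargeSets$base)
  expect_identical(same@atoms, topo@atoms)

  zero <- applyChargeSet(topo, ChargeSet("null", rep(0, nAtoms(topo))))
  expect_true(all(charges(zero) == 0))
  expect_equal(hbondCoulombEnergy(fx$native, fx$hbonds, zero),
               rep(0, 3))

  pol <- applyChargeSet(topo, fx$chargeSets$polarized)
  expect_identical(pol@atoms$rmin_half, topo@atoms$rmin_half)
  expect_identical(pol@atoms$epsilon, topo@atoms$epsilon)
  # second application overwrites, never accumulates
  again <- applyChargeSet(pol, fx$chargeSets$polarized)
  expect_identical(charges(again), charges(pol))
  back <- applyChargeSet(pol, fx$chargeSets$base)
  expect_identical(charges(back), charges(topo))

  expect_error(applyChargeSet(topo, ChargeSet("short", c(0, 0))), "atoms")
})

test_that("charge-set CSV round-trips", {
  fx <- cachedFixture("toy_complex")
  f <- withr::local_tempfile(fileext = ".csv")
  writeChargeSet(fx$chargeSets$polarized, f)
  back <- readChargeSet(f, "polarized")
  expect_equal(charges(back), charges(fx$chargeSets$polarized))
})

test_that("selection grammar resolves structural subsets deterministically", {
  hx <- cachedFixture("mini_helix", nres = 10)
  topo <- hx$topology
  expect_length(atomSelect(topo, "backbone")@indices, 40L)  # 4 per residue
  expect_length(atomSelect(topo, "calpha")@indices, 10L)
  expect_length(atomSelect(topo, "all")@indices, nAtoms(topo))
  expect_length(atomSelect(topo, "none")@indices, 0L)

  tc <- cachedFixture("toy_complex")
  lig <- atomSelect(tc$topology, "segment ligand")
  expect_equal(lig@indices, which(atoms(tc$topology)$segment == "ligand"))

  # residue + atom-name conjunction picks exactly the acceptor oxygens
  a <- atoms(tc$topology)
  for (r in unique(a$resid[tc$hbonds$acceptor[a$segment[tc$hbonds$acceptor] == "protein"]])) {
    sel <- atomSelect(tc$topology, sprintf("resid %d and name O", r))
    expect_equal(sel@indices, which(a$resid == r & a$name == "O" &
                                    a$segment == "protein"))
  }

  expect_length(atomSelect(topo, "resid 2:4 and name CA")@indices, 3L)
  expect_length(atomSelect(topo, "resid 2 to 4 and name CA")@indices, 3L)
  expect_length(atomSelect(topo, "(resid 1 or resid 10) and backbone")@indices, 8L)
  expect_length(atomSelect(topo, "not protein")@indices, 0L)
  expect_error(atomSelect(topo, "resid foo"), "parse")
  expect_error(atomSelect(topo, "bogus"), "parse")
  expect_error(atomSelect(topo, "(backbone"), "parse")
})
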