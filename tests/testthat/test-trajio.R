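test_that("GRO reading parses atoms, coordinates and the box line", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "tiny fixture t= 12.5",
    "    3",
    "    1ALA      N    1   0.100   0.200   0.300",
    "    1ALA     CA    2   0.400   0.500   0.600",
    "    2GLY     CA    3   0.700   0.800   0.900",
    "   5.00000   6.00000   7.00000"), f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 3L)
  expect_equal(atoms(s)$name, c("N", "CA", "CA"))
  expect_equal(atoms(s)$resid, c(1L, 1L, 2L))
  expect_equal(boxDims(s, 1), c(5, 6, 7))
  expect_equal(frameCoords(s, 1)[2, ], c(0.4, 0.5, 0.6))
  expect_equal(frameTimes(s), 12.5)
})

test_that("malformed GRO input fails with informative errors", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("bad", "    1",
               "    1ALA      N    1     nan   0.200   0.300",
               "   5.0   5.0   5.0"), f)
  expect_error(readStructure(f), "line 3")
  g <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("no box", "    1",
               "    1ALA      N    1   0.100   0.200   0.300"), g)
  expect_error(readStructure(g), "box")
  h <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("triclinic", "    1",
               "    1ALA      N    1   0.100   0.200   0.300",
               "  5.0 5.0 5.0 0.0 0.0 1.2 0.0 0.0 0.0"), h)
  expect_error(readStructure(h), "triclinic")
  e <- withr::local_tempfile(fileext = ".gro")
  file.create(e)
  expect_error(readStructure(e), "short")
})

test_that("PDB chains map to segment ids", {
  rb <- makeRigidBody(nParticles = 10,
                      schedule = pitchRampSchedule(0, 0, 1), seed = 1)
  tr <- rb$trajectory
  tr@topology@atoms$segid <- rep(c("A", "B"), each = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(tr, f)
  s <- readStructure(f)
  expect_equal(unique(atoms(s)$segid), c("A", "B"))
  expect_equal(sum(atoms(s)$segid == "A"), 5L)
})

test_that("write/read round-trips preserve coordinates to format precision", {
  rb <- makeRigidBody(nParticles = 40,
                      schedule = pitchRampSchedule(0, 30, 4), seed = 7)
  tr <- rb$trajectory
  fg <- withr::local_tempfile(fileext = ".gro")
  writeGRO(tr, fg)
  tg <- readTrajectory(fg, topologyOf(tr))
  expect_equal(nFrames(tg), 4L)
  expect_lt(max(abs(tg@coords - tr@coords)), 1e-3)  # %8.3f nm
  expect_equal(tg@times, tr@times)
  fp <- withr::local_tempfile(fileext = ".pdb")
  writePDB(tr, fp)
  tp <- readTrajectory(fp, topologyOf(tr))
  expect_equal(nFrames(tp), 4L)
  expect_lt(max(abs(tp@coords - tr@coords)), 1e-4)  # %8.3f Angstrom
  expect_equal(boxDims(tp, 1), boxDims(tr, 1), tolerance = 1e-6)
})

test_that("trajectory reading validates atom counts and formats", {
  rb <- makeRigidBody(nParticles = 12,
                      schedule = pitchRampSchedule(0, 0, 2), seed = 1)
  f <- withr::local_tempfile(fileext = ".gro")
  writeGRO(rb$trajectory, f)
  other <- Topology(name = rep("CA", 5), resid = 1:5)
  expect_error(readTrajectory(f, other), "12")
  expect_error(readTrajectory(f, other), "5")
  x <- withr::local_tempfile(fileext = ".xtc")
  file.create(x)
  expect_error(readTrajectory(x, other), "not supported")
  expect_error(readStructure("/nonexistent/file.gro"), "no such file")
})

test_that("selections resolve the documented mini-language deterministically", {
  # three-chain fixture with a TM-helix residue range per chain
  nres <- 200
  top <- Topology(name = rep("CA", 3 * nres),
                  resname = "ALA",
                  resid = rep(seq_len(nres), 3),
                  segid = rep(c("A", "B", "C"), each = nres))
  selA <- atomSelect(top, "segid A and resid 153-189")
  expect_length(selectionIndices(selA), 37L)
  expect_true(all(atoms(top)$segid[selectionIndices(selA)] == "A"))
  expect_true(all(atoms(top)$resid[selectionIndices(selA)] %in% 153:189))
  expect_error(atomSelect(top, "resid 9999"), "matched no atoms")
  expect_error(atomSelect(top, "chain A"), "unknown selection keyword")

  bl <- makeBilayerSurrogate(c(POPC = 20, CHOL = 5), seed = 3)
  selP <- atomSelect(bl, "name P")
  expect_length(selectionIndices(selP), 40L)  # both leaflets
  expect_true(all(atoms(bl)$name[selectionIndices(selP)] == "P"))

  # stability under an order-preserving file rewrite
  f <- withr::local_tempfile(fileext = ".gro")
  writeGRO(bl, f)
  bl2 <- readStructure(f, isBead = TRUE)
  expect_identical(selectionIndices(atomSelect(bl2, "name P")),
                   selectionIndices(selP))
})

test_that("minimum-image displacement matches the 27-image brute force", {
  expect_equal(
    sqrt(sum(minImageDisplacement(c(0.1, 0, 0), c(5.1, 0, 0),
                                  c(5.2, 5.2, 5.2))^2)), 0.2)
  expect_equal(minImageDisplacement(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5)),
               c(0, 0, 0))
  expect_error(minImageDisplacement(c(0, 0, 0), c(1, 1, 1), c(5, -1, 5)),
               "positive")
  set.seed(42)
  for (i in 1:250) {
    box <- runif(3, 1, 8)
    # in-box points: the 27 translates cover every candidate image
    r1 <- runif(3, 0, 1) * box; r2 <- runif(3, 0, 1) * box
    d <- minImageDisplacement(r1, r2, box)
    expect_equal(d, bruteMinImage(r1, r2, box), tolerance = 1e-12)
    expect_true(all(abs(d) <= box / 2 + 1e-12))
    expect_lte(sum(d^2), sum((r2 - r1)^2) + 1e-12)
  }
})

test_that("cell-list neighbor search equals brute force with and without PBC", {
  set.seed(11)
  for (i in 1:25) {
    box <- runif(3, 2, 9)
    nA <- sample(20:150, 1); nB <- sample(20:300, 1)
    A <- cbind(runif(nA, -3, 12), runif(nA, -3, 12), runif(nA, -3, 12))
    B <- cbind(runif(nB, -3, 12), runif(nB, -3, 12), runif(nB, -3, 12))
    cut <- runif(1, 0.2, 4)
    expect_identical(anyWithin(A, B, cut, box, method = "cell"),
                     anyWithin(A, B, cut, box, method = "brute"))
    expect_identical(anyWithin(A, B, cut, NULL, method = "cell"),
                     anyWithin(A, B, cut, NULL, method = "brute"))
  }
})
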