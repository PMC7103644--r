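test_that("contact boundary is strict and occupancy counts frames", {
  # residue probes (CB == sidechain COM here) at controlled distances from P
  probes <- rbind(c(5, 5, 5.50), c(5, 5, 6.50))
  partner <- matrix(c(5, 5, 5.99), 1, 3)
  tr <- contactFixture(probes, partner)
  cs <- residueLipidContacts(tr, atomSelect(tr, "segid A"),
                             atomSelect(tr, "name P"),
                             contactCriterion(cutoff = 0.5))
  occ <- occupancy(cs)
  expect_equal(occ$occupancy, c(1, 0))   # 0.49 in, 0.51 out (strict <)

  # planted occupancy: contact in 4 of 10 frames
  top <- topologyOf(tr)
  frames <- lapply(1:10, function(f) {
    z <- if (f <= 4) 5.6 else 7.0
    rbind(c(5, 5, z), c(5, 5, z), c(5, 5, 9), c(5, 5, 9), c(5, 5, 5.99))
  })
  tr10 <- Trajectory(top, frames, box = c(10, 10, 10))
  cs10 <- residueLipidContacts(tr10, atomSelect(tr10, "segid A"),
                               atomSelect(tr10, "name P"),
                               contactCriterion(cutoff = 0.5))
  expect_equal(occupancy(cs10)$occupancy, c(0.4, 0))
  expect_equal(nFrames(cs10), 10L)
})

test_that("glycine-style residues fall back to CA and are flagged", {
  top <- Topology(name = c("CA", "CA", "CB", "P"),
                  resname = c("GLY", "ALA", "ALA", "POPC"),
                  resid = c(1, 2, 2, 3), segid = c("A", "A", "A", "M"))
  tr <- Trajectory(top, rbind(c(1, 1, 1), c(3, 3, 3), c(3, 3, 3.2),
                              c(1, 1, 1.3)), box = c(8, 8, 8))
  cs <- residueLipidContacts(tr, atomSelect(tr, "segid A"),
                             atomSelect(tr, "name P"),
                             contactCriterion(cutoff = 0.5))
  occ <- occupancy(cs)
  expect_true(occ$fallback[occ$resname == "GLY"])
  expect_false(occ$fallback[occ$resname == "ALA"])
  expect_equal(occ$occupancy, c(1, 0))
})

test_that("per-type CG contacts resolve lipid species independently", {
  # protein: one BB + one SC1 bead residue; GM3 close, POPC far
  top <- Topology(name = c("BB", "SC1", "GM", "P", "P"),
                  resname = c("CPY", "CPY", "GM3", "POPC", "POPS"),
                  resid = c(1, 1, 2, 3, 4),
                  segid = c("A", "A", "M", "M", "M"), isBead = TRUE)
  xyz <- rbind(c(5, 5, 5), c(5, 5, 5.3), c(5, 5, 5.8),  # GM3 0.5 from SC1
               c(5, 5, 8), c(5, 5.55, 5.3))             # POPS 0.55 from SC1
  tr <- Trajectory(top, replicate(4, xyz, simplify = FALSE), box = c(10, 10, 10))
  res <- cgLipidContacts(tr, atomSelect(tr, "segid A"),
                         c("GM3", "POPC", "POPS"), cutoff = 0.65)
  expect_named(res, c("GM3", "POPC", "POPS"))
  expect_equal(occupancy(res$GM3)$occupancy, 1)
  expect_equal(occupancy(res$POPC)$occupancy, 0)
  expect_equal(occupancy(res$POPS)$occupancy, 1)  # equal-distance types count independently
  expect_error(cgLipidContacts(tr, atomSelect(tr, "segid A"), "PIP2"),
               "unknown lipid type")
})

test_that("randomized lipid-contact scenes match the all-pairs oracle", {
  set.seed(23)
  for (rep in 1:5) {
    box <- c(6, 6, 6)
    np <- 30; nl <- 80
    probes <- cbind(runif(np, 0, 6), runif(np, 0, 6), runif(np, 0, 6))
    lipids <- cbind(runif(nl, 0, 6), runif(nl, 0, 6), runif(nl, 0, 6))
    tr <- contactFixture(probes, lipids, box = box)
    cs <- residueLipidContacts(tr, atomSelect(tr, "segid A"),
                               atomSelect(tr, "name P"),
                               contactCriterion(cutoff = 0.65))
    # oracle: explicit double loop over probes and partners, 27 images
    want <- vapply(seq_len(np), function(i) {
      any(vapply(seq_len(nl), function(j) {
        d <- bruteMinImage(probes[i, ], lipids[j, ], box)
        sqrt(sum(d^2)) < 0.65
      }, logical(1)))
    }, logical(1))
    expect_identical(unname(cs@hits[, 1]), want)
  }
})

test_that("protein-protein occupancy finds planted interfaces, rejects overlap", {
  sc <- makeMulticopyScene(planted = c(2, 1, 1), nFrames = 5, seed = 3)
  tr <- sc$trajectory
  occ <- proteinProteinContacts(tr, sc$copies, cutoff = 0.65)
  # dimer interface: tip of copy 1, base of copy 2, in contact every frame
  o11 <- occ[occ$copy == 1, ]
  expect_equal(o11$occupancy[o11$resid == 4], 1)  # tip bead B4
  expect_equal(o11$occupancy[o11$resid == 1], 0)  # far end
  expect_true(all(occ$occupancy[occ$copy %in% c(3, 4)] == 0))
  mask <- thresholdMask(occ, 0.025)
  expect_setequal(mask$copy, c(1, 2))
  expect_error(proteinProteinContacts(tr, list(sc$copies[[1]],
                                               sc$copies[[1]])), "overlap")
  expect_error(proteinProteinContacts(tr, sc$copies[1]), "at least two")
})

test_that("multi-copy contact occupancies equal a brute-force oracle", {
  set.seed(31)
  box <- c(5, 5, 5)
  nCopies <- 4
  xyz <- lapply(1:nCopies, function(i)
    cbind(runif(6, 0, 5), runif(6, 0, 5), runif(6, 0, 5)))
  top <- Topology(name = rep(paste0("B", 1:6), nCopies), resname = "CPY",
                  resid = rep(1:6, nCopies),
                  segid = rep(LETTERS[1:nCopies], each = 6), isBead = TRUE)
  tr <- Trajectory(top, do.call(rbind, xyz), box = box)
  copies <- lapply(1:nCopies, function(i)
    atomSelect(tr, paste("segid", LETTERS[i])))
  occ <- proteinProteinContacts(tr, copies, cutoff = 1.2)
  for (ci in 1:nCopies) for (ri in 1:6) {
    mine <- xyz[[ci]][ri, , drop = FALSE]
    others <- do.call(rbind, xyz[-ci])
    want <- any(vapply(seq_len(nrow(others)), function(j)
      sqrt(sum(bruteMinImage(mine[1, ], others[j, ], box)^2)) < 1.2,
      logical(1)))
    expect_equal(occ$occupancy[occ$copy == ci & occ$resid == ri],
                 as.numeric(want))
  }
})

test_that("threshold masking is strictly greater-than, sorted descending", {
  tab <- data.frame(resid = 1:3, occupancy = c(0.026, 0.025, 0))
  out <- thresholdMask(tab, 0.025)
  expect_equal(out$resid, 1L)
  expect_equal(nrow(thresholdMask(data.frame(resid = 1:2,
                                             occupancy = c(0, 0)))), 0L)
  all3 <- thresholdMask(data.frame(resid = 1:3,
                                   occupancy = c(0.3, 0.1, 0.2)), 0)
  expect_equal(all3$resid, c(1L, 3L, 2L))  # descending occupancy
})

test_that("occupancy is frame-order invariant; pooling equals per-run mean", {
  probes <- rbind(c(5, 5, 5))
  partner <- matrix(c(5, 5, 5.3), 1, 3)
  tr <- contactFixture(probes, partner)
  top <- topologyOf(tr)
  mkTraj <- function(zs) Trajectory(top, lapply(zs, function(z)
    rbind(c(5, 5, z), c(5, 5, z), c(5, 5, 5.3))), box = c(10, 10, 10))
  sel <- function(t) atomSelect(t, "segid A")
  par <- function(t) atomSelect(t, "name P")
  crit <- contactCriterion(cutoff = 0.5)
  zs <- c(5.1, 7, 5.2, 7, 7)
  a <- residueLipidContacts(mkTraj(zs), sel(mkTraj(zs)), par(mkTraj(zs)), crit)
  b <- residueLipidContacts(mkTraj(rev(zs)), sel(mkTraj(zs)),
                            par(mkTraj(zs)), crit)
  expect_equal(occupancy(a)$occupancy, occupancy(b)$occupancy)
  # pooled occupancy over equal-length replicas = mean of per-replica
  r1 <- residueLipidContacts(mkTraj(c(5.1, 7, 7, 7)), sel(mkTraj(zs)),
                             par(mkTraj(zs)), crit)
  r2 <- residueLipidContacts(mkTraj(c(5.1, 5.2, 7, 7)), sel(mkTraj(zs)),
                             par(mkTraj(zs)), crit)
  pooled <- poolContactSeries(list(r1, r2))
  expect_equal(pooled$occupancy,
               (occupancy(r1)$occupancy + occupancy(r2)$occupancy) / 2)
})
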