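# Independent oracles used across the suite.  These deliberately use naive
# formulations (double loops, exhaustive image search, transitive closure)
# so they share no code with the implementation they check.

# Moment-of-inertia tensor by explicit double loop over atoms and basis
# vectors: I = sum_i m_i [ (r_i.r_i) sum_a e_a (x) e_a - r_i (x) r_i ].
bruteInertia <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  I <- matrix(0, 3, 3)
  E <- diag(3)
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, ] - com
    outerSum <- matrix(0, 3, 3)
    for (a in 1:3) outerSum <- outerSum + E[, a] %*% t(E[, a])
    I <- I + masses[i] * (sum(r * r) * outerSum - r %*% t(r))
  }
  I
}

# Minimum-image displacement by exhaustive search over the 27 periodic
# translates of r2.
bruteMinImage <- function(r1, r2, box) {
  best <- NULL; bestD <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (r2 + c(ix, iy, iz) * box) - r1
    if (sum(d^2) < bestD) { bestD <- sum(d^2); best <- d }
  }
  best
}

# Torsion by the Gram-Schmidt projection formulation (independent of the
# cross-product construction in the package).
projDihedral <- function(p1, p2, p3, p4) {
  a1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  b2n <- b2 / sqrt(sum(b2^2))
  u <- a1 - sum(a1 * b2n) * b2n     # component of p1-p2 normal to the bond
  w <- b3 - sum(b3 * b2n) * b2n
  cr <- c(b2n[2] * u[3] - b2n[3] * u[2],
          b2n[3] * u[1] - b2n[1] * u[3],
          b2n[1] * u[2] - b2n[2] * u[1])
  atan2(sum(cr * w), sum(u * w)) * 180 / pi
}

# Connected components by brute-force transitive closure of the adjacency
# matrix.
closureComponents <- function(edges, n) {
  A <- diag(TRUE, n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- TRUE
    A[edges[k, 2], edges[k, 1]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  vapply(seq_len(n), function(i) min(which(A[i, ])), integer(1))
}

# Random proper rotation from a normalized quaternion.
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# A small atomistic-style fixture: one "protein" chain of nRes one-atom
# sidechain residues at given positions plus partner atoms, as a Trajectory.
contactFixture <- function(probePos, partnerPos, box = c(10, 10, 10),
                           nFramesContact = NULL) {
  np <- nrow(probePos); nl <- nrow(partnerPos)
  top <- Topology(
    name = c(rep(c("CA", "CB"), np), rep("P", nl)),
    resname = c(rep("ALA", 2 * np), rep("POPC", nl)),
    resid = c(rep(seq_len(np), each = 2), np + seq_len(nl)),
    segid = c(rep("A", 2 * np), rep("M", nl)))
  coords <- rbind(probePos[rep(seq_len(np), each = 2), , drop = FALSE],
                  partnerPos)
  Trajectory(top, coords, box = box)
}
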