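#' Synthetic rigid body on a programmed orientation schedule
#'
#' Generates an anisotropic particle cloud, expresses it exactly in its own
#' principal frame (long axis along x, so the frame-0 principal axes
#' coincide with the standard basis), then renders each frame as the body
#' rotated by \code{Rz(yaw) Ry(pitch) Rx(roll)} about its center of mass,
#' plus optional isotropic Gaussian noise.  The schedule is the ground
#' truth an orientation analysis should recover.
#'
#' @param nParticles number of particles (default 500)
#' @param schedule data.frame with columns \code{yaw}, \code{pitch},
#'   \code{roll} in degrees, one row per frame (see [pitchRampSchedule()]
#'   and [stationaryPitchSchedule()])
#' @param halfAxes length-3 decreasing scales (nm) of the Gaussian cloud;
#'   must be clearly anisotropic for the angles to be observable
#' @param noiseSd isotropic per-particle, per-frame Gaussian noise, nm
#' @param box orthorhombic box edges, nm
#' @param dt frame spacing, ps
#' @param seed RNG seed (fixed seed gives identical output)
#' @return list: \code{trajectory} ([Trajectory-class]), \code{truth}
#'   (the schedule with a \code{time} column)
#' @export
makeRigidBody <- function(nParticles = 500L,
                          schedule = pitchRampSchedule(0, 60, 100L),
                          halfAxes = c(2.0, 0.8, 0.4), noiseSd = 0,
                          box = c(15, 15, 15), dt = 1, seed = 1L) {
  stopifnot(nParticles >= 4L, noiseSd >= 0)
  restore <- localRNG(seed)
  on.exit(restore())
  gaps <- abs(diff(sort(halfAxes))) / max(halfAxes)
  anyAngle <- any(abs(as.matrix(schedule[, c("yaw", "pitch", "roll")])) > 1e-12)
  if (any(gaps < 0.05) && anyAngle)
    stop("near-isotropic body: programmed angles would be unobservable")
  base <- cbind(stats::rnorm(nParticles, 0, halfAxes[1]),
                stats::rnorm(nParticles, 0, halfAxes[2]),
                stats::rnorm(nParticles, 0, halfAxes[3]))
  el <- sample(c("C", "N", "O"), nParticles, replace = TRUE)
  masses <- inferMasses(el)
  # exact principal frame: subtract COM, rotate onto principal axes
  I0 <- inertiaTensor(base, masses)
  P <- principalAxes(I0)$axes
  body <- sweep(base, 2, I0$center) %*% P
  center <- box / 2
  nf <- nrow(schedule)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    R <- eulerZYX(schedule$yaw[f], schedule$pitch[f], schedule$roll[f])
    xyz <- body %*% t(R)
    if (noiseSd > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * nParticles, 0, noiseSd),
                          nParticles, 3)
    frames[[f]] <- sweep(xyz, 2, center, "+")
  }
  top <- Topology(name = el, resname = "BDY",
                  resid = seq_len(nParticles), segid = "A", mass = masses)
  traj <- Trajectory(top, frames, box = box,
                     times = (seq_len(nf) - 1) * dt)
  truth <- cbind(time = traj@times, schedule)
  list(trajectory = traj, truth = truth)
}

#' Orientation schedules for the rigid-body generator
#'
#' \code{pitchRampSchedule}: pitch ramps linearly between two angles with
#' yaw = roll = 0.  \code{stationaryPitchSchedule}: pitch drawn i.i.d. from
#' a normal distribution truncated to [-90, 90]; the default spread
#' (1.5 degrees) keeps the population mode bin well separated from its
#' neighbors at 1-degree binning for a few thousand frames.
#'
#' @param from,to ramp endpoints, degrees
#' @param nFrames number of frames
#' @return data.frame with columns \code{yaw}, \code{pitch}, \code{roll}
#' @export
pitchRampSchedule <- function(from, to, nFrames) {
  data.frame(yaw = 0, pitch = seq(from, to, length.out = nFrames), roll = 0)
}

#' @rdname pitchRampSchedule
#' @param mean,sd normal parameters of the stationary pitch, degrees
#' @param seed RNG seed
#' @export
stationaryPitchSchedule <- function(mean = 30, sd = 1.5, nFrames = 5000L,
                                    seed = 1L) {
  restore <- localRNG(seed)
  on.exit(restore())
  p <- stats::rnorm(nFrames, mean, sd)
  while (any(bad <- abs(p) > 90))
    p[bad] <- stats::rnorm(sum(bad), mean, sd)
  data.frame(yaw = 0, pitch = p, roll = 0)
}

#' Ideal tilted helix (C-alpha trace)
#'
#' Builds an ideal helical C-alpha trace (rise 0.15 nm and 100 degrees of
#' twist per residue, radius 0.23 nm), then tilts its axis away from +z by
#' the requested angle in the plane set by \code{azimuth}.  Whole numbers
#' of turns (multiples of 3.6 residues) keep the point cloud's principal
#' axis exactly on the helix axis; the default 36 residues is ten turns.
#'
#' @param nResidues number of residues (>= 8)
#' @param tilt tilt from the membrane normal, degrees, in [0, 90]
#' @param azimuth direction of the tilt in the membrane plane, degrees
#' @param radius,rise,twist helix geometry (nm, nm, degrees per residue)
#' @param box orthorhombic box, nm
#' @return a one-frame [Trajectory-class] with atoms named CA
#' @export
makeIdealHelix <- function(nResidues = 36L, tilt = 0, azimuth = 0,
                           radius = 0.23, rise = 0.15, twist = 100,
                           box = c(9, 9, 9)) {
  if (nResidues < 8L) stop("need at least 8 residues (about two turns)")
  if (tilt < 0 || tilt > 90)
    stop("tilt must lie in [0, 90] degrees (tilt is sign-free)")
  i <- seq_len(nResidues) - 1
  th <- i * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), i * rise)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  R <- rotZ(azimuth) %*% rotY(tilt)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, box / 2, "+")
  top <- Topology(name = rep("CA", nResidues), resname = "ALA",
                  resid = seq_len(nResidues), segid = "A", mass = 12.011)
  Trajectory(top, xyz, box = box)
}

#' Ideal polypeptide backbone from internal coordinates
#'
#' Builds an N-CA-C backbone chain by sequential placement (natural
#' extension of reference frame) from canonical bond lengths (N-CA 0.1458,
#' CA-C 0.1525, C-N 0.1329 nm), bond angles (N-CA-C 111.2, CA-C-N 116.2,
#' C-N-CA 121.7 degrees) and the requested phi/psi torsions with omega
#' fixed at 180 degrees.  The alpha-helical defaults are phi = -57,
#' psi = -47 degrees.
#'
#' @param nResidues chain length
#' @param phi,psi backbone torsions, degrees (scalar or per residue)
#' @param box orthorhombic box, nm
#' @return a one-frame [Trajectory-class] with atoms N, CA, C per residue
#' @export
makeAlphaHelixBackbone <- function(nResidues = 12L, phi = -57, psi = -47,
                                   box = c(9, 9, 9)) {
  stopifnot(nResidues >= 2L)
  phi <- rep_len(phi, nResidues); psi <- rep_len(psi, nResidues)
  bNCA <- 0.1458; bCAC <- 0.1525; bCN <- 0.1329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  place <- function(A, B, C, bond, angle, torsion) {
    th <- angle * pi / 180; ph <- torsion * pi / 180
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
    m <- cross3(n, bc)
    d <- c(-bond * cos(th), bond * sin(th) * cos(ph),
           bond * sin(th) * sin(ph))
    C + d[1] * bc + d[2] * m + d[3] * n
  }
  coords <- matrix(NA_real_, 3L * nResidues, 3L)
  coords[1, ] <- c(0, 0, 0)                        # N1
  coords[2, ] <- c(bNCA, 0, 0)                     # CA1
  th <- aNCAC * pi / 180
  coords[3, ] <- coords[2, ] + bCAC * c(-cos(th), sin(th), 0)  # C1
  for (r in 2:nResidues) {
    iN <- 3L * (r - 1L) + 1L
    pN <- coords[iN - 3L, ]; pCA <- coords[iN - 2L, ]; pC <- coords[iN - 1L, ]
    N2 <- place(pN, pCA, pC, bCN, aCACN, psi[r - 1L])
    CA2 <- place(pCA, pC, N2, bNCA, aCNCA, 180)
    C2 <- place(pC, N2, CA2, bCAC, aNCAC, phi[r])
    coords[iN, ] <- N2; coords[iN + 1L, ] <- CA2; coords[iN + 2L, ] <- C2
  }
  coords <- sweep(coords, 2, colMeans(coords))
  coords <- sweep(coords, 2, box / 2, "+")
  top <- Topology(name = rep(c("N", "CA", "C"), nResidues),
                  resname = "ALA", resid = rep(seq_len(nResidues), each = 3),
                  segid = "A")
  Trajectory(top, coords, box = box)
}

#' Planar bilayer surrogate with typed headgroup marker sites
#'
#' Two leaflet lattices of lipid headgroup markers at +/- the leaflet
#' offset from the box midplane, typed by lipid residue name and jittered
#' by seeded Gaussian noise.  Phospholipids (POPC, POPE, POPS, PIP2, Sph)
#' carry a phosphorus-like "P" site; POPC additionally carries a
#' nitrogen-like "N" choline site displaced outward; cholesterol carries
#' "ROH" and GM3 a "GM" site.  Types are distributed randomly over lattice
#' positions.
#'
#' @param upper,lower named integer vectors of lipid counts per type, e.g.
#'   \code{c(POPC = 40, POPE = 10, Sph = 15, GM3 = 10, CHOL = 25)}
#' @param box orthorhombic box, nm; lateral capacity is checked against a
#'   minimum headgroup spacing of 0.6 nm
#' @param leafletOffset distance of each headgroup plane from the box
#'   midplane, nm
#' @param jitter in-plane and vertical Gaussian jitter, nm
#' @param seed RNG seed
#' @return a one-frame [Trajectory-class] of coarse-grained marker beads
#' @export
makeBilayerSurrogate <- function(upper, lower = upper, box = c(9, 9, 9),
                                 leafletOffset = 2.0, jitter = 0.02,
                                 seed = 1L) {
  restore <- localRNG(seed)
  on.exit(restore())
  if (any(upper < 0) || any(lower < 0)) stop("lipid counts must be >= 0")
  capacity <- floor(box[1] / 0.6) * floor(box[2] / 0.6)
  buildLeaflet <- function(counts, z, outward) {
    counts <- counts[counts > 0]
    n <- sum(counts)
    if (n == 0L) return(NULL)
    if (n > capacity)
      stop(sprintf("%d lipids exceed lattice capacity %d for this box",
                   n, capacity))
    side <- ceiling(sqrt(n))
    gx <- (seq_len(side) - 0.5) / side * box[1]
    gy <- (seq_len(side) - 0.5) / side * box[2]
    pos <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n), , drop = FALSE]
    pos <- pos[sample(n), , drop = FALSE]
    types <- rep(names(counts), counts)
    name <- character(0); resname <- character(0); resid <- integer(0)
    xyz <- NULL
    for (k in seq_len(n)) {
      ty <- types[k]
      p0 <- c(pos[k, ], z) + stats::rnorm(3, 0, jitter)
      site <- switch(ty, CHOL = "ROH", GM3 = "GM", "P")
      name <- c(name, site); resname <- c(resname, ty)
      resid <- c(resid, k); xyz <- rbind(xyz, p0)
      if (ty == "POPC") {
        name <- c(name, "N"); resname <- c(resname, ty); resid <- c(resid, k)
        xyz <- rbind(xyz, p0 + c(0, 0, outward * 0.12))
      }
    }
    list(name = name, resname = resname, resid = resid, xyz = xyz)
  }
  up <- buildLeaflet(upper, box[3] / 2 + leafletOffset, +1)
  lo <- buildLeaflet(lower, box[3] / 2 - leafletOffset, -1)
  parts <- Filter(Negate(is.null), list(up, lo))
  if (length(parts) == 0L) {
    top <- Topology(name = character(0), resname = character(0),
                    resid = integer(0), segid = character(0),
                    mass = numeric(0), isBead = logical(0))
    return(Trajectory(top, array(numeric(0), c(0, 3, 1)), box = box))
  }
  name <- unlist(lapply(parts, `[[`, "name"))
  resname <- unlist(lapply(parts, `[[`, "resname"))
  nUp <- if (is.null(up)) 0L else max(up$resid)
  resid <- c(if (!is.null(up)) up$resid,
             if (!is.null(lo)) lo$resid + nUp)
  xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  top <- Topology(name = name, resname = resname, resid = resid,
                  segid = "MEMB", isBead = TRUE)
  Trajectory(top, xyz, box = box)
}

#' Multi-copy coarse-grained scene with planted oligomer clusters
#'
#' Places \code{sum(planted)} protein copies (each a four-bead rod with
#' distinguishable base "B1" and tip "B4" beads) in the membrane plane.
#' Copies of one planted cluster form an end-on chain with tip-base gaps
#' well inside the contact cutoff; distinct clusters are separated by at
#' least twice the cutoff, so single-linkage clustering at the generating
#' cutoff recovers the planted partition exactly in static mode.
#'
#' @param planted integer cluster sizes, summing to the number of copies
#'   (e.g. \code{c(3, 2, rep(1, 31))} for a trimer, a dimer and 31
#'   monomers)
#' @param box orthorhombic box, nm
#' @param nFrames frames to render
#' @param diffusionSd per-frame random-walk step (nm) per copy; 0 (static)
#'   guarantees the planted partition at every frame, positive drift does
#'   not
#' @param cutoff the contact cutoff (nm) the placement is built around
#' @param dt frame spacing, ps
#' @param seed RNG seed
#' @return list: \code{trajectory}, \code{copies} (list of
#'   [Selection-class], one per copy), \code{truth} (data.frame
#'   \code{copy}, \code{cluster} with lowest-member cluster ids)
#' @export
makeMulticopyScene <- function(planted = c(3, 2, rep(1, 31)),
                               box = c(30, 30, 10), nFrames = 10L,
                               diffusionSd = 0, cutoff = 0.65, dt = 1,
                               seed = 1L) {
  restore <- localRNG(seed)
  on.exit(restore())
  planted <- as.integer(planted)
  if (any(planted < 1L)) stop("planted cluster sizes must be >= 1")
  nCopies <- sum(planted)
  rod <- cbind(c(0, 0.3, 0.6, 0.9), 0, 0)      # B1..B4 along +x
  gap <- 0.6 * cutoff                           # tip-base gap inside cutoff
  pitchX <- 0.9 + gap
  margin <- 2 * cutoff + 0.5                    # inter-cluster spacing floor
  rowH <- margin
  z0 <- box[3] / 2
  segPool <- c(LETTERS, 0:9, letters)
  coords0 <- vector("list", nCopies)
  truth <- integer(nCopies)
  # shelf packing: rows of chains, per-cluster width, >= 2*cutoff apart
  xcur <- margin; ycur <- margin
  ci <- 1L
  for (k in seq_along(planted)) {
    extent <- (planted[k] - 1L) * pitchX + 0.9
    w <- extent + margin
    if (xcur + w > box[1]) { xcur <- margin; ycur <- ycur + rowH }
    if (ycur + rowH > box[2] || w + margin > box[1])
      stop(sprintf(
        "cannot pack %d clusters (max chain %.1f nm) into a %g x %g nm box",
        length(planted), extent, box[1], box[2]))
    first <- ci
    for (m in seq_len(planted[k])) {
      coords0[[ci]] <- sweep(rod, 2,
        c(xcur + (m - 1L) * pitchX, ycur, z0), "+")
      truth[ci] <- first
      ci <- ci + 1L
    }
    xcur <- xcur + w
  }
  nAt <- 4L * nCopies
  frames <- vector("list", nFrames)
  drift <- matrix(0, nCopies, 3)
  for (f in seq_len(nFrames)) {
    if (diffusionSd > 0 && f > 1L)
      drift <- drift + cbind(matrix(stats::rnorm(2 * nCopies, 0,
                                                 diffusionSd), nCopies, 2), 0)
    xyz <- do.call(rbind, lapply(seq_len(nCopies), function(i)
      sweep(coords0[[i]], 2, drift[i, ], "+")))
    frames[[f]] <- xyz
  }
  seg <- rep(segPool[seq_len(nCopies)], each = 4L)
  top <- Topology(name = rep(c("B1", "B2", "B3", "B4"), nCopies),
                  resname = "CPY",
                  resid = rep(1:4, nCopies), segid = seg, isBead = TRUE)
  traj <- Trajectory(top, frames, box = box,
                     times = (seq_len(nFrames) - 1) * dt)
  copies <- lapply(seq_len(nCopies), function(i)
    new("Selection", label = paste0("copy", i),
        indices = as.integer((i - 1L) * 4L + 1:4)))
  list(trajectory = traj, copies = copies,
       truth = data.frame(copy = seq_len(nCopies), cluster = truth))
}
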