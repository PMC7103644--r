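#' Dominant axis of a helix backbone
#'
#' Estimates the helix axis by averaging local axis vectors built from
#' successive backbone second differences (for four consecutive atoms the
#' second differences are radial, so their cross product lies exactly on
#' the local helix axis), the construction used by classical helix-geometry
#' tools.  For an ideal helix this is exact regardless of length or phase,
#' unlike the principal axis of the raw point cloud, which carries a phase
#' bias of up to about half a degree at transmembrane-helix lengths.
#' Degenerate (near-straight-line) backbones fall back to the
#' smallest-moment principal axis.  The sign is chosen so the axis points
#' from the first toward the last atom.
#'
#' @param coords \code{n x 3} backbone (e.g. C-alpha) coordinates, nm;
#'   at least 8 atoms (about two turns)
#' @return unit length-3 vector
#' @export
helixAxis <- function(coords) {
  coords <- asCoordMatrix(coords)
  n <- nrow(coords)
  if (n < 8L)
    stop("need at least 8 backbone atoms to define a helix axis")
  # second differences: radial vectors for an ideal helix
  d2 <- coords[1:(n - 2), ] - 2 * coords[2:(n - 1), ] + coords[3:n, ]
  local <- matrix(NA_real_, n - 3L, 3L)
  for (i in seq_len(n - 3L)) local[i, ] <- cross3(d2[i, ], d2[i + 1L, ])
  nrm <- sqrt(rowSums(local^2))
  keep <- nrm > 1e-12
  ax <- if (any(keep)) colSums(local[keep, , drop = FALSE] / nrm[keep])
        else c(0, 0, 0)
  if (sqrt(sum(ax^2)) < 0.5 * sum(keep) || !any(keep)) {
    # degenerate winding: fall back to the long principal axis
    I <- inertiaTensor(coords, rep(1, n))
    ax <- principalAxes(I)$axes[, 1]
  }
  ends <- coords[n, ] - coords[1, ]
  if (sum(ax * ends) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Helix tilt angle against the membrane normal
#'
#' \code{acos(|axis . normal|)} in degrees, folded to [0, 90] so the tilt is
#' independent of the axis sign.
#'
#' @param axis helix axis vector (any length > 0)
#' @param normal membrane normal (default +z, the usual planar-bilayer
#'   convention)
#' @return tilt in degrees, in [0, 90]
#' @export
tiltAngle <- function(axis, normal = c(0, 0, 1)) {
  na <- sqrt(sum(axis^2)); nn <- sqrt(sum(normal^2))
  if (na == 0 || nn == 0) stop("zero vector has no direction")
  acos(min(1, abs(sum(axis * normal)) / (na * nn))) * 180 / pi
}

#' Per-frame helix tilt series
#'
#' @param traj a [Trajectory-class]
#' @param selection backbone atoms of one helix ([Selection-class] or
#'   selection string)
#' @param normal membrane normal
#' @return data.frame: \code{time} (ps), \code{tilt} (degrees)
#' @export
tiltSeries <- function(traj, selection, normal = c(0, 0, 1)) {
  if (is.character(selection)) selection <- atomSelect(traj, selection)
  tl <- vapply(seq_len(nFrames(traj)), function(f)
    tiltAngle(helixAxis(frameCoords(traj, f, selection)), normal),
    numeric(1))
  data.frame(time = frameTimes(traj), tilt = tl)
}

#' RMSD with optional Kabsch superposition
#'
#' Root-mean-square deviation between two conformations of the same atom
#' set.  With \code{superpose = TRUE} the optimal rigid-body rotation and
#' translation (proper rotation only, via SVD) minimizing the RMSD is
#' applied first.
#'
#' @param mobile,target \code{M x 3} coordinate matrices, nm, same ordering
#' @param superpose apply optimal superposition first (default TRUE)
#' @return RMSD in nm
#' @export
kabschRMSD <- function(mobile, target, superpose = TRUE) {
  mobile <- asCoordMatrix(mobile); target <- asCoordMatrix(target)
  if (nrow(mobile) != nrow(target))
    stop("mobile and target must have the same atom count")
  if (superpose) {
    if (nrow(mobile) < 3L) stop("superposition needs at least 3 atoms")
    mobile <- kabschFit(mobile, target)
  }
  sqrt(mean(rowSums((mobile - target)^2)))
}

# Superpose mobile onto target (Kabsch, proper rotation).
kabschFit <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(crossprod(P, Q))                  # H = P^T Q
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2, ct, "+")
}

#' Per-frame C-alpha RMSD series against a reference frame
#'
#' @param traj a [Trajectory-class]
#' @param selection atoms to compare ([Selection-class] or string)
#' @param referenceFrame frame index used as target (default 1)
#' @param superpose superpose before measuring (default TRUE)
#' @return data.frame: \code{time} (ps), \code{rmsd} (nm)
#' @export
rmsdSeries <- function(traj, selection, referenceFrame = 1L,
                       superpose = TRUE) {
  if (is.character(selection)) selection <- atomSelect(traj, selection)
  ref <- frameCoords(traj, referenceFrame, selection)
  r <- vapply(seq_len(nFrames(traj)), function(f)
    kabschRMSD(frameCoords(traj, f, selection), ref, superpose), numeric(1))
  data.frame(time = frameTimes(traj), rmsd = r)
}

#' Torsion angle of four points
#'
#' Signed dihedral in degrees, in (-180, 180], by the standard
#' atan2(cross, dot) construction.  Degenerate (collinear) tetrads return
#' \code{NA}.
#'
#' @param p1,p2,p3,p4 length-3 positions
#' @return angle in degrees, or NA when undefined
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  atan2(sum(cross3(n1, n2) * b2n), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone phi/psi dihedral series (Ramachandran input)
#'
#' For each selected residue, phi = C(i-1)-N(i)-CA(i)-C(i) and
#' psi = N(i)-CA(i)-C(i)-N(i+1).  Terminal residues, residues with missing
#' backbone atoms, and degenerate geometries yield \code{NA} entries rather
#' than errors.
#'
#' @param traj a [Trajectory-class] whose topology carries N, CA, C atoms
#' @param selection residues to analyze (Selection, selection string, or
#'   NULL for all residues)
#' @return data.frame: \code{time}, \code{resid}, \code{resname},
#'   \code{segid}, \code{phi}, \code{psi} (degrees)
#' @export
backboneDihedrals <- function(traj, selection = NULL) {
  top <- topologyOf(traj)
  a <- atoms(top)
  if (is.character(selection)) selection <- atomSelect(traj, selection)
  res <- residueTable(top, NULL)
  wanted <- if (is.null(selection)) seq_len(nrow(res)) else {
    sidx <- selection@indices
    which(vapply(res$atomIdx, function(ii) any(ii %in% sidx), logical(1)))
  }
  pick <- function(ri, nm) {
    ii <- res$atomIdx[[ri]]
    j <- ii[a$name[ii] == nm]
    if (length(j)) j[1] else NA_integer_
  }
  out <- list()
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    for (ri in wanted) {
      sameSeg <- function(k) k >= 1 && k <= nrow(res) &&
        res$segid[k] == res$segid[ri]
      iN <- pick(ri, "N"); iCA <- pick(ri, "CA"); iC <- pick(ri, "C")
      phi <- psi <- NA_real_
      if (!anyNA(c(iN, iCA, iC))) {
        if (sameSeg(ri - 1L)) {
          iCp <- pick(ri - 1L, "C")
          if (!is.na(iCp))
            phi <- torsionAngle(xyz[iCp, ], xyz[iN, ], xyz[iCA, ], xyz[iC, ])
        }
        if (sameSeg(ri + 1L)) {
          iNn <- pick(ri + 1L, "N")
          if (!is.na(iNn))
            psi <- torsionAngle(xyz[iN, ], xyz[iCA, ], xyz[iC, ], xyz[iNn, ])
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        time = frameTimes(traj)[f], resid = res$resid[ri],
        resname = res$resname[ri], segid = res$segid[ri],
        phi = phi, psi = psi, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Minimum-distance time series between two atom groups
#'
#' Per frame, either the minimum over all pairs (\code{mode = "min"}) or the
#' distance from the mass-weighted COM of group A to the nearest atom of
#' group B (\code{mode = "com"}, e.g. sidechain-oxygen COM to the nearest
#' lipid nitrogen).  Distances use the minimum image when the frame has a
#' box.
#'
#' @param traj a [Trajectory-class]
#' @param groupA,groupB [Selection-class] or selection strings
#' @param mode "min" or "com"
#' @return data.frame: \code{time} (ps), \code{distance} (nm)
#' @export
minDistanceSeries <- function(traj, groupA, groupB,
                              mode = c("min", "com")) {
  mode <- match.arg(mode)
  if (is.character(groupA)) groupA <- atomSelect(traj, groupA)
  if (is.character(groupB)) groupB <- atomSelect(traj, groupB)
  mA <- atoms(traj)$mass[groupA@indices]
  d <- vapply(seq_len(nFrames(traj)), function(f) {
    box <- boxDims(traj, f)
    if (anyNA(box)) box <- NULL
    A <- frameCoords(traj, f, groupA)
    B <- frameCoords(traj, f, groupB)
    if (mode == "com") A <- matrix(centerOfMass(A, mA), 1, 3)
    min(minDistToSet(A, B, box))
  }, numeric(1))
  data.frame(time = frameTimes(traj), distance = d)
}
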