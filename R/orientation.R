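#' Mass-weighted moment-of-inertia tensor
#'
#' Computes the 3x3 moment-of-inertia tensor of a point set about its own
#' center of mass,
#' \deqn{I = \sum_i m_i [ (r_i \cdot r_i)\, \mathbf{1} - r_i \otimes r_i ]}
#' with \eqn{r_i} taken relative to the mass-weighted centroid.  The tensor
#' is symmetric positive semi-definite; its eigenvectors are the principal
#' axes of the body and its eigenvalues the principal moments (amu nm^2).
#'
#' @param coords \code{M x 3} coordinates, nm (M >= 3, non-collinear)
#' @param masses masses, amu (total > 0)
#' @return list with \code{matrix} (3x3, amu nm^2) and \code{center} (nm)
#' @examples
#' # two unit masses at (+-1, 0, 0): moments 0 about x, 2 about y and z
#' inertiaTensor(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, 1))$matrix
#' @export
inertiaTensor <- function(coords, masses) {
  coords <- asCoordMatrix(coords)
  masses <- as.numeric(masses)
  if (length(masses) != nrow(coords)) stop("masses/coords length mismatch")
  if (any(masses < 0)) stop("masses must be non-negative")
  tm <- sum(masses)
  if (tm <= 0) stop("total mass must be positive")
  com <- colSums(coords * masses) / tm
  r <- sweep(coords, 2, com)
  rw <- r * masses
  # sum_i m_i r_i r_i^T and its trace give both terms of the tensor
  S <- crossprod(rw, r)                      # sum m r (x) r
  I <- diag(sum(diag(S)), 3) - S
  I <- (I + t(I)) / 2                        # kill rounding asymmetry
  list(matrix = I, center = as.numeric(com))
}

#' Principal axes of an inertia tensor
#'
#' Eigen-decomposition of a symmetric inertia tensor with moments ordered
#' ascending, so \code{p1} (smallest moment) is the body's long axis.
#' Eigenvectors are sign-ambiguous; signs are fixed by continuity against
#' \code{previous} (flip each axis so \code{p_k . previous_p_k >= 0}), or,
#' for the first frame, by alignment with the reference basis
#' (\code{p_k . e_k >= 0}, ties broken toward \code{+e_z}).  Handedness is
#' then enforced by flipping \code{p3} so \code{det = +1}.
#'
#' @param I 3x3 symmetric tensor, or the list returned by [inertiaTensor()]
#' @param previous optional previous-frame axes (3x3 matrix, columns p1..p3)
#'   for sign continuity
#' @param reference 3x3 reference basis used for first-frame signs
#'   (default the standard basis)
#' @param degenTol relative eigenvalue-gap tolerance below which the axes
#'   are flagged degenerate (a warning condition, axes still returned)
#' @return list: \code{axes} (3x3, columns p1..p3, det +1), \code{moments}
#'   (ascending, amu nm^2), \code{degenerate} (logical)
#' @export
principalAxes <- function(I, previous = NULL, reference = diag(3),
                          degenTol = 1e-6) {
  if (is.list(I)) I <- I$matrix
  if (any(abs(I - t(I)) > 1e-8 * max(1, max(abs(I)))))
    stop("inertia tensor must be symmetric")
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)                     # ascending: p1 = long axis
  mom <- e$values[ord]
  P <- e$vectors[, ord, drop = FALSE]
  scale <- max(abs(mom), 1e-300)
  gaps <- diff(mom) / scale
  degenerate <- any(gaps < degenTol)
  if (max(mom) <= 1e-12 * max(1, scale) && all(mom >= -1e-12))
    degenerate <- TRUE
  if (!is.null(previous)) {
    for (k in 1:3) if (sum(P[, k] * previous[, k]) < 0) P[, k] <- -P[, k]
  } else {
    for (k in 1:3) {
      d <- sum(P[, k] * reference[, k])
      if (d < 0 || (abs(d) < 1e-12 && sum(P[, k] * reference[, 3]) < 0))
        P[, k] <- -P[, k]
    }
  }
  if (det(P) < 0) P[, 3] <- -P[, 3]
  list(axes = P, moments = mom, degenerate = degenerate)
}

#' Direction cosine matrix between principal axes and a reference basis
#'
#' \code{R[j, k] = e_j . p_k}: the rotation carrying the reference basis
#' onto the principal axes.  Both inputs must be orthonormal and
#' right-handed; the result is orthogonal with det +1.
#'
#' @param axes 3x3 principal-axis matrix (columns p1..p3), or the list from
#'   [principalAxes()]
#' @param reference 3x3 reference basis (columns e_x, e_y, e_z)
#' @return 3x3 rotation matrix
#' @export
directionCosineMatrix <- function(axes, reference = diag(3)) {
  if (is.list(axes)) axes <- axes$axes
  checkRotation(axes, "axes")
  checkRotation(reference, "reference")
  crossprod(reference, axes)                 # t(E) %*% P
}

checkRotation <- function(R, what = "matrix", tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != 3L)) stop(what, " must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop(what, " must be orthonormal")
  if (det(R) < 0) stop(what, " must be right-handed (det +1)")
  invisible(R)
}

#' Tait-Bryan angles from a rotation matrix (intrinsic ZYX)
#'
#' Decomposes a proper rotation as \code{R = Rz(yaw) Ry(pitch) Rx(roll)}
#' (intrinsic Z-Y'-X'').  Pitch lies in [-90, 90] degrees; yaw and roll in
#' (-180, 180].  At gimbal lock (|pitch| = 90 degrees) yaw and roll are not
#' separable: the convention here sets roll to 0, lets yaw absorb the
#' remaining rotation, and flags the output.
#'
#' @param R 3x3 rotation matrix (orthogonal, det +1)
#' @param gimbalTol tolerance on \code{|R[3,1]| - 1} for lock detection
#' @return list: \code{yaw}, \code{pitch}, \code{roll} (degrees),
#'   \code{gimbal} (logical)
#' @examples
#' taitBryanZYX(diag(3))          # (0, 0, 0)
#' taitBryanZYX(eulerZYX(30, 20, 10))
#' @export
taitBryanZYX <- function(R, gimbalTol = 1e-10) {
  checkRotation(R, "R")
  s <- -R[3, 1]                              # sin(pitch)
  if (abs(s) >= 1 - gimbalTol) {
    pitch <- if (s > 0) 90 else -90
    # R reduces to Rz(yaw -/+ roll); attribute everything to yaw
    yaw <- atan2(-R[1, 2], R[2, 2]) * 180 / pi
    return(list(yaw = yaw, pitch = pitch, roll = 0, gimbal = TRUE))
  }
  list(yaw = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       pitch = asin(min(1, max(-1, s))) * 180 / pi,
       roll = atan2(R[3, 2], R[3, 3]) * 180 / pi,
       gimbal = FALSE)
}

#' Compose a rotation from intrinsic-ZYX Tait-Bryan angles
#'
#' @param yaw,pitch,roll angles in degrees
#' @return 3x3 rotation matrix \code{Rz(yaw) Ry(pitch) Rx(roll)}
#' @export
eulerZYX <- function(yaw, pitch, roll) {
  rotZ(yaw) %*% rotY(pitch) %*% rotX(roll)
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes.
#'
#' @param angle angle in degrees
#' @return 3x3 rotation matrix
#' @export
rotX <- function(angle) {
  a <- angle * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotX
#' @export
rotY <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotX
#' @export
rotZ <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Per-frame domain orientation of a trajectory
#'
#' For every frame, computes the mass-weighted inertia tensor of the
#' selected atoms (use the stable secondary-structure core of a domain to
#' avoid loop noise), extracts principal axes with frame-to-frame sign
#' continuity, forms the direction cosine matrix against the reference
#' basis, and decomposes it into intrinsic-ZYX yaw/pitch/roll.
#'
#' Two reference modes: \code{"standard"} measures angles against the fixed
#' laboratory basis (x, y, z), so pitch 0 means the domain long axis lies in
#' the membrane (xy) plane; \code{"firstFrame"} measures against the
#' principal axes of frame 1, so the series starts at (0, 0, 0) and reports
#' motion relative to the starting pose.
#'
#' @param traj a [Trajectory-class]
#' @param selection a [Selection-class] (or selection string)
#' @param referenceMode "standard" or "firstFrame"
#' @param degenTol eigenvalue-gap tolerance passed to [principalAxes()]
#' @return an [OrientationSeries-class]
#' @export
orientationSeries <- function(traj, selection,
                              referenceMode = c("standard", "firstFrame"),
                              degenTol = 1e-6) {
  referenceMode <- match.arg(referenceMode)
  if (is.character(selection)) selection <- atomSelect(traj, selection)
  idx <- selection@indices
  masses <- atoms(traj)$mass[idx]
  if (all(masses == 0)) {
    warning("all selected masses are zero; using equal masses")
    masses <- rep(1, length(idx))
  }
  nf <- nFrames(traj)
  axesArr <- array(NA_real_, c(3, 3, nf))
  moments <- matrix(NA_real_, nf, 3)
  degen <- logical(nf)
  prev <- NULL
  for (f in seq_len(nf)) {
    I <- inertiaTensor(frameCoords(traj, f, idx), masses)
    pa <- principalAxes(I, previous = prev, degenTol = degenTol)
    axesArr[, , f] <- pa$axes
    moments[f, ] <- pa$moments
    degen[f] <- pa$degenerate
    prev <- pa$axes
  }
  reference <- if (referenceMode == "standard") diag(3) else axesArr[, , 1]
  ang <- data.frame(yaw = numeric(nf), pitch = numeric(nf),
                    roll = numeric(nf), gimbal = logical(nf),
                    degenerate = degen)
  for (f in seq_len(nf)) {
    tb <- taitBryanZYX(directionCosineMatrix(axesArr[, , f], reference))
    ang$yaw[f] <- tb$yaw; ang$pitch[f] <- tb$pitch; ang$roll[f] <- tb$roll
    ang$gimbal[f] <- tb$gimbal
  }
  if (any(degen))
    warning(sum(degen), " frame(s) have near-degenerate principal moments")
  new("OrientationSeries", times = frameTimes(traj), axes = axesArr,
      moments = moments, angles = ang, reference = reference,
      selectionLabel = selection@label)
}

#' @rdname angles
#' @export
setMethod("angles", "OrientationSeries", function(x) {
  cbind(data.frame(time = x@times), x@angles)
})

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "OrientationSeries", function(x) x@times)

#' @rdname nFrames
#' @export
setMethod("nFrames", "OrientationSeries", function(x) length(x@times))

setMethod("show", "OrientationSeries", function(object) {
  p <- object@angles$pitch
  cat(sprintf(
    "OrientationSeries '%s': %d frames, pitch %.1f..%.1f deg (median %.1f)\n",
    object@selectionLabel, length(object@times), min(p), max(p),
    stats::median(p)))
})

#' Probability-normalized angle histogram, pooled over replicas
#'
#' Pools one or more angle series weighting every frame equally and returns
#' a probability histogram (bin masses sum to 1).  Pooling replicas of
#' unequal length is identical to histogramming their concatenation.
#'
#' @param series an [OrientationSeries-class], numeric vector of angles, or
#'   a list of either (replicas)
#' @param binWidth bin width, degrees (default 1)
#' @param range histogram range, degrees; bins are left-closed
#'   \code{[lo, hi)} except the last, which is closed
#' @param angle which angle to histogram ("pitch", "yaw" or "roll")
#' @param absolute fold angles to absolute values before binning
#' @return data.frame: \code{binLow}, \code{binHigh}, \code{binMid},
#'   \code{count}, \code{mass}
#' @export
angleHistogram <- function(series, binWidth = 1, range = c(-90, 90),
                           angle = "pitch", absolute = FALSE) {
  vals <- poolAngles(series, angle)
  if (length(vals) == 0L) stop("no angle values to histogram")
  if (absolute) vals <- abs(vals)
  breaks <- seq(range[1], range[2], by = binWidth)
  if (breaks[length(breaks)] < range[2])
    breaks <- c(breaks, range[2])
  if (any(vals < range[1] | vals > range[2]))
    stop("angle values outside histogram range")
  h <- graphics::hist(vals, breaks = breaks, right = FALSE, plot = FALSE)
  data.frame(binLow = breaks[-length(breaks)], binHigh = breaks[-1],
             binMid = h$mids, count = h$counts,
             mass = h$counts / sum(h$counts))
}

poolAngles <- function(series, angle = "pitch") {
  one <- function(s) {
    if (is(s, "OrientationSeries")) return(s@angles[[angle]])
    if (is.numeric(s)) return(as.numeric(s))
    stop("series must be OrientationSeries or numeric")
  }
  if (is.list(series) && !is(series, "OrientationSeries"))
    unlist(lapply(series, one), use.names = FALSE)
  else one(series)
}

#' Run-by-time pitch table for heat-map plotting
#'
#' One row per replica.  Series on different time grids are resampled to
#' the first series' grid by nearest-frame lookup.
#'
#' @param seriesList list of [OrientationSeries-class] (or numeric vectors
#'   sharing the first series' grid)
#' @param angle which angle to tabulate
#' @return matrix, runs x frames, with times as column names
#' @export
angleHeatmapTable <- function(seriesList, angle = "pitch") {
  if (is(seriesList, "OrientationSeries")) seriesList <- list(seriesList)
  ref <- seriesList[[1]]
  refT <- if (is(ref, "OrientationSeries")) ref@times else
    seq_along(poolAngles(ref, angle)) - 1
  rows <- lapply(seriesList, function(s) {
    v <- poolAngles(s, angle)
    tt <- if (is(s, "OrientationSeries")) s@times else seq_along(v) - 1
    if (length(v) == length(refT) && isTRUE(all.equal(tt, refT))) return(v)
    # nearest-frame resampling onto the reference grid
    v[vapply(refT, function(t0) which.min(abs(tt - t0)), integer(1))]
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(paste0("run", seq_along(rows)),
                        format(refT, trim = TRUE))
  out
}
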