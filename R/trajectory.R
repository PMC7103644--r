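#' Construct a Trajectory
#'
#' @param topology a [Topology-class]
#' @param coords coordinates in nm: an \code{nAtoms x 3} matrix (one frame),
#'   an \code{nAtoms x 3 x nFrames} array, or a list of \code{nAtoms x 3}
#'   matrices
#' @param box orthorhombic box edges in nm: length-3 vector (recycled) or
#'   \code{nFrames x 3} matrix; \code{NA} when no box applies
#' @param times frame times in ps (default \code{0, 1, ...} ps)
#' @return a [Trajectory-class]
#' @export
Trajectory <- function(topology, coords, box = NA_real_, times = NULL) {
  if (is.list(coords)) coords <- simplify2array(coords)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  storage.mode(coords) <- "double"
  nf <- dim(coords)[3]
  if (is.matrix(box)) {
    bx <- box
  } else {
    bx <- matrix(rep_len(as.numeric(box), 3L), nf, 3L, byrow = TRUE)
  }
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  new("Trajectory", topology = topology, coords = coords, box = bx,
      times = as.numeric(times))
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame = 1L, indices = NULL) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > nFrames(x)) stop("frame out of range")
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(x@coords)[1:2]
  if (!is.null(indices)) m <- m[resolveIndices(indices, nrow(m)), , drop = FALSE]
  m
})

#' @rdname boxDims
#' @export
setMethod("boxDims", "Trajectory", function(x, frame = 1L) {
  as.numeric(x@box[as.integer(frame), ])
})

#' Topology of a Trajectory
#' @param x a Trajectory
#' @return the bound [Topology-class]
#' @export
topologyOf <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@topology
}

setMethod("show", "Trajectory", function(object) {
  b <- boxDims(object, 1L)
  cat(sprintf("Trajectory: %d atoms x %d frames, t = %g..%g ps\n",
              nAtoms(object), nFrames(object),
              min(object@times), max(object@times)))
  if (all(is.finite(b)))
    cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm\n", b[1], b[2], b[3]))
})

#' Mass-weighted center of mass
#'
#' @param coords \code{n x 3} coordinate matrix, nm
#' @param masses numeric masses, amu (equal weights when NULL)
#' @return length-3 numeric vector, nm
#' @export
centerOfMass <- function(coords, masses = NULL) {
  coords <- asCoordMatrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords)) stop("masses/coords length mismatch")
  tm <- sum(masses)
  if (tm <= 0) stop("total mass must be positive")
  as.numeric(colSums(coords * masses) / tm)
}

asCoordMatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3L) stop("coordinates must be n x 3")
  storage.mode(x) <- "double"
  x
}
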