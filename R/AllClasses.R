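#' @import methods
NULL

#' Topology: per-atom metadata for a molecular system
#'
#' A \code{Topology} holds the static per-atom description of a system:
#' atom names, residue names and ids, segment (chain) ids, masses in amu and
#' a coarse-grained flag.  Atom indices are 1-based, residue ids are taken
#' verbatim from the source file (1-based in both PDB and GRO).
#'
#' @slot atoms data.frame with columns \code{name}, \code{resname},
#'   \code{resid}, \code{segid}, \code{mass}, \code{isBead}.
#'
#' @seealso [readStructure()], [atomSelect()]
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("name", "resname", "resid", "segid", "mass", "isBead")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0) {
    if (any(!nzchar(a$name))) return("atom names must be non-empty")
    if (any(!is.finite(a$mass)) || any(a$mass < 0))
      return("masses must be finite and non-negative")
  }
  TRUE
})

#' Trajectory: ordered coordinate frames bound to a Topology
#'
#' Coordinates are stored as an \code{nAtoms x 3 x nFrames} array in nm,
#' box edges (orthorhombic) as an \code{nFrames x 3} matrix in nm, and frame
#' times in ps.  Triclinic boxes are out of scope; readers reject them.
#'
#' @slot topology a [Topology-class]
#' @slot coords numeric array, \code{nAtoms x 3 x nFrames}, nm
#' @slot box numeric matrix, \code{nFrames x 3}, nm (row of \code{NA} when
#'   the frame carries no box)
#' @slot times numeric vector, ps
#' @export
setClass("Trajectory", representation(
  topology = "Topology", coords = "array", box = "matrix", times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be nAtoms x 3 x nFrames")
  if (d[3] < 1L) return("a Trajectory needs at least one frame")
  if (d[1] != nrow(object@topology@atoms))
    return(sprintf("coords atom count (%d) != topology atom count (%d)",
                   d[1], nrow(object@topology@atoms)))
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
    return("box must be nFrames x 3")
  if (length(object@times) != d[3]) return("times length must equal nFrames")
  if (is.unsorted(object@times)) return("frame times must be non-decreasing")
  TRUE
})

#' Selection: a labelled, order-stable set of atom indices
#'
#' @slot label character scalar
#' @slot indices sorted integer vector of 1-based atom indices
#' @export
setClass("Selection", representation(label = "character", indices = "integer"))

setValidity("Selection", function(object) {
  if (length(object@indices) == 0L) return("selection is empty")
  if (any(object@indices < 1L)) return("atom indices are 1-based")
  if (anyDuplicated(object@indices)) return("duplicate atom indices")
  if (is.unsorted(object@indices)) return("indices must be sorted")
  TRUE
})

#' OrientationSeries: per-frame principal axes and Tait-Bryan angles
#'
#' Produced by [orientationSeries()].  \code{axes} holds the sign-continuous
#' principal-axis matrix per frame (columns p1, p2, p3, moments ascending so
#' p1 is the long axis); \code{angles} the intrinsic-ZYX yaw/pitch/roll in
#' degrees relative to \code{reference}.
#'
#' @slot times numeric, ps
#' @slot axes numeric array \code{3 x 3 x nFrames}
#' @slot moments numeric matrix \code{nFrames x 3}, amu nm^2, ascending
#' @slot angles data.frame with columns \code{yaw}, \code{pitch}, \code{roll}
#'   (degrees) and logical \code{gimbal}, \code{degenerate}
#' @slot reference 3 x 3 orthonormal reference basis (columns)
#' @slot selectionLabel character
#' @export
setClass("OrientationSeries", representation(
  times = "numeric", axes = "array", moments = "matrix",
  angles = "data.frame", reference = "matrix", selectionLabel = "character"))

setValidity("OrientationSeries", function(object) {
  n <- length(object@times)
  if (dim(object@axes)[3] != n || nrow(object@angles) != n ||
      nrow(object@moments) != n)
    return("times, axes, moments and angles must have equal length")
  if (any(abs(crossprod(object@reference) - diag(3)) > 1e-8))
    return("reference basis must be orthonormal")
  TRUE
})

#' ContactSeries: residue x frame boolean contact records
#'
#' @slot residues data.frame with one row per probed residue
#'   (\code{resid}, \code{resname}, \code{segid}, logical \code{fallback}
#'   marking residues probed at a fallback site)
#' @slot times numeric, ps
#' @slot hits logical matrix, residues x frames
#' @slot criterion list describing probe, partner and cutoff (nm)
#' @export
setClass("ContactSeries", representation(
  residues = "data.frame", times = "numeric", hits = "matrix",
  criterion = "list"))

setValidity("ContactSeries", function(object) {
  if (nrow(object@hits) != nrow(object@residues))
    return("hits rows must match residues")
  if (ncol(object@hits) != length(object@times))
    return("hits columns must match times")
  if (!is.logical(object@hits)) return("hits must be logical")
  TRUE
})

#' ClusterTimeSeries: per-frame partition of protein copies into clusters
#'
#' @slot times numeric, ps
#' @slot assignment integer matrix, copies x frames; cluster ids are the
#'   lowest member index of each cluster, so series are stable for diffing
#' @slot sizes list (per frame) of integer cluster-size multisets
#' @slot cutoff numeric, nm
#' @slot window integer smoothing window (frames; 1 = none)
#' @export
setClass("ClusterTimeSeries", representation(
  times = "numeric", assignment = "matrix", sizes = "list",
  cutoff = "numeric", window = "integer"))

setValidity("ClusterTimeSeries", function(object) {
  nf <- length(object@times)
  if (ncol(object@assignment) != nf || length(object@sizes) != nf)
    return("assignment columns and sizes must match times")
  nc <- nrow(object@assignment)
  ok <- vapply(object@sizes, function(s) sum(s) == nc, logical(1))
  if (!all(ok)) return("cluster sizes must sum to the number of copies")
  TRUE
})

#' RDFProfile: radial distribution functions of lipid types around a protein
#'
#' @slot r numeric bin centers, nm
#' @slot g numeric matrix, bins x lipid types (dimensionless)
#' @slot counts numeric matrix of raw neighbor counts per bin and type
#' @slot params list (mode, binWidth, rMax, densities, shellVolumes, nFrames)
#' @export
setClass("RDFProfile", representation(
  r = "numeric", g = "matrix", counts = "matrix", params = "list"))

setValidity("RDFProfile", function(object) {
  if (nrow(object@g) != length(object@r)) return("g rows must match r")
  if (any(object@g < -1e-12)) return("g(r) must be non-negative")
  TRUE
})
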