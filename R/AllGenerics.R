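#' Number of atoms
#' @param x a Topology or Trajectory
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#' @param x a Trajectory or series object
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom table
#' @param x a Topology or Trajectory
#' @return data.frame of per-atom metadata
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Frame times (ps)
#' @param x a Trajectory or series object
#' @return numeric vector of times in ps
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Coordinates of one frame
#' @param x a Trajectory
#' @param frame 1-based frame index
#' @param indices optional atom indices (or a Selection)
#' @return nAtoms x 3 numeric matrix, nm
#' @export
setGeneric("frameCoords", function(x, frame = 1L, indices = NULL)
  standardGeneric("frameCoords"))

#' Box edges of one frame (nm)
#' @param x a Trajectory
#' @param frame 1-based frame index
#' @return length-3 numeric vector of orthorhombic edges, nm (NA if absent)
#' @export
setGeneric("boxDims", function(x, frame = 1L) standardGeneric("boxDims"))

#' Per-residue contact occupancy
#'
#' Occupancy is the fraction of frames in which a residue satisfies the
#' contact criterion; values lie in [0, 1].
#'
#' @param x a ContactSeries
#' @param ... unused
#' @return data.frame with residue metadata and an \code{occupancy} column
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

#' Tait-Bryan angle table of an OrientationSeries
#' @param x an OrientationSeries
#' @return data.frame with time, yaw, pitch, roll (degrees) and flags
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' Cluster sizes per frame
#' @param x a ClusterTimeSeries
#' @return list of integer size multisets, one per frame
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
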