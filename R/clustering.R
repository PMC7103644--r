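#' Copy-copy contact graph of one frame
#'
#' An edge joins copies i and j when any particle of i lies strictly within
#' the cutoff of any particle of j (minimum image).
#'
#' @param coordsList list of per-copy coordinate matrices (nm)
#' @param cutoff nm
#' @param box orthorhombic box edges (nm) or NULL
#' @return integer matrix with columns \code{i}, \code{j} (i < j); zero rows
#'   when no contacts
#' @export
contactGraph <- function(coordsList, cutoff, box = NULL) {
  n <- length(coordsList)
  sizes <- vapply(coordsList, nrow, integer(1))
  copyOf <- rep(seq_len(n), sizes)
  all <- do.call(rbind, coordsList)
  edges <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (nrow(all) <= 4000L) {
    # one distance matrix, then aggregate particle hits to copy pairs
    D <- distMatrixPBC(all, all, box)
    hit <- which(D < cutoff, arr.ind = TRUE)
    ci <- copyOf[hit[, 1]]; cj <- copyOf[hit[, 2]]
    keep <- ci < cj
    if (any(keep))
      edges <- unique(cbind(i = ci[keep], j = cj[keep]))
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (any(anyWithin(coordsList[[i]], coordsList[[j]], cutoff, box,
                        method = "brute")))
        edges <- rbind(edges, c(i, j))
    }
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Single-linkage connected components over copies
#'
#' Components of the copy contact graph; any touching pair merges clusters
#' (so end-on fibril chains count as one cluster even when their ends never
#' touch).  Cluster ids are deterministic: the lowest member index.
#'
#' @param edges edge matrix from [contactGraph()]
#' @param nCopies total number of copies
#' @return list: \code{assignment} (integer per copy: cluster id = lowest
#'   member), \code{sizes} (decreasing integer multiset)
#' @export
connectedComponents <- function(edges, nCopies) {
  g <- igraph::make_empty_graph(n = nCopies, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  mem <- igraph::components(g)$membership
  lowest <- vapply(split(seq_len(nCopies), mem), min, integer(1))
  assignment <- lowest[as.character(mem)]
  names(assignment) <- NULL
  sizes <- sort(as.integer(table(assignment)), decreasing = TRUE)
  list(assignment = as.integer(assignment), sizes = sizes)
}

#' Cluster-size evolution over a trajectory
#'
#' Per frame, builds the copy contact graph and its single-linkage
#' partition.  An odd smoothing window \code{w > 1} replaces each frame's
#' edge set by the majority vote over the centered window (an edge exists
#' where it is present in more than half of the window frames), which
#' suppresses single-frame touch events; \code{window = 1} disables it.
#'
#' @param traj a [Trajectory-class]
#' @param copies list of [Selection-class] (or selection strings), one per
#'   copy
#' @param cutoff contact cutoff, nm
#' @param window odd smoothing window in frames (default 1)
#' @return a [ClusterTimeSeries-class]
#' @export
clusterTimeSeries <- function(traj, copies, cutoff, window = 1L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  idxList <- lapply(copies, function(s)
    if (is.character(s)) atomSelect(traj, s)@indices else s@indices)
  n <- length(idxList)
  nf <- nFrames(traj)
  pairIds <- utils::combn(n, 2)
  adj <- matrix(FALSE, ncol(pairIds), nf)     # pair x frame edge presence
  for (f in seq_len(nf)) {
    xyz <- frameCoords(traj, f)
    box <- boxDims(traj, f)
    if (anyNA(box)) box <- NULL
    cl <- lapply(idxList, function(ii) xyz[ii, , drop = FALSE])
    e <- contactGraph(cl, cutoff, box)
    if (nrow(e)) {
      key <- (e[, 1] - 1) * n + e[, 2]
      pk <- (pairIds[1, ] - 1) * n + pairIds[2, ]
      adj[match(key, pk), f] <- TRUE
    }
  }
  if (window > 1L) {
    h <- window %/% 2L
    sm <- adj
    for (f in seq_len(nf)) {
      w <- max(1L, f - h):min(nf, f + h)
      sm[, f] <- rowMeans(adj[, w, drop = FALSE]) > 0.5
    }
    adj <- sm
  }
  assignment <- matrix(NA_integer_, n, nf)
  sizes <- vector("list", nf)
  for (f in seq_len(nf)) {
    on <- which(adj[, f])
    e <- cbind(pairIds[1, on], pairIds[2, on])
    cc <- connectedComponents(e, n)
    assignment[, f] <- cc$assignment
    sizes[[f]] <- cc$sizes
  }
  new("ClusterTimeSeries", times = frameTimes(traj),
      assignment = assignment, sizes = sizes, cutoff = cutoff,
      window = window)
}

#' @rdname clusterSizes
#' @export
setMethod("clusterSizes", "ClusterTimeSeries", function(x) x@sizes)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "ClusterTimeSeries", function(x) x@times)

#' @rdname nFrames
#' @export
setMethod("nFrames", "ClusterTimeSeries", function(x) length(x@times))

setMethod("show", "ClusterTimeSeries", function(object) {
  last <- object@sizes[[length(object@sizes)]]
  cat(sprintf(
    "ClusterTimeSeries: %d copies x %d frames (cutoff %.3g nm, window %d)\n",
    nrow(object@assignment), length(object@times), object@cutoff,
    object@window))
  cat("  final sizes:", paste(last, collapse = " "), "\n")
})

#' Per-frame occupancy of each cluster-size class
#'
#' The machine-readable twin of a cluster-evolution stack plot: for every
#' frame, the fraction of copies found in clusters of each size.
#'
#' @param cts a [ClusterTimeSeries-class]
#' @return data.frame, one row per frame, one \code{size<k>} column per
#'   observed size class, values summing to 1 per row
#' @export
clusterSizeOccupancy <- function(cts) {
  n <- nrow(cts@assignment)
  maxSize <- max(unlist(cts@sizes))
  m <- t(vapply(cts@sizes, function(s) {
    out <- numeric(maxSize)
    for (sz in s) out[sz] <- out[sz] + sz / n
    out
  }, numeric(maxSize)))
  df <- data.frame(time = cts@times)
  colnames(m) <- paste0("size", seq_len(maxSize))
  cbind(df, as.data.frame(m))
}

#' Classify the Ig-domain pose from its pitch angle
#'
#' Three-state classification of the extracellular-domain pose: "down"
#' (long axis near the membrane plane), "intermediate", and "up" (pointing
#' away from the membrane, the crystal-like pose).  Thresholds apply to
#' |pitch| with inclusive bounds on the intermediate band; the defaults
#' (20, 60) degrees are declared package defaults, configurable.
#'
#' @param pitch numeric pitch angle(s), degrees, in [-90, 90]
#' @param thresholds length-2 increasing vector (low, high), degrees
#' @return character vector: "down", "intermediate" or "up"
#' @export
classifyIgState <- function(pitch, thresholds = c(20, 60)) {
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stop("thresholds must be increasing (low, high)")
  if (any(abs(pitch) > 90 + 1e-9)) stop("pitch must lie in [-90, 90]")
  p <- abs(pitch)
  ifelse(p < thresholds[1], "down",
         ifelse(p <= thresholds[2], "intermediate", "up"))
}
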