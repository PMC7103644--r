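#' Minimum-image displacement between two points
#'
#' Returns the displacement \code{r2 - r1} wrapped into the primary image of
#' an orthorhombic box, so every component has magnitude at most half the
#' corresponding box edge.  With \code{box = NULL} the plain displacement is
#' returned.
#'
#' @param r1,r2 length-3 positions (nm), or \code{n x 3} matrices
#' @param box length-3 orthorhombic box edges, nm, or NULL for no periodicity
#' @return displacement vector (or matrix), nm
#' @examples
#' minImageDisplacement(c(0.1, 0, 0), c(5.1, 0, 0), box = c(5.2, 5.2, 5.2))
#' @export
minImageDisplacement <- function(r1, r2, box = NULL) {
  r1 <- asCoordMatrix(r1); r2 <- asCoordMatrix(r2)
  d <- r2 - r1
  if (!is.null(box) && !anyNA(box)) {
    checkBox(box)
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  }
  if (nrow(d) == 1L) as.numeric(d) else d
}

checkBox <- function(box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths (nm)")
  box
}

# Full minimum-image distance matrix between point sets A (n x 3) and
# B (m x 3); chunked over A to bound memory.  Desk-scale workhorse.
distMatrixPBC <- function(A, B, box = NULL, chunk = 512L) {
  A <- asCoordMatrix(A); B <- asCoordMatrix(B)
  periodic <- !is.null(box) && !anyNA(box)
  if (periodic) box <- checkBox(box)
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    dx <- outer(A[idx, 1], B[, 1], "-")
    dy <- outer(A[idx, 2], B[, 2], "-")
    dz <- outer(A[idx, 3], B[, 3], "-")
    if (periodic) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    out[idx, ] <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  out
}

#' Minimum distance from each point of a set to another set
#'
#' @param A \code{n x 3} query points, nm
#' @param B \code{m x 3} target points, nm
#' @param box optional orthorhombic box for minimum-image distances
#' @return numeric vector of length \code{n}: distance from each row of A to
#'   its nearest point in B
#' @export
minDistToSet <- function(A, B, box = NULL) {
  A <- asCoordMatrix(A); B <- asCoordMatrix(B)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = 512L)) {
    e <- min(s + 511L, nrow(A))
    out[s:e] <- apply(distMatrixPBC(A[s:e, , drop = FALSE], B, box), 1, min)
  }
  out
}

#' Cutoff neighbor test between two point sets
#'
#' For each point of \code{A}, reports whether any point of \code{B} lies
#' strictly within \code{cutoff} (minimum image when a box is given).  The
#' default method bins \code{B} into a cell list with cell edge >= cutoff and
#' scans only the 27 neighboring cells; \code{method = "brute"} computes all
#' pairs.  Both methods are exact and agree on every input.
#'
#' @param A,B point sets, \code{n x 3} / \code{m x 3}, nm
#' @param cutoff contact cutoff, nm (strict \code{<} comparison)
#' @param box optional orthorhombic box edges, nm
#' @param method "cell" (default) or "brute"
#' @return logical vector of length \code{nrow(A)}
#' @export
anyWithin <- function(A, B, cutoff, box = NULL, method = c("cell", "brute")) {
  method <- match.arg(method)
  A <- asCoordMatrix(A); B <- asCoordMatrix(B)
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (method == "brute")
    return(minDistToSet(A, B, box) < cutoff)
  cellSearch(A, B, cutoff, box, function(d) d < cutoff,
             combine = "any", default = FALSE)
}

# Cell-list scan: for each A point, applies `test` to distances to candidate
# B points from the 27 neighbor cells and combines with any().  With a box
# the cell grid tiles the box and neighbor lookup wraps; without, the grid
# tiles the bounding slab of both sets (no wrap).
cellSearch <- function(A, B, cutoff, box, test, combine = "any",
                       default = FALSE) {
  periodic <- !is.null(box) && !anyNA(box)
  if (periodic) {
    box <- checkBox(box)
    lo <- c(0, 0, 0); span <- box
    Aw <- sweep(A, 2, box, function(x, b) x - b * floor(x / b))
    Bw <- sweep(B, 2, box, function(x, b) x - b * floor(x / b))
  } else {
    lo <- pmin(apply(A, 2, min), apply(B, 2, min))
    hi <- pmax(apply(A, 2, max), apply(B, 2, max))
    span <- pmax(hi - lo, cutoff)
    Aw <- A; Bw <- B
  }
  ncell <- pmax(1L, as.integer(floor(span / cutoff)))
  cellOf <- function(P) {
    ix <- pmin(ncell[1] - 1L, pmax(0L,
          as.integer(floor((P[, 1] - lo[1]) / span[1] * ncell[1]))))
    iy <- pmin(ncell[2] - 1L, pmax(0L,
          as.integer(floor((P[, 2] - lo[2]) / span[2] * ncell[2]))))
    iz <- pmin(ncell[3] - 1L, pmax(0L,
          as.integer(floor((P[, 3] - lo[3]) / span[3] * ncell[3]))))
    cbind(ix, iy, iz)
  }
  ca <- cellOf(Aw); cb <- cellOf(Bw)
  id <- function(cc) cc[, 1] + ncell[1] * (cc[, 2] + ncell[2] * cc[, 3])
  bByCell <- split(seq_len(nrow(Bw)), id(cb))
  out <- rep(default, nrow(Aw))
  aCells <- unique(ca)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (k in seq_len(nrow(aCells))) {
    cc <- aCells[k, ]
    aIdx <- which(ca[, 1] == cc[1] & ca[, 2] == cc[2] & ca[, 3] == cc[3])
    nb <- sweep(offs, 2, cc, "+")
    if (periodic) {
      nb <- sweep(nb, 2, ncell, function(x, n) ((x %% n) + n) %% n)
    } else {
      keep <- nb[, 1] >= 0 & nb[, 1] < ncell[1] &
              nb[, 2] >= 0 & nb[, 2] < ncell[2] &
              nb[, 3] >= 0 & nb[, 3] < ncell[3]
      nb <- nb[keep, , drop = FALSE]
    }
    cand <- unlist(bByCell[as.character(unique(id(nb)))], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d <- distMatrixPBC(A[aIdx, , drop = FALSE], B[cand, , drop = FALSE],
                       if (periodic) box else NULL)
    hit <- test(d)
    out[aIdx] <- apply(hit, 1, any)
  }
  out
}
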