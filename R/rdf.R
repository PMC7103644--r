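#' Radial distribution function of lipid beads around a protein
#'
#' Histograms minimum-image distances from each lipid reference bead to the
#' protein reference and normalizes by shell volume and mean number density
#' so that a uniformly distributed species gives g(r) = 1.
#'
#' Two reference modes: \code{"com"} measures to the mass-weighted protein
#' center of mass and normalizes with exact spherical-shell volumes;
#' \code{"surface"} measures to the nearest protein particle and normalizes
#' with a seeded Monte-Carlo estimate of each accessible shell volume
#' (uniform samples in the box binned by their own distance-to-protein),
#' since analytic shell volumes are wrong for an extended reference.
#'
#' @param traj a [Trajectory-class] with a periodic box
#' @param proteinSelection protein reference ([Selection-class] or string)
#' @param lipidSelections named list of lipid-bead selections, one per type
#' @param mode "surface" (default) or "com"
#' @param binWidth bin width, nm (default 0.02)
#' @param rMax maximum radius, nm; must not exceed half the smallest box
#'   edge (default: that bound)
#' @param mcSamples Monte-Carlo samples per frame for surface-mode
#'   normalization
#' @param seed seed for the Monte-Carlo volume estimate (surface mode)
#' @return an [RDFProfile-class]
#' @export
computeRDF <- function(traj, proteinSelection, lipidSelections,
                       mode = c("surface", "com"), binWidth = 0.02,
                       rMax = NULL, mcSamples = 20000L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(proteinSelection))
    proteinSelection <- atomSelect(traj, proteinSelection)
  lipidSelections <- lapply(lipidSelections, function(s)
    if (is.character(s)) atomSelect(traj, s) else s)
  box1 <- boxDims(traj, 1L)
  if (anyNA(box1)) stop("RDF requires a periodic box")
  halfMin <- min(box1) / 2
  if (is.null(rMax)) rMax <- halfMin
  if (rMax > halfMin + 1e-9)
    stop(sprintf("rMax (%.3g nm) exceeds half the smallest box edge (%.3g nm)",
                 rMax, halfMin))
  breaks <- seq(0, rMax, by = binWidth)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  nb <- length(breaks) - 1L
  nf <- nFrames(traj)
  types <- names(lipidSelections)
  counts <- matrix(0, nb, length(types), dimnames = list(NULL, types))
  shellVol <- numeric(nb)
  vBox <- prod(box1)
  mProt <- atoms(traj)$mass[proteinSelection@indices]
  if (mode == "surface") {
    rng <- localRNG(seed)
    on.exit(rng(), add = TRUE)
  }
  for (f in seq_len(nf)) {
    box <- boxDims(traj, f)
    xyz <- frameCoords(traj, f)
    prot <- xyz[proteinSelection@indices, , drop = FALSE]
    refDist <- function(P) {
      if (mode == "com")
        minDistToSet(P, matrix(centerOfMass(prot, mProt), 1, 3), box)
      else minDistToSet(P, prot, box)
    }
    for (ty in types) {
      d <- refDist(xyz[lipidSelections[[ty]]@indices, , drop = FALSE])
      d <- d[d < rMax]
      if (length(d))
        counts[, ty] <- counts[, ty] +
          graphics::hist(d, breaks = breaks, right = FALSE,
                         plot = FALSE)$counts
    }
    if (mode == "surface") {
      S <- cbind(stats::runif(mcSamples, 0, box[1]),
                 stats::runif(mcSamples, 0, box[2]),
                 stats::runif(mcSamples, 0, box[3]))
      ds <- refDist(S)
      ds <- ds[ds < rMax]
      shellVol <- shellVol + graphics::hist(ds, breaks = breaks,
        right = FALSE, plot = FALSE)$counts / mcSamples * prod(box)
    }
  }
  if (mode == "com") {
    shellVol <- 4 / 3 * pi * diff(breaks^3) * nf
  }
  dens <- vapply(lipidSelections, function(s)
    length(s@indices) / vBox, numeric(1))
  g <- counts
  for (ty in types) {
    denom <- shellVol * dens[ty]
    g[, ty] <- ifelse(denom > 0, counts[, ty] / denom, 0)
  }
  new("RDFProfile", r = (breaks[-1] + breaks[-length(breaks)]) / 2,
      g = g, counts = counts,
      params = list(mode = mode, binWidth = binWidth, rMax = rMax,
                    densities = dens, shellVolumes = shellVol,
                    nFrames = nf, seed = if (mode == "surface") seed else NA))
}

# Run code under a locally-seeded RNG, restoring the caller's state.
localRNG <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' RDF as a data.frame
#' @param profile an [RDFProfile-class]
#' @return data.frame with column \code{r} (nm) and one \code{g_<type>}
#'   column per lipid type
#' @export
rdfTable <- function(profile) {
  df <- data.frame(r = profile@r)
  for (ty in colnames(profile@g)) df[[paste0("g_", ty)]] <- profile@g[, ty]
  df
}

setMethod("show", "RDFProfile", function(object) {
  cat(sprintf("RDFProfile (%s mode): %d bins to %.2f nm, types: %s\n",
              object@params$mode, length(object@r), object@params$rMax,
              paste(colnames(object@g), collapse = ", ")))
})
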