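#' Contact criterion
#'
#' Bundles the probe rule, partner atom names and cutoff used by the contact
#' analyses.  Distances compare strictly (\code{distance < cutoff}).  The
#' two criteria of interest for membrane binding are the atomistic rule
#' (side-chain center of mass within 0.5 nm of a lipid-headgroup phosphorus)
#' and the coarse-grained rule (first side-chain bead within 0.65 nm of a
#' lipid headgroup bead).
#'
#' @param probe "sidechain_com", "first_sidechain_bead" or "any_atom"
#' @param partnerNames atom names defining the partner set (informational
#'   when an explicit partner Selection is supplied)
#' @param cutoff cutoff in nm (> 0)
#' @param periodic use minimum-image distances (default TRUE)
#' @return a list of class "contactCriterion"
#' @export
contactCriterion <- function(probe = c("sidechain_com",
                                       "first_sidechain_bead", "any_atom"),
                             partnerNames = "P", cutoff = 0.5,
                             periodic = TRUE) {
  probe <- match.arg(probe)
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive (nm)")
  structure(list(probe = probe, partnerNames = partnerNames,
                 cutoff = cutoff, periodic = periodic),
            class = "contactCriterion")
}

backboneNames <- c("N", "CA", "C", "O", "OXT", "H", "HA", "BB")

# Probe coordinates for one residue in one frame, per the criterion.
# Returns list(coords = matrix, fallback = logical).
residueProbe <- function(xyz, a, atomIdx, criterion) {
  if (criterion$probe == "any_atom")
    return(list(coords = xyz[atomIdx, , drop = FALSE], fallback = FALSE))
  nm <- a$name[atomIdx]
  heavy <- atomIdx[!(nm %in% backboneNames) &
                   !grepl("^[0-9]*H", toupper(nm))]
  if (criterion$probe == "first_sidechain_bead") {
    if (length(heavy))
      return(list(coords = xyz[heavy[1], , drop = FALSE], fallback = FALSE))
    return(list(coords = xyz[atomIdx[1], , drop = FALSE], fallback = TRUE))
  }
  # sidechain_com: mass-weighted COM of side-chain heavy atoms; glycine
  # (no side-chain heavy atoms) falls back to CA, flagged
  if (length(heavy)) {
    com <- centerOfMass(xyz[heavy, , drop = FALSE], a$mass[heavy])
    return(list(coords = matrix(com, 1, 3), fallback = FALSE))
  }
  ca <- atomIdx[nm == "CA"]
  if (!length(ca)) return(NULL)
  list(coords = xyz[ca[1], , drop = FALSE], fallback = TRUE)
}

#' Residue-lipid contact series (atomistic criterion)
#'
#' A residue is in contact in a frame when its probe site (by default the
#' side-chain heavy-atom center of mass; glycine falls back to C-alpha,
#' flagged in the residue table) lies strictly within the cutoff of any
#' partner atom (by default lipid-headgroup phosphorus), using minimum-image
#' distances.
#'
#' @param traj a [Trajectory-class]
#' @param proteinSelection protein atoms whose residues are probed
#' @param partnerSelection lipid partner atoms (e.g. \code{"name P"})
#' @param criterion a [contactCriterion()] (default: sidechain COM, 0.5 nm)
#' @return a [ContactSeries-class]
#' @export
residueLipidContacts <- function(traj, proteinSelection, partnerSelection,
                                 criterion = contactCriterion()) {
  if (is.character(proteinSelection))
    proteinSelection <- atomSelect(traj, proteinSelection)
  if (is.character(partnerSelection))
    partnerSelection <- atomSelect(traj, partnerSelection)
  a <- atoms(traj)
  res <- residueTable(topologyOf(traj), proteinSelection)
  nf <- nFrames(traj)
  hits <- matrix(FALSE, nrow(res), nf)
  fallback <- logical(nrow(res))
  for (f in seq_len(nf)) {
    xyz <- frameCoords(traj, f)
    box <- if (criterion$periodic) boxDims(traj, f) else NULL
    if (!is.null(box) && anyNA(box)) box <- NULL
    partner <- xyz[partnerSelection@indices, , drop = FALSE]
    probes <- matrix(NA_real_, nrow(res), 3)
    multi <- vector("list", nrow(res))
    for (ri in seq_len(nrow(res))) {
      pr <- residueProbe(xyz, a, res$atomIdx[[ri]], criterion)
      if (is.null(pr))
        stop("residue ", res$resid[ri], " (", res$resname[ri],
             ") has no probe atoms and no fallback")
      fallback[ri] <- fallback[ri] || pr$fallback
      if (nrow(pr$coords) == 1L) probes[ri, ] <- pr$coords else
        multi[[ri]] <- pr$coords
    }
    single <- which(is.finite(probes[, 1]))
    if (length(single))
      hits[single, f] <- anyWithin(probes[single, , drop = FALSE], partner,
                                   criterion$cutoff, box)
    for (ri in which(!vapply(multi, is.null, logical(1))))
      hits[ri, f] <- any(anyWithin(multi[[ri]], partner,
                                   criterion$cutoff, box))
  }
  res$fallback <- fallback
  res$atomIdx <- NULL
  new("ContactSeries", residues = res, times = frameTimes(traj),
      hits = hits, criterion = unclass(criterion))
}

#' Coarse-grained protein-lipid contacts per lipid type
#'
#' Counts contacts between the first side-chain bead of each protein
#' residue and the headgroup bead of each lipid type, strict cutoff 0.65 nm
#' by default.  Lipid types are identified by residue name; an unknown type
#' (no matching beads) is an error.
#'
#' @param traj a [Trajectory-class]
#' @param proteinSelection protein beads
#' @param lipidTypes character vector of lipid residue names
#'   (e.g. \code{c("POPC", "POPE", "Sph", "GM3", "CHOL", "POPS", "PIP2")})
#' @param headgroupName optional atom-name filter for the headgroup bead
#'   within each lipid residue (NULL: all beads of the lipid)
#' @param cutoff nm (default 0.65)
#' @return named list of [ContactSeries-class], one per lipid type
#' @export
cgLipidContacts <- function(traj, proteinSelection, lipidTypes,
                            headgroupName = NULL, cutoff = 0.65) {
  crit <- contactCriterion(probe = "first_sidechain_bead", cutoff = cutoff,
                           partnerNames = headgroupName %||% "headgroup")
  out <- list()
  for (lt in lipidTypes) {
    expr <- paste("resname", lt)
    if (!is.null(headgroupName)) expr <- paste(expr, "and name", headgroupName)
    sel <- tryCatch(atomSelect(traj, expr, label = lt),
                    error = function(e) stop("unknown lipid type '", lt,
                                             "': ", conditionMessage(e)))
    out[[lt]] <- residueLipidContacts(traj, proteinSelection, sel, crit)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname occupancy
#' @export
setMethod("occupancy", "ContactSeries", function(x, ...) {
  cbind(x@residues, occupancy = rowMeans(x@hits))
})

#' @rdname nFrames
#' @export
setMethod("nFrames", "ContactSeries", function(x) length(x@times))

setMethod("show", "ContactSeries", function(object) {
  occ <- rowMeans(object@hits)
  cat(sprintf(
    "ContactSeries: %d residues x %d frames (cutoff %.3g nm), %d residues ever in contact\n",
    nrow(object@hits), ncol(object@hits), object@criterion$cutoff,
    sum(occ > 0)))
})

#' Pool contact series over replicas
#'
#' Pooled occupancy counts every frame of every replica equally; for
#' equal-length replicas this equals the mean of per-replica occupancies.
#'
#' @param seriesList list of [ContactSeries-class] over the same residues
#' @return data.frame of residues with pooled \code{occupancy}
#' @export
poolContactSeries <- function(seriesList) {
  r0 <- seriesList[[1]]@residues
  for (s in seriesList[-1])
    if (!identical(s@residues$resid, r0$resid) ||
        !identical(s@residues$segid, r0$segid))
      stop("replicas cover different residues")
  tot <- Reduce(`+`, lapply(seriesList, function(s) rowSums(s@hits)))
  nf <- sum(vapply(seriesList, function(s) ncol(s@hits), numeric(1)))
  cbind(r0, occupancy = tot / nf)
}

#' Protein-protein contact occupancy over multiple copies
#'
#' For every residue of every copy: the fraction of frames in which any of
#' its particles lies strictly within the cutoff of any particle of a
#' different copy (minimum image).  Copy selections must be disjoint.
#'
#' @param traj a [Trajectory-class]
#' @param copies list of [Selection-class], one per protein copy
#' @param cutoff contact cutoff, nm (default 0.65, the coarse-grained
#'   headgroup cutoff reused as a declared assumption)
#' @return data.frame: \code{copy}, \code{resid}, \code{resname},
#'   \code{segid}, \code{occupancy}
#' @export
proteinProteinContacts <- function(traj, copies, cutoff = 0.65) {
  if (length(copies) < 2L) stop("need at least two copies")
  idxList <- lapply(copies, function(s)
    if (is.character(s)) atomSelect(traj, s)@indices else s@indices)
  all_idx <- unlist(idxList)
  if (anyDuplicated(all_idx)) stop("copy selections overlap")
  top <- topologyOf(traj)
  resList <- lapply(idxList, function(ii) residueTable(top, ii))
  nf <- nFrames(traj)
  occ <- lapply(resList, function(r) numeric(nrow(r)))
  for (f in seq_len(nf)) {
    xyz <- frameCoords(traj, f)
    box <- boxDims(traj, f)
    if (anyNA(box)) box <- NULL
    for (ci in seq_along(idxList)) {
      others <- xyz[unlist(idxList[-ci]), , drop = FALSE]
      mine <- xyz[idxList[[ci]], , drop = FALSE]
      hit <- anyWithin(mine, others, cutoff, box)
      names(hit) <- idxList[[ci]]
      r <- resList[[ci]]
      resHit <- vapply(r$atomIdx, function(ii)
        any(hit[as.character(ii)]), logical(1))
      occ[[ci]] <- occ[[ci]] + resHit
    }
  }
  out <- do.call(rbind, lapply(seq_along(resList), function(ci) {
    r <- resList[[ci]]
    data.frame(copy = ci, resid = r$resid, resname = r$resname,
               segid = r$segid, occupancy = occ[[ci]] / nf,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Residues above an occupancy threshold
#'
#' Strict comparison: a residue passes only when its occupancy exceeds the
#' threshold (default 2.5 percent of total time).  Results are sorted by
#' occupancy, descending.
#'
#' @param occupancyTable data.frame with an \code{occupancy} column (from
#'   [occupancy()], [poolContactSeries()] or [proteinProteinContacts()])
#' @param fraction threshold fraction (default 0.025)
#' @return the qualifying rows, occupancy-descending
#' @export
thresholdMask <- function(occupancyTable, fraction = 0.025) {
  keep <- occupancyTable$occupancy > fraction
  out <- occupancyTable[keep, , drop = FALSE]
  out[order(-out$occupancy), , drop = FALSE]
}
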