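#' Read a structure file (PDB or GRO)
#'
#' Returns a one-frame [Trajectory-class] (topology plus coordinates and
#' box).  PDB coordinates (Angstrom) are converted to nm; GRO files are
#' already in nm.  Orthorhombic boxes only: a triclinic GRO box line or a
#' CRYST1 record with non-90-degree angles raises an error.
#'
#' @param path file path; format chosen by extension (.pdb / .gro)
#' @param isBead mark all atoms as coarse-grained beads (mass 72 amu unless
#'   names resolve to elements)
#' @return a [Trajectory-class] with a single frame
#' @export
readStructure <- function(path, isBead = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gro = readGRO(path, isBead = isBead),
    pdb = readPDBFile(path, isBead = isBead, multi = FALSE),
    stop("unsupported structure format '.", ext, "' (use PDB or GRO)"))
}

#' Read a coordinate trajectory
#'
#' Supported formats: multi-model PDB, multi-frame GRO (concatenated
#' blocks), and DCD (via bio3d; lengths converted Angstrom to nm).
#' XTC and TRR are not supported and raise an explicit error.
#'
#' @param path trajectory file path
#' @param topology the [Topology-class] the frames belong to; atom counts
#'   must match
#' @param dt frame spacing in ps used when the format carries no times
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(path, topology, dt = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  # file-derived masses are placeholders here (the caller's topology is
  # rebound below), so mass-inference warnings are noise
  traj <- switch(ext,
    pdb = suppressWarnings(readPDBFile(path, multi = TRUE)),
    gro = suppressWarnings(readGRO(path)),
    dcd = readDCDFile(path, topology),
    xtc = ,
    trr = stop("XTC/TRR reading is not supported; convert to multi-model ",
               "PDB or DCD"),
    stop("unsupported trajectory format '.", ext, "'"))
  if (nAtoms(traj) != nAtoms(topology))
    stop(sprintf("trajectory has %d atoms but topology has %d",
                 nAtoms(traj), nAtoms(topology)))
  if (all(traj@times == seq_len(nFrames(traj)) - 1))
    traj@times <- (seq_len(nFrames(traj)) - 1) * dt
  # rebind the caller's topology (file-derived masses may be placeholders)
  new("Trajectory", topology = topology, coords = traj@coords,
      box = traj@box, times = traj@times)
}

# ---- GRO ------------------------------------------------------------------

readGRO <- function(path, isBead = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  frames <- list(); boxes <- list(); times <- numeric(0)
  top <- NULL
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L)
      stop("GRO parse error at line ", i + 1L, ": bad atom count")
    if (i + 1L + nat + 1L > length(lines))
      stop("GRO file truncated (missing box line after atoms)")
    block <- lines[(i + 2L):(i + 1L + nat)]
    resid <- suppressWarnings(as.integer(substr(block, 1, 5)))
    resname <- trimws(substr(block, 6, 10))
    name <- trimws(substr(block, 11, 15))
    xyz <- matrix(NA_real_, nat, 3L)
    for (k in 1:3) {
      f <- substr(block, 21 + (k - 1) * 8, 28 + (k - 1) * 8)
      xyz[, k] <- suppressWarnings(as.numeric(f))
    }
    bad <- which(!is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) |
                 !is.finite(xyz[, 3]) | is.na(resid))
    if (length(bad))
      stop("GRO parse error at line ", i + 1L + bad[1],
           ": non-finite coordinate or bad residue field")
    bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                               "\\s+")[[1]]))
    if (length(bv) < 3L || anyNA(bv))
      stop("GRO box line missing or unparseable at line ", i + 2L + nat)
    if (length(bv) > 3L && any(abs(bv[4:length(bv)]) > 1e-9))
      stop("triclinic GRO box is not supported (orthorhombic only)")
    if (is.null(top))
      top <- Topology(name = name, resname = resname, resid = resid,
                      segid = "", isBead = isBead)
    t0 <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(t0))
      as.numeric(sub("t=\\s*", "", t0)) else length(frames))
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bv[1:3]
    i <- i + nat + 3L
  }
  Trajectory(top, frames, box = do.call(rbind, boxes), times = times)
}

#' Write a structure or trajectory as GRO
#'
#' Multi-frame trajectories are written as concatenated GRO blocks with the
#' frame time recorded in each title line, a convention the [readTrajectory()]
#' GRO reader round-trips.
#'
#' @param traj a [Trajectory-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGRO <- function(traj, path) {
  a <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    b <- boxDims(traj, f)
    if (anyNA(b)) b <- apply(xyz, 2, function(v) diff(range(v)) + 2)
    writeLines(sprintf("memborient t= %.4f", frameTimes(traj)[f]), con)
    writeLines(sprintf("%5d", nAtoms(traj)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000L, substr(a$resname, 1, 5),
                       substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
  }
  invisible(path)
}

# ---- PDB (bio3d) ----------------------------------------------------------

readPDBFile <- function(path, isBead = FALSE, multi = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  seg <- at$chain
  seg[is.na(seg) | !nzchar(seg)] <- ""
  top <- Topology(name = at$elety, resname = at$resid, resid = at$resno,
                  segid = seg, isBead = isBead)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (!all(is.finite(xyz))) stop("non-finite coordinate in PDB file: ", path)
  nf <- nrow(xyz)
  frames <- lapply(seq_len(nf), function(f)
    matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10)
  box <- readCryst1(path)
  Trajectory(top, frames, box = box)
}

# Parse the CRYST1 record ourselves (orthorhombic check).
readCryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 500L), value = TRUE)
  if (!length(ln)) return(NA_real_)
  v <- suppressWarnings(as.numeric(c(
    substr(ln[1], 7, 15), substr(ln[1], 16, 24), substr(ln[1], 25, 33),
    substr(ln[1], 34, 40), substr(ln[1], 41, 47), substr(ln[1], 48, 54))))
  if (anyNA(v)) return(NA_real_)
  if (any(abs(v[4:6] - 90) > 1e-3))
    stop("triclinic CRYST1 box is not supported (orthorhombic only)")
  v[1:3] / 10
}

readDCDFile <- function(path, topology) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10)
  Trajectory(topology, frames, box = NA_real_)
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Coordinates are converted nm to Angstrom.  Segment ids are written to the
#' chain column (first character) and the segid column; an orthorhombic box
#' becomes a CRYST1 record.
#'
#' @param traj a [Trajectory-class]
#' @param path output path
#' @param bFactor optional per-atom values stamped into the B-factor column
#'   (frame-independent), e.g. contact occupancies for visualization
#' @return \code{path}, invisibly
#' @export
writePDB <- function(traj, path, bFactor = NULL) {
  a <- atoms(traj)
  b <- boxDims(traj, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!anyNA(b))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1] * 10, b[2] * 10, b[3] * 10, 90, 90, 90), con)
  if (is.null(bFactor)) bFactor <- rep(0, nrow(a))
  chain <- substr(ifelse(nzchar(a$segid), a$segid, "A"), 1, 1)
  nf <- nFrames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frameCoords(traj, f) * 10
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
      seq_len(nrow(a)) %% 100000L, substr(nm, 1, 4), substr(a$resname, 1, 3),
      chain, a$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      1, pmin(bFactor, 999.99), substr(a$segid, 1, 4)), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
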