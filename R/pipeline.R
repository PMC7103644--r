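#' Parse a length with explicit units
#'
#' Config cutoffs carry explicit units to avoid Angstrom/nm mix-ups:
#' \code{"5 A"} parses to 0.5 nm, \code{"0.65 nm"} to 0.65 nm.  Bare
#' numbers are taken as nm.
#'
#' @param x character like "5 A", "6.5 angstrom", "0.5 nm", or a number
#' @return length in nm
#' @export
parseLength <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(x)
  m <- regmatches(x, regexec("^([-0-9.eE+]+)\\s*([A-Za-z]*)$", x))[[1]]
  if (length(m) < 2L || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse length: '", x, "'")
  val <- as.numeric(m[2])
  unit <- tolower(m[3])
  if (unit %in% c("", "nm")) return(val)
  if (unit %in% c("a", "ang", "angstrom")) return(val / 10)
  stop("unknown length unit '", m[3], "' in '", x, "'")
}

#' Run the full analysis pipeline from a declarative config
#'
#' Executes the requested stages (simulate, orient, tilt, rmsd, mindist,
#' lipid_contacts, protein_contacts, cluster, rdf) in order over a synthetic
#' scene or input files, writing one or more CSVs per stage plus a JSON
#' provenance record (inputs, parameters, seed, package version, wall time)
#' and a stage-status manifest.  A failing stage stops execution with the
#' stage name and cause; completed stages' outputs remain on disk.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   See the bundled example under \code{system.file("extdata",
#'   "demo_config.yaml", package = "memborient")}.
#' @param outDir output directory (created if needed); defaults to the
#'   config's \code{out_dir} or "."
#' @return (invisibly) named list of per-stage output file paths
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  outDir <- outDir %||% cfg$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prefix <- cfg$out_prefix %||% "memborient"
  seed <- as.integer(cfg$seed %||% 1L)
  stages <- cfg$stages
  if (is.null(stages)) stop("config must list 'stages'")
  outPath <- function(...) file.path(outDir, paste0(prefix, "_", ...))
  logMsg <- function(stage, ...) message("[", stage, "] ", ...)

  # ---- inputs -------------------------------------------------------------
  scene <- NULL
  traj <- NULL
  copies <- NULL
  if (!is.null(cfg$scene)) {
    sc <- cfg$scene
    kind <- sc$kind %||% stop("scene needs a 'kind'")
    scene <- switch(kind,
      rigid_body = makeRigidBody(
        nParticles = sc$n_particles %||% 500L,
        schedule = if (identical(sc$schedule, "stationary"))
          stationaryPitchSchedule(mean = sc$pitch_mean %||% 30,
                                  sd = sc$pitch_sd %||% 1.5,
                                  nFrames = sc$n_frames %||% 1000L,
                                  seed = seed)
        else pitchRampSchedule(sc$pitch_from %||% 0, sc$pitch_to %||% 60,
                               sc$n_frames %||% 100L),
        noiseSd = sc$noise_sd %||% 0, seed = seed),
      multicopy_scene = makeMulticopyScene(
        planted = unlist(sc$planted %||% c(3, 2, rep(1, 31))),
        nFrames = sc$n_frames %||% 10L,
        diffusionSd = sc$diffusion_sd %||% 0,
        cutoff = parseLength(sc$cutoff %||% 0.65), seed = seed),
      ideal_helix = list(trajectory = makeIdealHelix(
        nResidues = sc$n_residues %||% 36L, tilt = sc$tilt %||% 0)),
      bilayer_surrogate = list(trajectory = makeBilayerSurrogate(
        upper = unlist(sc$upper), lower = unlist(sc$lower %||% sc$upper),
        seed = seed)),
      stop("unknown scene kind: ", kind))
    traj <- scene$trajectory
    copies <- scene$copies
  } else {
    if (is.null(cfg$topology)) stop("config needs 'scene' or 'topology'")
    ref <- readStructure(cfg$topology)
    top <- topologyOf(ref)
    traj <- if (!is.null(cfg$trajectory))
      readTrajectory(cfg$trajectory, top) else ref
  }
  selections <- cfg$selections %||% list()
  getSel <- function(label) {
    if (is.null(selections[[label]]))
      stop("selection '", label, "' is not defined in the config")
    atomSelect(traj, selections[[label]], label = label)
  }
  # validate all referenced selections before any computation
  for (st in stages) {
    p <- cfg[[st]] %||% list()
    for (key in c("selection", "group_a", "group_b", "protein"))
      if (!is.null(p[[key]])) getSel(p[[key]])
  }

  results <- list()
  status <- list()
  writeStage <- function(stage, tables, params) {
    files <- character(0)
    for (nm in names(tables)) {
      f <- outPath(stage, "_", nm, ".csv")
      utils::write.csv(tables[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    prov <- list(stage = stage, params = params, seed = seed,
                 package = "memborient",
                 version = as.character(utils::packageVersion("memborient")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 outputs = basename(files))
    pf <- outPath(stage, "_provenance.json")
    jsonlite::write_json(prov, pf, auto_unbox = TRUE, digits = NA)
    results[[stage]] <<- c(files, pf)
    status[[stage]] <<- "ok"
    files
  }

  for (stage in stages) {
    p <- cfg[[stage]] %||% list()
    t0 <- Sys.time()
    tryCatch(switch(stage,
      simulate = {
        if (is.null(scene)) stop("simulate stage needs a 'scene' block")
        writeGRO(traj, outPath("scene.gro"))
        writePDB(traj, outPath("scene.pdb"))
        tabs <- list()
        if (!is.null(scene$truth)) tabs$truth <- scene$truth
        writeStage("simulate", tabs, cfg$scene)
        logMsg("simulate", "wrote scene (", nAtoms(traj), " atoms, ",
               nFrames(traj), " frames)")
      },
      orient = {
        sel <- getSel(p$selection %||% "domain")
        mode <- p$reference %||% "standard"
        os <- orientationSeries(traj, sel,
          referenceMode = if (mode %in% c("first-frame", "firstFrame"))
            "firstFrame" else "standard")
        bw <- p$bin_width %||% 1
        hist <- angleHistogram(os, binWidth = bw)
        heat <- angleHeatmapTable(list(os))
        writeStage("orient", list(
          angles = angles(os), hist = hist,
          heatmap = as.data.frame(heat)), p)
        logMsg("orient", "pitch range ",
               paste(round(range(angles(os)$pitch), 2), collapse = ".."))
      },
      tilt = {
        sel <- getSel(p$selection %||% "helix")
        ts <- tiltSeries(traj, sel)
        writeStage("tilt", list(series = ts,
          hist = angleHistogram(ts$tilt, binWidth = p$bin_width %||% 1,
                                range = c(0, 90))), p)
      },
      rmsd = {
        sel <- getSel(p$selection %||% "domain")
        writeStage("rmsd", list(series = rmsdSeries(traj, sel)), p)
      },
      mindist = {
        d <- minDistanceSeries(traj, getSel(p$group_a), getSel(p$group_b),
                               mode = p$mode %||% "com")
        writeStage("mindist", list(series = d), p)
      },
      lipid_contacts = {
        sel <- getSel(p$protein %||% "protein")
        cutoff <- parseLength(p$cutoff %||% "5 A")
        partner <- getSel(p$partner %||% "headgroups")
        cs <- residueLipidContacts(traj, sel, partner,
          contactCriterion(probe = p$probe %||% "sidechain_com",
                           cutoff = cutoff))
        occ <- occupancy(cs)
        occ$passes_threshold <- occ$occupancy > (p$threshold %||% 0.025)
        writeStage("lipid_contacts", list(occupancy = occ), p)
      },
      protein_contacts = {
        if (is.null(copies)) stop("protein_contacts needs a multicopy scene")
        occ <- proteinProteinContacts(traj, copies,
          cutoff = parseLength(p$cutoff %||% 0.65))
        occ$passes_threshold <- occ$occupancy > (p$threshold %||% 0.025)
        writeStage("protein_contacts", list(occupancy = occ), p)
      },
      cluster = {
        if (is.null(copies)) stop("cluster stage needs a multicopy scene")
        cts <- clusterTimeSeries(traj, copies,
          cutoff = parseLength(p$cutoff %||% 0.65),
          window = p$window %||% 1L)
        part <- data.frame(copy = seq_len(nrow(cts@assignment)))
        part <- cbind(part, as.data.frame(cts@assignment))
        names(part)[-1] <- paste0("frame", seq_len(ncol(cts@assignment)))
        writeStage("cluster", list(partition = part,
          size_occupancy = clusterSizeOccupancy(cts)), p)
      },
      rdf = {
        protein <- getSel(p$protein %||% "protein")
        types <- p$lipid_types %||% stop("rdf stage needs 'lipid_types'")
        lip <- lapply(types, function(ty) paste("resname", ty))
        names(lip) <- types
        prof <- computeRDF(traj, protein, lip,
          mode = p$mode %||% "surface",
          binWidth = p$bin_width %||% 0.02,
          rMax = if (!is.null(p$rmax)) parseLength(p$rmax) else NULL,
          seed = seed)
        writeStage("rdf", list(profile = rdfTable(prof)), p)
      },
      stop("unknown stage: ", stage)),
      error = function(e) {
        status[[stage]] <<- paste("failed:", conditionMessage(e))
        writeManifest(outPath, status)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    logMsg(stage, sprintf("done in %.2f s",
                          as.numeric(Sys.time() - t0, units = "secs")))
  }
  writeManifest(outPath, status)
  invisible(results)
}

writeManifest <- function(outPath, status) {
  jsonlite::write_json(status, outPath("manifest.json"), auto_unbox = TRUE)
}
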