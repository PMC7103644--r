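#' Construct a Topology
#'
#' @param name character atom names
#' @param resname character residue names
#' @param resid integer residue ids (as in the source file, usually 1-based)
#' @param segid character segment / chain ids ("" when the format has none)
#' @param mass numeric masses in amu; when NULL, inferred from atom names for
#'   atomistic systems ([inferMasses()]) or set to the standard 72 amu bead
#'   mass when \code{isBead} is TRUE
#' @param isBead logical coarse-grained flag (scalar or per atom)
#' @return a [Topology-class]
#' @examples
#' top <- Topology(name = c("N", "CA", "C"), resname = "ALA", resid = 1L)
#' nAtoms(top)
#' @export
Topology <- function(name, resname = "UNK", resid = 1L, segid = "",
                     mass = NULL, isBead = FALSE) {
  n <- length(name)
  isBead <- rep_len(as.logical(isBead), n)
  if (is.null(mass)) {
    mass <- ifelse(isBead, 72, inferMasses(name))
  }
  a <- data.frame(
    name = as.character(name),
    resname = rep_len(as.character(resname), n),
    resid = rep_len(as.integer(resid), n),
    segid = rep_len(as.character(segid), n),
    mass = rep_len(as.numeric(mass), n),
    isBead = isBead,
    stringsAsFactors = FALSE)
  new("Topology", atoms = a)
}

#' Infer atomic masses from atom names
#'
#' Uses the leading element letter of standard PDB/GRO atom names
#' (H, C, N, O, P, S); unknown names fall back to carbon (12.011) with a
#' warning.  Intended for structure files that carry no mass information.
#'
#' @param name character vector of atom names
#' @return numeric vector of masses, amu
#' @export
inferMasses <- function(name) {
  el <- sub("^[0-9]*", "", toupper(name))
  two <- substr(el, 1, 2)
  one <- substr(el, 1, 1)
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, K = 39.098, F = 18.998)
  tab2 <- c(CL = 35.45, "NA" = 22.990, MG = 24.305, ZN = 65.38)
  m <- unname(tab[one])
  m2 <- unname(tab2[two])
  # two-letter ions only when the full name is the element symbol
  use2 <- !is.na(m2) & el %in% c("CL", "NA", "MG", "ZN")
  m[use2] <- m2[use2]
  if (anyNA(m)) {
    warning("unknown element for atom name(s) ",
            paste(unique(name[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- 12.011
  }
  m
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname atoms
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, %d segments%s\n",
              nrow(a), length(unique(paste(a$segid, a$resid))),
              length(unique(a$segid)),
              if (any(a$isBead)) " (coarse-grained)" else ""))
})

#' Residue table of a Topology
#'
#' One row per (segid, resid) pair in order of first appearance, with the
#' atom indices belonging to each residue.
#'
#' @param topology a [Topology-class]
#' @param indices optional atom indices (or a [Selection-class]) restricting
#'   the table
#' @return data.frame with columns \code{resid}, \code{resname}, \code{segid}
#'   and a list-column \code{atomIdx}
#' @export
residueTable <- function(topology, indices = NULL) {
  a <- atoms(topology)
  idx <- resolveIndices(indices, nrow(a))
  key <- paste(a$segid[idx], a$resid[idx], sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    resid = a$resid[idx][first],
    resname = a$resname[idx][first],
    segid = a$segid[idx][first],
    stringsAsFactors = FALSE)
  out$atomIdx <- unname(split(idx, factor(key, levels = key[first])))
  out
}

# Normalize NULL / integer vector / Selection to an integer index vector.
resolveIndices <- function(indices, n) {
  if (is.null(indices)) return(seq_len(n))
  if (is(indices, "Selection")) indices <- indices@indices
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("empty atom index set")
  if (any(indices < 1L | indices > n))
    stop("atom indices out of range 1..", n)
  indices
}
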