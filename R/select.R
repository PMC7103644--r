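#' Select atoms by a simple expression
#'
#' The selection mini-language is a conjunction of clauses joined by
#' \code{and}.  Each clause is a keyword followed by one or more values:
#' \itemize{
#'   \item \code{name CA P N} -- atom names
#'   \item \code{resname POPC POPE} -- residue names
#'   \item \code{resid 153-189 200} -- residue ids, single or dashed ranges
#'   \item \code{segid A B} -- segment / chain ids
#'   \item \code{index 1-30} -- 1-based atom indices
#'   \item \code{all} -- every atom
#' }
#' Examples used throughout: \code{"segid A and resid 153-189"} (the
#' transmembrane helix of one chain), \code{"name P"} (phosphorus markers of
#' the lipid headgroups).
#'
#' @param topology a [Topology-class] (or [Trajectory-class])
#' @param expression selection string
#' @param label selection label (defaults to the expression)
#' @return a [Selection-class]; an empty result is an error, since the
#'   analyses are undefined on empty selections
#' @export
atomSelect <- function(topology, expression, label = expression) {
  if (is(topology, "Trajectory")) topology <- topologyOf(topology)
  a <- atoms(topology)
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) == 0L) stop("empty selection clause in: ", expression)
    kw <- tolower(tok[1])
    vals <- tok[-1]
    if (kw == "all") next
    if (length(vals) == 0L)
      stop("selection keyword '", kw, "' needs at least one value")
    keep <- keep & switch(kw,
      name = a$name %in% vals,
      resname = a$resname %in% vals,
      resid = a$resid %in% expandRanges(vals),
      index = seq_len(nrow(a)) %in% expandRanges(vals),
      segid = a$segid %in% vals,
      stop("unknown selection keyword: ", kw))
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selection '", expression, "' matched no atoms")
  new("Selection", label = label, indices = as.integer(idx))
}

expandRanges <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+[-:][0-9]+$", v)) {
      sep <- if (grepl(":", v)) ":" else "-"
      p <- strsplit(sub("^(-?[0-9]+)", "\\1\r", v), paste0("\r", sep))[[1]]
      out <- c(out, as.integer(p[1]):as.integer(p[2]))
    } else {
      n <- suppressWarnings(as.integer(v))
      if (is.na(n)) stop("bad numeric value in selection: ", v)
      out <- c(out, n)
    }
  }
  out
}

#' Indices of a Selection
#' @param sel a [Selection-class]
#' @return sorted integer atom indices (1-based)
#' @export
selectionIndices <- function(sel) sel@indices

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection '%s': %d atoms\n", object@label,
              length(object@indices)))
})
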