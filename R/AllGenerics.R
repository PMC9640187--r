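#' @rdname Trajectory-class
#' @param x a [Trajectory] or [Topology].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname Topology-class
#' @param x a [Topology] or [Trajectory].
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Extract the coordinates of one frame
#'
#' @param x a [Trajectory].
#' @param i frame index (1-based).
#' @param sel optional [AtomSelection] restricting the atoms.
#' @return numeric `n x 3` matrix of Angstrom coordinates.
#' @export
setGeneric("frameCoords", function(x, i = 1L, sel = NULL)
  standardGeneric("frameCoords"))

#' Resolve an atom selection expression
#'
#' The selection language covers the vocabulary needed for linker-region
#' analyses: `all`, `backbone` (N, CA, C, O), `heavy` (element != H),
#' `polar` (element in N, O, S, P), `hydrogen`, `name <N1> <N2> ...`,
#' `resid <a>-<b>` or `resid <a> <b> ...`, `chain <c>`,
#' `element <e> ...`, combined left-associatively with `and` / `or`,
#' and negated with a leading `not` inside a term.
#'
#' @param x a [Topology] or [Trajectory].
#' @param expr selection expression string.
#' @return an [AtomSelection]; empty selections are allowed but warned about.
#' @examples
#' traj <- makeIdealHelix(nRes = 12, withBackbone = TRUE)
#' selectAtoms(traj, "backbone and resid 3-10")
#' @export
setGeneric("selectAtoms", function(x, expr) standardGeneric("selectAtoms"))

setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
setMethod("topology", "Trajectory", function(x) x@topology)
setMethod("atomData", "Topology", function(x) x@atoms)
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

setMethod("frameCoords", "Trajectory", function(x, i = 1L, sel = NULL) {
  stopifnot(length(i) == 1, i >= 1, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(x@coords)[1:2]
  colnames(m) <- c("x", "y", "z")
  if (!is.null(sel)) m <- m[selIndices(sel), , drop = FALSE]
  m
})

#' @rdname AtomSelection-class
#' @param sel an [AtomSelection].
#' @export
selIndices <- function(sel) {
  if (is(sel, "AtomSelection")) sel@indices else as.integer(sel)
}

#' @rdname AtomSelection-class
#' @param a,b [AtomSelection] objects on the same topology.
#' @export
selectionUnion <- function(a, b) {
  new("AtomSelection",
      indices = sort(union(selIndices(a), selIndices(b))),
      label = paste0("(", a@label, ") or (", b@label, ")"))
}

#' @rdname AtomSelection-class
#' @export
selectionIntersect <- function(a, b) {
  new("AtomSelection",
      indices = sort(intersect(selIndices(a), selIndices(b))),
      label = paste0("(", a@label, ") and (", b@label, ")"))
}

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resid))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nAtoms(object), "atoms x", nFrames(object), "frames\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "AtomSelection", function(object) {
  cat("AtomSelection '", object@label, "': ", length(object@indices),
      " atoms\n", sep = "")
})

setMethod("show", "RMSDMap", function(object) {
  cat("RMSDMap:", nrow(object@matrix), "x", ncol(object@matrix),
      "frames | fit:", object@fitSel, "| measure:", object@measureSel, "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@medoids), "clusters over",
      length(object@labels), "frames\n")
  cat("  sizes:", paste(tabulate(object@labels), collapse = ", "), "\n")
})

setMethod("show", "HelixDescriptor", function(object) {
  cat(sprintf(
    "HelixDescriptor resid %d-%d | length %.2f A | bend radius %s A\n",
    object@residueSpan[1], object@residueSpan[2], object@length,
    if (object@bendRadius >= 1000) ">=1000 (straight)"
    else sprintf("%.1f", object@bendRadius)))
})

setMethod("show", "SSETimeline", function(object) {
  cat("SSETimeline:", nrow(object@codes), "residues x", ncol(object@codes),
      "frames\n")
})
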