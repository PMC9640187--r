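#' @import methods
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "MSE", "HOH", "TIP3", "WAT"
)

#' Topology: atom metadata for a structure
#'
#' Ordered per-atom metadata shared by every frame of a [Trajectory].
#' Atom order is file order; `(chain, resid, name)` is unique.
#'
#' @slot atoms `data.frame` with columns `serial` (integer), `name`
#'   (short atom name, e.g. `"CA"`), `element` (one of `C,N,O,S,P,H,other`),
#'   `resname` (3-letter residue name), `resid` (integer residue number),
#'   `chain` (1-character chain identifier).
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "chain")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("topology must contain at least one atom")
  if (any(is.na(a$element) | a$element == ""))
    return("every atom needs a nonempty element")
  key <- paste(a$chain, a$resid, a$name)
  if (anyDuplicated(key))
    return("(chain, resid, name) must be unique across atoms")
  TRUE
})

#' Trajectory: a conformational ensemble bound to one Topology
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom.
#' All frames share one [Topology]; per-frame times (ns) are optional.
#'
#' @slot topology a [Topology].
#' @slot coords numeric array, `n_atoms x 3 x n_frames`, finite.
#' @slot times numeric vector of frame times in ns (may be length 0).
#' @slot metadata list of generator ground truth or provenance notes.
#' @export
setClass("Trajectory", representation(
  topology = "Topology", coords = "array", times = "numeric",
  metadata = "list"
), prototype(times = numeric(0), metadata = list()))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[3] < 1) return("trajectory needs at least one frame")
  if (d[1] != nrow(object@topology@atoms))
    return("coords atom count does not match topology")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@times) && length(object@times) != d[3])
    return("times must match the number of frames")
  TRUE
})

#' AtomSelection: an ordered set of atom indices into a Topology
#'
#' @slot indices strictly increasing integer vector of 1-based atom indices.
#' @slot label human-readable label (usually the selection expression).
#' @export
setClass("AtomSelection",
         representation(indices = "integer", label = "character"),
         prototype(label = ""))

setValidity("AtomSelection", function(object) {
  i <- object@indices
  if (length(i) && (any(i < 1) || is.unsorted(i, strictly = TRUE)))
    return("indices must be strictly increasing positive integers")
  TRUE
})

#' Steric-clash distance thresholds
#'
#' Element-dependent heavy-atom distance thresholds below which an atom pair
#' is counted as a clash: pairs involving S use `thresholdS`, otherwise pairs
#' involving N or O use `thresholdNO`, otherwise `thresholdC`. Defaults are
#' the published values (2.10, 1.68 and 1.65 Angstrom).
#'
#' @slot thresholdS,thresholdNO,thresholdC numeric thresholds in Angstrom.
#' @export
setClass("ClashParams", representation(
  thresholdS = "numeric", thresholdNO = "numeric", thresholdC = "numeric"
), prototype(thresholdS = 2.10, thresholdNO = 1.68, thresholdC = 1.65))

setValidity("ClashParams", function(object) {
  if (object@thresholdS <= 0 || object@thresholdNO <= 0 ||
      object@thresholdC <= 0) return("thresholds must be positive")
  if (!(object@thresholdS >= object@thresholdNO &&
        object@thresholdNO >= object@thresholdC))
    return("expected thresholdS >= thresholdNO >= thresholdC")
  TRUE
})

#' Geometric hydrogen-bond parameters
#'
#' A hydrogen bond X...H-Y requires polar heavy atoms X and Y, an X...H-Y
#' angle above `angleMin` and an X-H distance below an acceptor-element
#' threshold. Defaults are the published criteria: angle > 120 degrees and
#' X-H thresholds 2.52 (N), 2.52 (O), 3.24 (P) and 3.15 (S) Angstrom.
#' `minSeqSep` (5 residues) and `minOccupancy` (0.15) are the residue-pair
#' track filters.
#'
#' @slot angleMin minimum X...H-Y angle, degrees.
#' @slot thresholds named numeric, X-H distance cutoffs per acceptor element.
#' @slot minSeqSep minimum |resid difference| for a tracked residue pair.
#' @slot minOccupancy minimum fraction of frames a tracked pair is bonded.
#' @export
setClass("HBondParams", representation(
  angleMin = "numeric", thresholds = "numeric",
  minSeqSep = "numeric", minOccupancy = "numeric"
), prototype(
  angleMin = 120,
  thresholds = c(N = 2.52, O = 2.52, P = 3.24, S = 3.15),
  minSeqSep = 5, minOccupancy = 0.15
))

setValidity("HBondParams", function(object) {
  if (object@angleMin <= 0 || object@angleMin >= 180)
    return("angleMin must lie in (0, 180)")
  if (any(object@thresholds <= 0)) return("thresholds must be positive")
  if (!all(c("N", "O", "P", "S") %in% names(object@thresholds)))
    return("thresholds must name acceptors N, O, P and S")
  TRUE
})

#' Pairwise RMSD map over evenly spaced frames
#'
#' @slot frameIndices integer frame indices sampled from the trajectory.
#' @slot matrix symmetric, zero-diagonal matrix of RMSDs (Angstrom).
#' @slot fitSel,measureSel labels of the superposition and measured
#'   selections.
#' @export
setClass("RMSDMap", representation(
  frameIndices = "integer", matrix = "matrix",
  fitSel = "character", measureSel = "character"
))

setValidity("RMSDMap", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (nrow(m) != length(object@frameIndices))
    return("frameIndices must match matrix dimension")
  if (any(m < 0)) return("RMSDs must be nonnegative")
  if (any(abs(diag(m)) > 1e-8)) return("diagonal must be zero")
  if (any(abs(m - t(m)) > 1e-8)) return("matrix must be symmetric")
  TRUE
})

#' k-medoid clustering result
#'
#' @slot labels integer cluster id per sampled frame (1..k).
#' @slot medoids row index (into the RMSD map) of each cluster medoid.
#' @slot representatives row index of each cluster's minimax representative
#'   (the member with the lowest maximum RMSD to the rest of its cluster).
#' @slot frameIndices trajectory frame indices of the sampled rows.
#' @export
setClass("ClusterResult", representation(
  labels = "integer", medoids = "integer", representatives = "integer",
  frameIndices = "integer"
))

setValidity("ClusterResult", function(object) {
  k <- length(object@medoids)
  if (length(object@representatives) != k)
    return("one representative per medoid required")
  if (any(object@labels < 1 | object@labels > k))
    return("labels must lie in 1..k")
  for (c in seq_len(k)) {
    if (object@labels[object@medoids[c]] != c)
      return("each medoid must belong to its own cluster")
    if (object@labels[object@representatives[c]] != c)
      return("each representative must belong to its own cluster")
  }
  TRUE
})

#' Per-helix geometric descriptor
#'
#' Helix geometry derived from the Calpha trace: a fitted axis (point +
#' N-to-C unit direction), end-to-end length, bend radius (radius of the
#' circle fitted to the smoothed local axis points; straight helices are
#' capped), and the local axis points themselves.
#'
#' @slot residueSpan integer(2), first and last residue number.
#' @slot axisPoint numeric(3), centroid of the local axis points (Angstrom).
#' @slot axisDir unit numeric(3), axis direction oriented N to C.
#' @slot length end-to-end Calpha distance (Angstrom).
#' @slot bendRadius fitted bend radius (Angstrom; straight-helix cap 1000).
#' @slot localAxisPoints m x 3 matrix of per-residue axis points.
#' @export
setClass("HelixDescriptor", representation(
  residueSpan = "integer", axisPoint = "numeric", axisDir = "numeric",
  length = "numeric", bendRadius = "numeric", localAxisPoints = "matrix"
))

setValidity("HelixDescriptor", function(object) {
  if (abs(vnorm(object@axisDir) - 1) > 1e-6)
    return("axisDir must be a unit vector")
  if (object@length <= 0) return("length must be positive")
  if (object@bendRadius <= 0) return("bendRadius must be positive")
  TRUE
})

#' Secondary-structure timeline
#'
#' Per-residue, per-frame Kabsch-Sander codes over the alphabet
#' `H,G,I,E,B,T,S,-`.
#'
#' @slot codes character matrix, residues x frames.
#' @slot resid integer residue numbers (row order).
#' @slot chain chain id per row.
#' @export
setClass("SSETimeline", representation(
  codes = "matrix", resid = "integer", chain = "character"
))

setValidity("SSETimeline", function(object) {
  ok <- c("H", "G", "I", "E", "B", "T", "S", "-")
  if (!all(object@codes %in% ok))
    return("codes must be in {H,G,I,E,B,T,S,-}")
  if (nrow(object@codes) != length(object@resid))
    return("resid must match code rows")
  TRUE
})
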