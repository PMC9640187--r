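# Structure input/output and atom selections. Parsing and writing of PDB
# records is delegated to bio3d; this layer binds models into a Trajectory,
# infers elements and resolves selection expressions.

TWO_LETTER_ELEMENTS <- c(
  "BR", "CL", "FE", "ZN", "MG", "MN", "CU", "CO", "NI", "SE", "CA", "NA",
  "CD", "HG", "AS", "SI", "AL", "LI", "BE"
)

#' Infer the element of an atom from its name
#'
#' Precedence: an explicit PDB element-column value wins; otherwise, for
#' non-standard residues, a two-letter leading match against known element
#' symbols (e.g. `FE`, `ZN`); otherwise the first alphabetic character of the
#' atom name. Within standard residues the two-letter match is skipped so
#' that `CA` stays an alpha carbon rather than calcium. Elements outside
#' `{C,N,O,S,P,H}` collapse to `"other"` with a warning.
#'
#' @param name atom name (e.g. `"CA"`, `"OD1"`, `"1HB"`).
#' @param resname 3-letter residue name, used to decide whether two-letter
#'   element symbols are plausible.
#' @param element optional explicit element symbol (PDB columns 77-78).
#' @return one of `"C","N","O","S","P","H","other"`.
#' @export
inferElement <- function(name, resname = "", element = "") {
  mapply(function(nm, rn, el) {
    el <- toupper(trimws(el))
    if (nzchar(el)) return(canonElement(el, nm))
    nm <- toupper(trimws(nm))
    if (!nzchar(nm)) stop("atom name must be nonempty")
    if (!(toupper(rn) %in% STANDARD_AA) &&
        substr(nm, 1, 2) %in% TWO_LETTER_ELEMENTS)
      return(canonElement(substr(nm, 1, 2), nm))
    alpha <- regmatches(nm, regexpr("[A-Z]", nm))
    if (!length(alpha)) {
      warning("cannot resolve element for atom name '", nm, "'")
      return("other")
    }
    canonElement(alpha, nm)
  }, name, resname, element, USE.NAMES = FALSE)
}

canonElement <- function(el, nm) {
  if (el %in% c("C", "N", "O", "S", "P", "H")) return(el)
  if (el %in% TWO_LETTER_ELEMENTS || el %in% c("D", "F", "I", "K", "B"))
    return("other")
  warning("unrecognized element '", el, "' for atom '", nm, "'")
  "other"
}

#' Read a (multi-model) PDB file into a Trajectory
#'
#' MODEL/ENDMDL records delimit frames; a file without MODEL records yields a
#' single frame. The topology is taken from the first model and every model
#' must contain the same number of atoms. Elements come from the PDB element
#' column when present, else from [inferElement()].
#'
#' @param path path to a PDB file.
#' @return a [Trajectory].
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isatom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isatom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(k)
      sum(isatom[bounds[k]:(bounds[k + 1] - 1L)]), integer(1))
    if (length(unique(counts)) != 1)
      stop("inconsistent atom count between models: ",
           paste(unique(counts), collapse = " vs "))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  coords_flat <- pdb$xyz                      # n_frames x 3N
  if (is.null(dim(coords_flat))) coords_flat <- matrix(coords_flat, nrow = 1)
  nfr <- nrow(coords_flat)
  nat <- nrow(a)
  if (any(!is.finite(coords_flat))) stop("non-numeric coordinates in ", path)
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  elesy <- if (!is.null(a$elesy)) ifelse(is.na(a$elesy), "", a$elesy) else ""
  topo <- new("Topology", atoms = data.frame(
    serial = as.integer(a$eleno), name = a$elety,
    element = inferElement(a$elety, a$resid, elesy),
    resname = a$resid, resid = as.integer(a$resno), chain = chain,
    stringsAsFactors = FALSE
  ))
  coords <- array(0, dim = c(nat, 3, nfr))
  for (k in seq_len(nfr))
    coords[, , k] <- matrix(coords_flat[k, ], ncol = 3, byrow = TRUE)
  new("Trajectory", topology = topo, coords = coords,
      metadata = list(source = path))
}

#' Write a Trajectory as a (multi-model) PDB file
#'
#' One MODEL block per frame (a single-frame trajectory is written without
#' MODEL records). Coordinates are written at the PDB's 3-decimal precision.
#'
#' @param traj a [Trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  a <- traj@topology@atoms
  nfr <- nFrames(traj)
  xyz <- matrix(0, nrow = nfr, ncol = 3 * nAtoms(traj))
  for (k in seq_len(nfr))
    xyz[k, ] <- as.vector(t(traj@coords[, , k]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resid,
                   elesy = ifelse(a$element == "other", "", a$element))
  invisible(path)
}

# ---- selection language -----------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O")
POLAR_ELEMENTS <- c("N", "O", "S", "P")

#' @describeIn selectAtoms resolve against a bare topology
setMethod("selectAtoms", "Topology", function(x, expr) {
  idx <- parseSelection(x@atoms, expr)
  if (!length(idx))
    warning("selection '", expr, "' matched no atoms")
  new("AtomSelection", indices = idx, label = expr)
})

#' @describeIn selectAtoms resolve against a trajectory's topology
setMethod("selectAtoms", "Trajectory", function(x, expr)
  selectAtoms(x@topology, expr))

parseSelection <- function(atoms, expr) {
  expr <- trimws(expr)
  if (!nzchar(expr)) stop("empty selection expression")
  toks <- strsplit(expr, "\\s+")[[1]]
  ops <- which(toks %in% c("and", "or"))
  bounds <- c(0L, ops, length(toks) + 1L)
  terms <- lapply(seq_len(length(bounds) - 1L), function(k) {
    t <- toks[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (!length(t)) stop("malformed selection expression: '", expr, "'")
    t
  })
  mask <- evalTerm(atoms, terms[[1]])
  if (length(ops)) {
    for (k in seq_along(ops)) {
      m2 <- evalTerm(atoms, terms[[k + 1L]])
      mask <- if (toks[ops[k]] == "and") mask & m2 else mask | m2
    }
  }
  which(mask)
}

evalTerm <- function(atoms, tok) {
  neg <- FALSE
  while (length(tok) && tok[1] == "not") {
    neg <- !neg
    tok <- tok[-1]
  }
  if (!length(tok)) stop("malformed selection term")
  key <- tolower(tok[1])
  args <- tok[-1]
  mask <- switch(key,
    all = rep(TRUE, nrow(atoms)),
    backbone = atoms$name %in% BACKBONE_NAMES,
    heavy = atoms$element != "H",
    hydrogen = atoms$element == "H",
    polar = ,
    `polar-heavy` = atoms$element %in% POLAR_ELEMENTS,
    name = {
      if (!length(args)) stop("'name' needs at least one atom name")
      atoms$name %in% toupper(args)
    },
    chain = {
      if (!length(args)) stop("'chain' needs at least one chain id")
      atoms$chain %in% args
    },
    element = {
      if (!length(args)) stop("'element' needs at least one element")
      atoms$element %in% toupper(args)
    },
    resname = {
      if (!length(args)) stop("'resname' needs at least one residue name")
      atoms$resname %in% toupper(args)
    },
    resid = {
      if (!length(args)) stop("'resid' needs residue numbers or ranges")
      ids <- unlist(lapply(args, function(a) {
        if (grepl("^-?\\d+--?\\d+$", a) && grepl("-", substring(a, 2))) {
          p <- regmatches(a, regexec("^(-?\\d+)-(-?\\d+)$", a))[[1]]
          seq(as.integer(p[2]), as.integer(p[3]))
        } else if (grepl("^-?\\d+$", a)) as.integer(a)
        else stop("malformed resid token '", a, "'")
      }))
      atoms$resid %in% ids
    },
    stop("unknown selection keyword '", key, "'")
  )
  if (neg) !mask else mask
}

#' Build a Trajectory from a template and a list of frames
#'
#' Binds per-frame coordinate matrices to the topology of an existing
#' [Trajectory] (or [Topology]). Useful for assembling ensembles
#' programmatically, e.g. from perturbed copies of one structure.
#'
#' @param template a [Trajectory] or [Topology] supplying the atom metadata.
#' @param frames list of `n x 3` coordinate matrices (Angstrom).
#' @param times optional frame times, ns.
#' @return a [Trajectory] with `length(frames)` frames.
#' @export
trajectoryFromFrames <- function(template, frames, times = numeric(0)) {
  atoms <- if (is(template, "Trajectory")) template@topology@atoms
           else template@atoms
  makeTrajectory(atoms, frames, times = times)
}

# Internal constructor used by generators and the assembly module.
makeTrajectory <- function(atoms, coordsList, times = numeric(0),
                           metadata = list()) {
  topo <- new("Topology", atoms = atoms)
  coords <- array(unlist(coordsList), dim = c(nrow(atoms), 3,
                                              length(coordsList)))
  new("Trajectory", topology = topo, coords = coords, times = times,
      metadata = metadata)
}

# Replace the coordinates of one frame, returning a new single-frame
# Trajectory bound to the same topology.
singleFrame <- function(traj, xyz, metadata = traj@metadata) {
  makeTrajectory(traj@topology@atoms, list(xyz), metadata = metadata)
}
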