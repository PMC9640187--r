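# Rigid-body two-domain assembly: anchor translation, Z-rotation scan
# minimizing the axis-aligned enclosing-box volume, and contact-breadth
# orientation selection. Both domains are assumed pre-oriented along the
# membrane normal (Z), leaving a single rotational degree of freedom.

#' Translate a structure so an anchor atom hits a target point
#'
#' @param mobile a single-frame [Trajectory].
#' @param mobileAnchor atom index of the anchor (e.g. the shared cysteine's
#'   Calpha).
#' @param targetPoint length-3 target position, Angstrom.
#' @return the translated [Trajectory].
#' @export
translateToAnchor <- function(mobile, mobileAnchor, targetPoint) {
  stopifnot(is(mobile, "Trajectory"), nFrames(mobile) == 1)
  if (mobileAnchor < 1 || mobileAnchor > nAtoms(mobile))
    stop("invalid anchor atom index")
  xyz <- frameCoords(mobile, 1)
  shift <- as.numeric(targetPoint) - xyz[mobileAnchor, ]
  singleFrame(mobile, sweep(xyz, 2, -shift))
}

#' Axis-aligned enclosing-box volume
#'
#' Volume of the axis-aligned bounding box of a point set
#' (`dx * dy * dz`), in cubic Angstrom. Rotation-variant by definition.
#'
#' @param coords `n x 3` coordinate matrix.
#' @return volume in Angstrom^3.
#' @export
enclosingBoxVolume <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1)
  prod(apply(coords, 2, max) - apply(coords, 2, min))
}

#' Coarse + fine Z-rotation scan for two-domain assembly
#'
#' The mobile domain is rotated about the Z axis through `pivot` (the anchor
#' Calpha). A coarse pass over `[0, 360)` in `coarseStep` increments scores
#' the enclosing-box volume of the merged system (set `mobileOnly = TRUE` to
#' score the mobile domain alone); a fine pass then samples `fineStep`
#' increments across the winning coarse angle +/- `coarseStep`. Each fine
#' candidate carries its mutually-proximal contacts between the two domains
#' within `contactCutoff` and the contact breadth (number of distinct
#' residue pairs).
#'
#' @param mobile,fixed single-frame [Trajectory] objects.
#' @param pivot rotation-axis anchor point (typically the anchor Calpha).
#' @param coarseStep coarse angular step, degrees (must divide 360).
#' @param fineStep fine angular step, degrees.
#' @param contactCutoff contact distance cutoff for breadth scoring,
#'   Angstrom.
#' @param mobileOnly score the bounding box of the mobile domain alone
#'   instead of the merged system.
#' @return list with `coarse` (data.frame: `angle`, `boxVolume`), `fine`
#'   (data.frame: `angle`, `boxVolume`, `nContacts`, `contactBreadth`) and
#'   `contacts` (list of per-candidate contact data.frames).
#' @export
rotationScan <- function(mobile, fixed, pivot, coarseStep = 45,
                         fineStep = 5, contactCutoff = 4.5,
                         mobileOnly = FALSE) {
  stopifnot(is(mobile, "Trajectory"), is(fixed, "Trajectory"),
            nFrames(mobile) == 1, nFrames(fixed) == 1)
  if (360 %% coarseStep != 0)
    stop("coarseStep must divide 360 cleanly")
  if (!nAtoms(mobile) || !nAtoms(fixed)) stop("empty structure")
  mxyz <- frameCoords(mobile, 1)
  fxyz <- frameCoords(fixed, 1)
  score <- function(a) {
    rot <- rotateAboutAxis(mxyz, c(0, 0, 1), a, pivot)
    vol <- enclosingBoxVolume(if (mobileOnly) rot else rbind(rot, fxyz))
    list(rot = rot, vol = vol)
  }
  coarseAngles <- seq(0, 360 - coarseStep, by = coarseStep)
  coarseVol <- vapply(coarseAngles, function(a) score(a)$vol, numeric(1))
  best <- coarseAngles[which.min(coarseVol)]
  fineAngles <- seq(best - coarseStep, best + coarseStep, by = fineStep)
  contacts <- vector("list", length(fineAngles))
  fine <- data.frame(angle = fineAngles %% 360, boxVolume = NA_real_,
                     nContacts = NA_integer_, contactBreadth = NA_integer_)
  for (k in seq_along(fineAngles)) {
    sc <- score(fineAngles[k])
    merged <- mergeStructures(singleFrame(mobile, sc$rot), fixed)
    nm <- nAtoms(mobile)
    selA <- new("AtomSelection", indices = seq_len(nm), label = "mobile")
    selB <- new("AtomSelection",
                indices = seq.int(nm + 1L, nAtoms(merged)), label = "fixed")
    ct <- mutualProximalContacts(merged, selA, selB,
                                 maxDist = contactCutoff)
    contacts[[k]] <- ct
    fine$boxVolume[k] <- sc$vol
    fine$nContacts[k] <- nrow(ct)
    fine$contactBreadth[k] <- length(unique(paste(ct$residA, ct$residB)))
  }
  list(coarse = data.frame(angle = coarseAngles, boxVolume = coarseVol),
       fine = fine, contacts = contacts)
}

#' Select the assembly orientation from scan candidates
#'
#' Picks the candidate with the broadest contacts (most distinct residue
#' pairs within the cutoff); ties break toward the smaller box volume, then
#' the smaller angle. This is an automated stand-in for what is otherwise a
#' visual-inspection step, and is reported as such in the returned
#' `criterion`. If no candidate has any contact, the smallest-volume
#' candidate is returned with a warning.
#'
#' @param scan the result of [rotationScan()] (or its `fine` data.frame).
#' @return one-row data.frame: the chosen candidate with a `criterion`
#'   column.
#' @export
selectOrientation <- function(scan) {
  fine <- if (is.data.frame(scan)) scan else scan$fine
  if (!nrow(fine)) stop("no scan candidates")
  if (all(fine$contactBreadth == 0)) {
    warning("no contacts within cutoff for any candidate; ",
            "falling back to smallest box volume")
    k <- order(fine$boxVolume, fine$angle)[1]
    out <- fine[k, , drop = FALSE]
    out$criterion <- "min-volume fallback"
    rownames(out) <- NULL
    return(out)
  }
  k <- order(-fine$contactBreadth, fine$boxVolume, fine$angle)[1]
  out <- fine[k, , drop = FALSE]
  out$criterion <- "max contact breadth (heuristic stand-in for visual choice)"
  rownames(out) <- NULL
  out
}

#' Merge two single-frame structures into one
#'
#' Atoms of `a` first, then `b`; serials are renumbered and clashing chain
#' ids on the `b` side are left as-is (residue identity is preserved).
#'
#' @param a,b single-frame [Trajectory] objects.
#' @return a single-frame [Trajectory].
#' @export
mergeStructures <- function(a, b) {
  at <- rbind(atomData(a), atomData(b))
  at$serial <- seq_len(nrow(at))
  key <- paste(at$chain, at$resid, at$name)
  if (anyDuplicated(key))
    stop("cannot merge: duplicated (chain, resid, name); ",
         "assign distinct chains first")
  makeTrajectory(at, list(rbind(frameCoords(a, 1), frameCoords(b, 1))),
                 metadata = list(kind = "merged"))
}

#' Full two-domain assembly heuristic
#'
#' Translate the mobile domain so its anchor Calpha coincides with the fixed
#' domain's anchor Calpha, scan rotations about Z through the anchor, and
#' select the orientation with the broadest inter-domain contacts. The fixed
#' domain is never moved and the mobile domain's internal geometry is
#' preserved exactly (rigid motions only).
#'
#' @param mobile,fixed single-frame [Trajectory] objects.
#' @param mobileAnchor,fixedAnchor anchor atom indices in each domain.
#' @param ... passed to [rotationScan()].
#' @return list with `merged` (the assembled [Trajectory]), `choice` (the
#'   selected candidate row) and `scan` (the full scan report).
#' @export
assembleDomains <- function(mobile, fixed, mobileAnchor, fixedAnchor, ...) {
  target <- frameCoords(fixed, 1)[fixedAnchor, ]
  mob <- translateToAnchor(mobile, mobileAnchor, target)
  scan <- rotationScan(mob, fixed, pivot = target, ...)
  choice <- selectOrientation(scan)
  rot <- rotateAboutAxis(frameCoords(mob, 1), c(0, 0, 1), choice$angle,
                         target)
  list(merged = mergeStructures(singleFrame(mob, rot), fixed),
       choice = choice, scan = scan)
}
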