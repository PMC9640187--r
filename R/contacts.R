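# Steric clashes, mutually-proximal inter-domain contacts, geometric
# hydrogen bonds, residue-pair bond tracks with occupancy filtering,
# saturation diagnostics and distance time series.

# Threshold class of an atom pair: S beats N/O beats C (thresholds are
# ordered by element size).
clashThreshold <- function(elemA, elemB, params) {
  t <- ifelse(elemA == "S" | elemB == "S", params@thresholdS,
       ifelse(elemA %in% c("N", "O") | elemB %in% c("N", "O"),
              params@thresholdNO, params@thresholdC))
  t
}

#' Find steric clashes between two atom groups
#'
#' A clash is a heavy-atom pair closer than an element-dependent threshold:
#' 2.10 Angstrom when either atom is S, 1.68 when either is N or O, and 1.65
#' for C (and any other heavy element). Hydrogens are silently excluded from
#' both selections. The summary counts distinct clashing atoms and residues
#' on the A side only, matching how clash burdens of a region are reported.
#'
#' @param traj a [Trajectory].
#' @param selA,selB [AtomSelection]s (or expression strings) for the two
#'   groups; group A is the reported side.
#' @param params a [ClashParams].
#' @param frame frame index to analyse.
#' @return list with `pairs` (data.frame: `atomA`, `atomB`, `distance`,
#'   `elementA`, `elementB`, `residA`, `residB`) and `summary`
#'   (`nAtomsA`, `nResiduesA`).
#' @export
findClashes <- function(traj, selA, selB, params = new("ClashParams"),
                        frame = 1L) {
  if (is.character(selA)) selA <- selectAtoms(traj, selA)
  if (is.character(selB)) selB <- selectAtoms(traj, selB)
  at <- atomData(traj)
  ia <- setdiff(selIndices(selA), which(at$element == "H"))
  ib <- setdiff(selIndices(selB), which(at$element == "H"))
  if (!length(ia) || !length(ib)) stop("empty heavy-atom selection")
  xyz <- frameCoords(traj, frame)
  d <- crossDist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  thr <- outer(at$element[ia], at$element[ib],
               function(x, y) clashThreshold(x, y, params))
  hit <- which(d < thr & outer(ia, ib, "!="), arr.ind = TRUE)
  pairs <- data.frame(
    atomA = ia[hit[, 1]], atomB = ib[hit[, 2]],
    distance = d[hit],
    elementA = at$element[ia[hit[, 1]]], elementB = at$element[ib[hit[, 2]]],
    residA = at$resid[ia[hit[, 1]]], residB = at$resid[ib[hit[, 2]]],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$atomA, pairs$atomB), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       summary = c(nAtomsA = length(unique(pairs$atomA)),
                   nResiduesA = length(unique(paste(
                     at$chain[pairs$atomA], pairs$residA)))))
}

#' Mutually-proximal contacts between two atom groups
#'
#' Atom pair (iA, jB) is a contact iff iA is the nearest atom of group A to
#' jB and jB is the nearest atom of group B to iA. Nearest-neighbor ties
#' break toward the lowest atom index, so the result is deterministic and
#' symmetric in A/B up to pair orientation.
#'
#' @inheritParams findClashes
#' @param maxDist optional distance cutoff applied after the mutual-proximity
#'   test, Angstrom.
#' @return data.frame with `atomA`, `atomB`, `distance`, `residA`, `residB`.
#' @export
mutualProximalContacts <- function(traj, selA, selB, maxDist = NULL,
                                   frame = 1L) {
  if (is.character(selA)) selA <- selectAtoms(traj, selA)
  if (is.character(selB)) selB <- selectAtoms(traj, selB)
  ia <- selIndices(selA); ib <- selIndices(selB)
  if (!length(ia) || !length(ib)) stop("empty selection")
  xyz <- frameCoords(traj, frame)
  d <- crossDist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  nearB <- apply(d, 1, which.min)   # for each a: nearest b (ties -> lowest)
  nearA <- apply(d, 2, which.min)   # for each b: nearest a
  keep <- which(nearA[nearB] == seq_along(ia))
  out <- data.frame(
    atomA = ia[keep], atomB = ib[nearB[keep]],
    distance = d[cbind(keep, nearB[keep])],
    residA = atomData(traj)$resid[ia[keep]],
    residB = atomData(traj)$resid[ib[nearB[keep]]],
    stringsAsFactors = FALSE)
  if (!is.null(maxDist)) out <- out[out$distance <= maxDist, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Geometric hydrogen bonds in one frame
#'
#' X...H-Y with X and Y polar heavy atoms (N, O, S, P), the X...H-Y angle
#' above `angleMin` and the X-H distance below the acceptor-element threshold
#' (N/O 2.52, P 3.24, S 3.15 Angstrom by default). Hydrogens are covalently
#' assigned to the nearest heavy atom within 1.2 Angstrom. Charge is ignored,
#' so salt bridges are included by construction. X and Y in the same residue
#' are excluded, matching residue-pair reporting.
#'
#' @param traj a [Trajectory] whose topology contains explicit hydrogens.
#' @param params an [HBondParams].
#' @param frame frame index.
#' @return data.frame with `X`, `H`, `Y` atom indices, `distXH` (Angstrom)
#'   and `angle` (degrees).
#' @export
findHBonds <- function(traj, params = new("HBondParams"), frame = 1L) {
  at <- atomData(traj)
  hIdx <- which(at$element == "H")
  if (!length(hIdx))
    stop("no hydrogens in topology; hydrogen-bond analysis needs explicit ",
         "hydrogens (see makePairFixture() or use protonated input)")
  polar <- which(at$element %in% POLAR_ELEMENTS)
  xyz <- frameCoords(traj, frame)
  heavy <- which(at$element != "H")
  dHheavy <- crossDist(xyz[hIdx, , drop = FALSE],
                       xyz[heavy, , drop = FALSE])
  out <- list()
  for (k in seq_along(hIdx)) {
    h <- hIdx[k]
    cov <- which(dHheavy[k, ] < 1.2)
    if (!length(cov)) next
    y <- heavy[cov[which.min(dHheavy[k, cov])]]
    if (!(at$element[y] %in% POLAR_ELEMENTS)) next
    cand <- polar[polar != y &
                    !(at$chain[polar] == at$chain[y] &
                        at$resid[polar] == at$resid[y])]
    if (!length(cand)) next
    dXH <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[h, ])^2))
    ok <- dXH < params@thresholds[at$element[cand]]
    for (m in which(ok)) {
      x <- cand[m]
      ang <- angleAt(xyz[x, ], xyz[h, ], xyz[y, ])
      if (ang > params@angleMin)
        out[[length(out) + 1]] <- data.frame(
          X = x, H = h, Y = y, distXH = dXH[m], angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(X = integer(0), H = integer(0), Y = integer(0),
                      distXH = numeric(0), angle = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residue-pair hydrogen-bond tracks over a trajectory
#'
#' Per-frame hydrogen bonds are collapsed onto unordered residue pairs, then
#' filtered: same-chain pairs closer than `minSeqSep` residues in sequence
#' are dropped (excluding the many intra-helix bonds) and pairs bonded in
#' fewer than `minOccupancy` of the frames are dropped. Tracks are labelled
#' `"intra"` when both residues fall inside `scope` and `"inter"` when only
#' one does; pairs with no residue in scope are discarded.
#'
#' By default atom-level bonds are merged into residue pairs before the
#' occupancy filter; `occupancyBeforeMerge = TRUE` instead filters atom-level
#' tracks at `minOccupancy` first and merges the survivors.
#'
#' @param traj a [Trajectory] with at least 2 frames.
#' @param scope [AtomSelection] (or expression) delimiting the region of
#'   interest, e.g. the linker region.
#' @param params an [HBondParams].
#' @param occupancyBeforeMerge apply the occupancy filter to atom-level
#'   tracks before merging into residue pairs.
#' @return list with `tracks` (data.frame: `chainI`, `residI`, `chainJ`,
#'   `residJ`, `occupancy`, `firstFormed`, `label`) and `presence`
#'   (logical matrix, tracks x frames).
#' @export
hbondResidueTracks <- function(traj, scope, params = new("HBondParams"),
                               occupancyBeforeMerge = FALSE) {
  if (nFrames(traj) < 2) stop("need at least 2 frames for bond tracks")
  if (is.character(scope)) scope <- selectAtoms(traj, scope)
  at <- atomData(traj)
  nf <- nFrames(traj)
  keyLevel <- if (occupancyBeforeMerge) "atom" else "residue"
  presenceByKey <- new.env(parent = emptyenv())
  keyResPair <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hb <- findHBonds(traj, params, frame = f)
    if (!nrow(hb)) next
    rp <- residuePairKeys(hb, at)
    keys <- if (keyLevel == "atom")
      paste(pmin(hb$X, hb$Y), pmax(hb$X, hb$Y)) else rp$key
    for (m in seq_along(keys)) {
      k <- keys[m]
      if (is.null(presenceByKey[[k]]))
        presenceByKey[[k]] <- logical(nf)
      presenceByKey[[k]][f] <- TRUE
      keyResPair[[k]] <- rp[m, c("chainI", "residI", "chainJ", "residJ")]
    }
  }
  keys <- ls(presenceByKey)
  if (!length(keys)) return(emptyTracks(nf))
  pres <- do.call(rbind, lapply(keys, function(k) presenceByKey[[k]]))
  info <- do.call(rbind, lapply(keys, function(k) keyResPair[[k]]))
  if (occupancyBeforeMerge) {
    keep <- rowMeans(pres) >= params@minOccupancy
    pres <- pres[keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
    if (!nrow(info)) return(emptyTracks(nf))
    # merge surviving atom tracks onto residue pairs
    rkey <- paste(info$chainI, info$residI, info$chainJ, info$residJ)
    groups <- split(seq_len(nrow(info)), rkey)
    pres <- do.call(rbind, lapply(groups, function(g)
      apply(pres[g, , drop = FALSE], 2, any)))
    info <- info[vapply(groups, `[`, integer(1), 1), , drop = FALSE]
  }
  # sequence-separation filter (same-chain pairs only)
  sep_ok <- info$chainI != info$chainJ |
    abs(info$residI - info$residJ) >= params@minSeqSep
  pres <- pres[sep_ok, , drop = FALSE]
  info <- info[sep_ok, , drop = FALSE]
  if (!nrow(info)) return(emptyTracks(nf))
  occ <- rowMeans(pres)
  keep <- occ >= params@minOccupancy
  pres <- pres[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  occ <- occ[keep]
  if (!nrow(info)) return(emptyTracks(nf))
  scopeRes <- unique(paste(at$chain[selIndices(scope)],
                           at$resid[selIndices(scope)]))
  inI <- paste(info$chainI, info$residI) %in% scopeRes
  inJ <- paste(info$chainJ, info$residJ) %in% scopeRes
  label <- ifelse(inI & inJ, "intra", ifelse(inI | inJ, "inter", "drop"))
  keep <- label != "drop"
  tracks <- data.frame(info[keep, , drop = FALSE],
                       occupancy = occ[keep],
                       firstFormed = apply(pres[keep, , drop = FALSE], 1,
                                           function(p) which(p)[1]),
                       label = label[keep], stringsAsFactors = FALSE)
  ord <- order(tracks$chainI, tracks$residI, tracks$chainJ, tracks$residJ)
  tracks <- tracks[ord, , drop = FALSE]
  rownames(tracks) <- NULL
  list(tracks = tracks, presence = pres[keep, , drop = FALSE][ord, ,
                                                              drop = FALSE])
}

residuePairKeys <- function(hb, at) {
  ci <- at$chain[hb$X]; ri <- at$resid[hb$X]
  cj <- at$chain[hb$Y]; rj <- at$resid[hb$Y]
  swap <- ci > cj | (ci == cj & ri > rj)
  out <- data.frame(chainI = ifelse(swap, cj, ci),
                    residI = ifelse(swap, rj, ri),
                    chainJ = ifelse(swap, ci, cj),
                    residJ = ifelse(swap, ri, rj),
                    stringsAsFactors = FALSE)
  out$key <- paste(out$chainI, out$residI, out$chainJ, out$residJ)
  out
}

emptyTracks <- function(nf) {
  list(tracks = data.frame(chainI = character(0), residI = integer(0),
                           chainJ = character(0), residJ = integer(0),
                           occupancy = numeric(0), firstFormed = integer(0),
                           label = character(0), stringsAsFactors = FALSE),
       presence = matrix(logical(0), 0, nf))
}

#' Hydrogen-bond track saturation diagnostic
#'
#' Histogram of track first-formation frames by trajectory quarter. The
#' sampling of an ensemble is deemed saturated when no track first forms in
#' the final quarter (the system only breaks and reforms existing bonds).
#'
#' @param tracks the `tracks` data.frame from [hbondResidueTracks()] (or the
#'   full list).
#' @param nFrames total number of frames in the trajectory.
#' @return list with `counts` (integer(4), new tracks per quarter) and
#'   `saturated` (logical).
#' @export
trackSaturation <- function(tracks, nFrames) {
  if (is.list(tracks) && !is.data.frame(tracks)) tracks <- tracks$tracks
  counts <- integer(4)
  if (nrow(tracks)) {
    q <- pmin(4L, ceiling(4 * tracks$firstFormed / nFrames))
    counts <- tabulate(q, nbins = 4)
  }
  list(counts = counts, saturated = counts[4] == 0L)
}

#' Per-pair distance time series
#'
#' Euclidean distance per frame for each requested atom pair, in frame order.
#' Used e.g. for tracking putative disulfide partners (cysteine SG-SG
#' distances) along a trajectory.
#'
#' @param traj a [Trajectory].
#' @param atomPairs 2-column matrix (or list of length-2 vectors) of atom
#'   indices.
#' @param labels optional pair labels.
#' @return data.frame with `frame`, `pair`, `distance` (Angstrom).
#' @export
distanceTimeseries <- function(traj, atomPairs, labels = NULL) {
  if (is.list(atomPairs)) atomPairs <- do.call(rbind, atomPairs)
  atomPairs <- matrix(as.integer(atomPairs), ncol = 2)
  if (any(atomPairs < 1) || any(atomPairs > nAtoms(traj)))
    stop("invalid atom index in atomPairs")
  if (is.null(labels))
    labels <- paste0(atomPairs[, 1], "-", atomPairs[, 2])
  nf <- nFrames(traj)
  out <- lapply(seq_len(nrow(atomPairs)), function(p) {
    d <- vapply(seq_len(nf), function(f) {
      xyz <- frameCoords(traj, f)
      vnorm(xyz[atomPairs[p, 1], ] - xyz[atomPairs[p, 2], ])
    }, numeric(1))
    data.frame(frame = seq_len(nf), pair = labels[p], distance = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
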