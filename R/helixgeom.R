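# Per-helix and helix-pair geometry from Calpha traces: local axis points,
# axis direction, end-to-end length, bend radius (circle fit), inter-helix
# distances/angles, and the range-based significance flag used when
# comparing representative structures with a reference.

STRAIGHT_HELIX_CAP <- 1000

#' Split a helix definition at prolines
#'
#' Prolines break a helix into sub-helices: each proline starts the next
#' segment. Segments shorter than `minLen` residues are discarded (with a
#' message), mirroring the convention that very short inter-segment pieces
#' are ignored.
#'
#' @param residues ordered, contiguous residue numbers of the helix.
#' @param sequence residue names (3-letter codes) aligned with `residues`.
#' @param minLen minimum segment length kept (default 4, the minimum for
#'   axis fitting).
#' @return list of integer vectors, one per kept sub-helix span.
#' @export
splitOnProline <- function(residues, sequence, minLen = 4) {
  stopifnot(length(residues) == length(sequence),
            all(diff(residues) == 1))
  pro <- which(toupper(sequence) == "PRO")
  starts <- sort(unique(c(1L, pro[pro > 1])))
  ends <- c(starts[-1] - 1L, length(residues))
  spans <- Map(function(s, e) residues[s:e], starts, ends)
  keep <- lengths(spans) >= minLen
  if (any(!keep))
    message("discarding ", sum(!keep), " sub-helix segment(s) shorter than ",
            minLen, " residues")
  spans[keep]
}

#' Fit a helix axis from the Calpha trace
#'
#' The local axis point of residue i (2 <= i <= n-1) is `CA_i + r * u_i`,
#' where `u_i` is the unit bisector of the vectors to the two neighboring
#' Calphas (equivalently the unit second difference, which points at the
#' local axis) and the local radius r is estimated per residue quadruple
#' from the turn geometry: with turn angle theta between consecutive
#' second-difference vectors, `r = |second difference| / (2 (1 - cos
#' theta))`. The axis direction is the first principal component of the
#' local axis points, oriented N to C; the axis point is their centroid.
#'
#' @param ca ordered `n x 3` matrix of Calpha coordinates, `n >= 5`.
#' @param residueSpan optional integer(2) first/last residue number for
#'   bookkeeping.
#' @return a [HelixDescriptor].
#' @export
fitHelixAxis <- function(ca, residueSpan = c(1L, nrow(ca))) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 5) stop("helix axis fitting needs at least 5 Calpha atoms")
  sd2 <- ca[seq_len(n - 2), , drop = FALSE] +
    ca[3:n, , drop = FALSE] - 2 * ca[2:(n - 1), , drop = FALSE]
  m <- n - 2                                # interior residues 2..n-1
  # turn angle between consecutive second-difference (radial) vectors
  costh <- numeric(m)
  for (i in seq_len(m)) {
    j <- if (i < m) i + 1L else i - 1L
    costh[i] <- sum(unitv(sd2[i, ]) * unitv(sd2[j, ]))
  }
  r <- sqrt(rowSums(sd2^2)) / (2 * (1 - costh))
  axisPts <- ca[2:(n - 1), , drop = FALSE] +
    r * t(apply(sd2, 1, unitv))
  ctr <- colMeans(axisPts)
  pc <- svd(sweep(axisPts, 2, ctr))$v[, 1]
  if (sum(pc * (axisPts[m, ] - axisPts[1, ])) < 0) pc <- -pc
  new("HelixDescriptor",
      residueSpan = as.integer(residueSpan),
      axisPoint = ctr, axisDir = unitv(pc),
      length = helixLength(ca),
      bendRadius = circleFitRadius(axisPts),
      localAxisPoints = axisPts)
}

#' Helix end-to-end length
#'
#' Euclidean distance from the first to the last Calpha.
#'
#' @param ca ordered `n x 3` matrix of Calpha coordinates, `n >= 2`.
#' @return length in Angstrom.
#' @export
helixLength <- function(ca) {
  ca <- as.matrix(ca)
  stopifnot(nrow(ca) >= 2)
  vnorm(ca[nrow(ca), ] - ca[1, ])
}

# Least-squares circle fit: project points onto their principal plane, then
# algebraic (Kasa) fit in-plane. Near-collinear point sets and radii above
# the straight-helix cap report the cap.
circleFitRadius <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) return(STRAIGHT_HELIX_CAP)
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  if (s$d[2] < 1e-6 * max(s$d[1], 1)) return(STRAIGHT_HELIX_CAP)
  uv <- sweep(pts, 2, ctr) %*% s$v[, 1:2]   # in-plane coordinates
  x <- uv[, 1]; y <- uv[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(STRAIGHT_HELIX_CAP)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  if (!is.finite(r) || r > STRAIGHT_HELIX_CAP) STRAIGHT_HELIX_CAP else r
}

#' Helix bend radius
#'
#' Radius of the circle fitted (least squares, in the principal plane) to the
#' smoothed local axis points of a helix: the smaller the radius, the more
#' bent the helix. Straight helices (collinear axis points, or fitted radii
#' above 1000 Angstrom) report the cap value 1000. Set `useRawCA = TRUE` to
#' fit the circle to the raw Calpha atoms instead; the helical winding
#' (~2.3 Angstrom radius) then contaminates the fit, which is why the
#' smoothed axis points are the default.
#'
#' @param desc a [HelixDescriptor] (or an `n x 3` matrix of Calpha
#'   coordinates, from which a descriptor is fitted first).
#' @param useRawCA fit the raw Calpha trace rather than the axis points;
#'   only available when `desc` is a coordinate matrix.
#' @return bend radius in Angstrom (1000 = straight-helix cap).
#' @export
bendRadius <- function(desc, useRawCA = FALSE) {
  if (is(desc, "HelixDescriptor")) {
    if (useRawCA)
      stop("useRawCA requires Calpha coordinates, not a descriptor")
    return(desc@bendRadius)
  }
  ca <- as.matrix(desc)
  if (useRawCA) return(circleFitRadius(ca))
  fitHelixAxis(ca)@bendRadius
}

#' Pairwise helix geometry
#'
#' Center distance (between the axis centroids), closest approach (minimum
#' distance between the two finite axis segments, each spanning the
#' projected extent of its Calphas) and the inter-axis angle in [0, 180]
#' degrees.
#'
#' @param d1,d2 [HelixDescriptor]s.
#' @return list with `centerDistance`, `closestApproach` (Angstrom) and
#'   `angle` (degrees).
#' @export
helixPairMetrics <- function(d1, d2) {
  seg1 <- axisSegment(d1); seg2 <- axisSegment(d2)
  ang <- acos(max(-1, min(1, sum(d1@axisDir * d2@axisDir)))) * 180 / pi
  list(centerDistance = vnorm(d1@axisPoint - d2@axisPoint),
       closestApproach = segmentSegmentDistance(seg1$a, seg1$b,
                                                seg2$a, seg2$b),
       angle = ang)
}

# Finite axis segment spanning the projections of the local axis points.
axisSegment <- function(desc) {
  t <- as.vector(sweep(desc@localAxisPoints, 2, desc@axisPoint) %*%
                   desc@axisDir)
  list(a = desc@axisPoint + min(t) * desc@axisDir,
       b = desc@axisPoint + max(t) * desc@axisDir)
}

# Minimum distance between segments [p1,p2] and [q1,q2] (clamped
# closest-point parametrization).
segmentSegmentDistance <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c - b * b
  if (D < 1e-12) {                      # parallel segments
    s <- 0
    t <- if (c > 1e-12) e / c else 0
  } else {
    s <- (b * e - c * d) / D
    t <- (a * e - b * d) / D
  }
  s <- max(0, min(1, s))
  # recompute t for the clamped s, then clamp and recompute s once more
  t <- if (c > 1e-12) max(0, min(1, (b * s + e) / c)) else 0
  s <- if (a > 1e-12) max(0, min(1, (b * t - d) / a)) else 0
  vnorm((p1 + s * u) - (q1 + t * v))
}

#' Range-based significance flag
#'
#' A change is deemed significant (`"S"`) when the reference value lies
#' outside the range of the values observed in the representative
#' structures; a reference on the range boundary counts as inside (`"n"`).
#'
#' @param reference reference value.
#' @param representativeValues values from the representative structures.
#' @return `"S"` or `"n"`.
#' @export
significanceFlag <- function(reference, representativeValues) {
  if (!length(representativeValues)) stop("no representative values")
  if (reference < min(representativeValues) ||
      reference > max(representativeValues)) "S" else "n"
}

#' Helix-bundle change report
#'
#' For each (proline-split) helix, the change in end-to-end length and bend
#' radius between representative structures and a reference (mean over
#' representatives minus reference), flagged with [significanceFlag()];
#' plus matrices of pairwise changes: closest approach (upper triangle) /
#' center distance (lower triangle), and inter-axis angles. Sub-helices from
#' proline splitting carry `.1`/`.2` suffixes.
#'
#' @param reference single-frame [Trajectory] (or frame index into `traj`).
#' @param traj a [Trajectory] containing the representative frames.
#' @param representativeFrames frame indices of the representatives.
#' @param helixDefs data.frame with columns `name`, `chain`, `first`, `last`
#'   (residue numbers).
#' @param minLen minimum sub-helix length kept after proline splitting.
#' @return list with `helices` (per-helix data.frame: name, length/radius
#'   changes and flags), `pairDistance` (matrix; upper = closest-approach
#'   change, lower = center-distance change), `pairDistanceFlags`,
#'   `angle` and `angleFlags` matrices.
#' @export
helixTableReport <- function(reference, traj, representativeFrames,
                             helixDefs, minLen = 4) {
  stopifnot(is(reference, "Trajectory"), nFrames(reference) == 1)
  spans <- resolveHelixSpans(reference, helixDefs, minLen)
  descFor <- function(tr, f) lapply(spans, function(sp) {
    sel <- selectAtoms(tr, sprintf("chain %s and resid %d-%d and name CA",
                                   sp$chain, sp$first, sp$last))
    fitHelixAxis(frameCoords(tr, f, sel), c(sp$first, sp$last))
  })
  refD <- descFor(reference, 1L)
  repD <- lapply(representativeFrames, function(f) descFor(traj, f))
  nh <- length(spans)
  nm <- vapply(spans, `[[`, character(1), "name")
  lenRef <- vapply(refD, function(d) d@length, numeric(1))
  radRef <- vapply(refD, function(d) d@bendRadius, numeric(1))
  lenRep <- sapply(repD, function(ds) vapply(ds, function(d) d@length,
                                             numeric(1)))
  radRep <- sapply(repD, function(ds) vapply(ds, function(d) d@bendRadius,
                                             numeric(1)))
  lenRep <- matrix(lenRep, nrow = nh)
  radRep <- matrix(radRep, nrow = nh)
  helices <- data.frame(
    name = nm,
    lengthChange = rowMeans(lenRep) - lenRef,
    lengthFlag = vapply(seq_len(nh), function(i)
      significanceFlag(lenRef[i], lenRep[i, ]), character(1)),
    radiusChange = rowMeans(radRep) - radRef,
    radiusFlag = vapply(seq_len(nh), function(i)
      significanceFlag(radRef[i], radRep[i, ]), character(1)),
    stringsAsFactors = FALSE)
  pairStat <- function(extract) {
    ref <- matrix(0, nh, nh)
    reps <- array(0, c(nh, nh, length(repD)))
    for (i in seq_len(nh)) for (j in seq_len(nh)) {
      if (i == j) next
      ref[i, j] <- extract(refD[[i]], refD[[j]])
      for (r in seq_along(repD))
        reps[i, j, r] <- extract(repD[[r]][[i]], repD[[r]][[j]])
    }
    list(change = apply(reps, c(1, 2), mean) - ref,
         flags = matrix(vapply(seq_len(nh * nh), function(k) {
           i <- (k - 1) %% nh + 1; j <- (k - 1) %/% nh + 1
           if (i == j) "n" else significanceFlag(ref[i, j], reps[i, j, ])
         }, character(1)), nh, nh))
  }
  closest <- pairStat(function(a, b) helixPairMetrics(a, b)$closestApproach)
  centers <- pairStat(function(a, b) helixPairMetrics(a, b)$centerDistance)
  angles <- pairStat(function(a, b) helixPairMetrics(a, b)$angle)
  pd <- centers$change; pd[upper.tri(pd)] <- closest$change[upper.tri(pd)]
  pf <- centers$flags; pf[upper.tri(pf)] <- closest$flags[upper.tri(pf)]
  dimnames(pd) <- dimnames(pf) <- list(nm, nm)
  ang <- angles$change; angF <- angles$flags
  dimnames(ang) <- dimnames(angF) <- list(nm, nm)
  list(helices = helices, pairDistance = pd, pairDistanceFlags = pf,
       angle = ang, angleFlags = angF)
}

# Expand helix definitions into proline-split spans with .1/.2 suffixes.
resolveHelixSpans <- function(traj, helixDefs, minLen) {
  at <- atomData(traj)
  out <- list()
  for (row in seq_len(nrow(helixDefs))) {
    h <- helixDefs[row, ]
    resids <- h$first:h$last
    ca <- at[at$chain == h$chain & at$name == "CA" &
               at$resid %in% resids, , drop = FALSE]
    ca <- ca[order(ca$resid), , drop = FALSE]
    spans <- splitOnProline(ca$resid, ca$resname, minLen)
    for (s in seq_along(spans)) {
      nm <- if (length(spans) > 1) paste0(h$name, ".", s) else
        as.character(h$name)
      out[[length(out) + 1]] <- list(name = nm, chain = h$chain,
                                     first = min(spans[[s]]),
                                     last = max(spans[[s]]))
    }
  }
  out
}
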