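# Pairwise RMSD maps over evenly spaced frames, k-medoid clustering and the
# minimax representative rule.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body superposition of `P` onto `Q` via singular value
#' decomposition, constrained to a proper rotation (det = +1).
#'
#' @param P,Q `n x 3` coordinate matrices with matched atom order, `n >= 3`.
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `P %*% t(rotation) + translation` best fits `Q`, and `rmsd` (Angstrom).
#'   Degenerate (collinear) point sets are flagged with a warning.
#' @export
kabschSuperpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3) stop("superposition needs at least 3 atoms")
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))            # covariance P^T Q
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    warning("degenerate (collinear) point set in superposition")
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)              # maps P-frame into Q-frame
  t <- cq - as.vector(R %*% cp)
  diff <- Qc - Pc %*% t(R)
  list(rotation = R, translation = t,
       rmsd = sqrt(sum(diff^2) / nrow(P)))
}

# RMSD over `measure` coordinates after superposing on `fit` coordinates.
fittedRMSD <- function(fitP, fitQ, measP, measQ) {
  k <- kabschSuperpose(fitP, fitQ)
  Pm <- sweep(measP %*% t(k$rotation), 2, -k$translation)
  sqrt(sum((Pm - measQ)^2) / nrow(measQ))
}

#' Evenly spaced frame indices
#'
#' `n` indices spanning `1..nFrames` at uniform stride:
#' `round(1 + i * (nFrames - 1) / (n - 1))` for `i = 0..n-1`.
#'
#' @param nFrames total number of frames.
#' @param n number of samples (`n <= nFrames`).
#' @return integer vector of length `n`.
#' @export
evenFrameIndices <- function(nFrames, n) {
  if (n > nFrames) stop("cannot sample more frames than available")
  if (n == 1) return(1L)
  unique(as.integer(round(1 + (seq_len(n) - 1) * (nFrames - 1) / (n - 1))))
}

#' Pairwise RMSD map
#'
#' Samples `nSamples` evenly spaced frames and computes, for every frame
#' pair, the RMSD over `measureSel` after superposing on `fitSel` (the two
#' coincide by default, as when mapping a linker region on itself; a distinct
#' `fitSel` reproduces maps superposed on a rigid domain only). Triangle
#' inequality violations are possible — RMSD after independent superpositions
#' is not a metric — and are reported via a message.
#'
#' @param traj a [Trajectory].
#' @param measureSel [AtomSelection] (or expression string) the RMSD is
#'   computed over.
#' @param fitSel selection used for superposition; defaults to `measureSel`.
#' @param nSamples number of evenly spaced frames (default all frames, capped
#'   at 2000).
#' @return an [RMSDMap].
#' @export
rmsdMap <- function(traj, measureSel, fitSel = NULL,
                    nSamples = min(nFrames(traj), 2000L)) {
  if (is.character(measureSel)) measureSel <- selectAtoms(traj, measureSel)
  if (is.character(fitSel)) fitSel <- selectAtoms(traj, fitSel)
  if (is.null(fitSel)) fitSel <- measureSel
  if (!length(selIndices(measureSel)) || !length(selIndices(fitSel)))
    stop("empty selection for RMSD map")
  idx <- evenFrameIndices(nFrames(traj), nSamples)
  n <- length(idx)
  fitC <- lapply(idx, function(i) frameCoords(traj, i, fitSel))
  measC <- lapply(idx, function(i) frameCoords(traj, i, measureSel))
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- fittedRMSD(fitC[[i]], fitC[[j]],
                                       measC[[i]], measC[[j]])
    }
  }
  viol <- 0L
  if (n >= 3) {
    for (i in seq_len(n)) {
      slack <- outer(m[i, ], m[i, ], "+") - m
      if (any(slack < -1e-9)) viol <- viol + 1L
    }
    if (viol) message("RMSD map: triangle inequality violated around ",
                      viol, " frame(s) (expected for fitted RMSD)")
  }
  new("RMSDMap", frameIndices = idx, matrix = m,
      fitSel = fitSel@label, measureSel = measureSel@label)
}

#' k-medoid clustering of an RMSD map
#'
#' PAM-style alternation: frames are assigned to the nearest medoid, then
#' each medoid is replaced by the cluster member minimizing the summed
#' distance to its cluster, until the assignment is stable. Initialization is
#' deterministic: the first medoid is the global minimax frame (lowest
#' maximum distance to all frames) and subsequent medoids are chosen by
#' farthest-point seeding; ties break toward the lowest frame index. The
#' `seed` argument is accepted for interface stability but the procedure is
#' fully deterministic.
#'
#' @param map an [RMSDMap] (or a plain symmetric distance matrix).
#' @param k number of clusters.
#' @param seed unused; kept so that callers can thread a seed through.
#' @return a [ClusterResult]; representatives are filled in with the minimax
#'   rule of [clusterRepresentative()].
#' @export
kmedoidCluster <- function(map, k, seed = 1L) {
  m <- if (is(map, "RMSDMap")) map@matrix else as.matrix(map)
  frameIdx <- if (is(map, "RMSDMap")) map@frameIndices
              else seq_len(nrow(m))
  n <- nrow(m)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  medoids <- integer(k)
  medoids[1] <- which.min(apply(m, 1, max))
  if (k > 1) {
    for (c in 2:k) {
      dmin <- apply(m[, medoids[seq_len(c - 1)], drop = FALSE], 1, min)
      medoids[c] <- which.max(dmin)
    }
  }
  labels <- integer(n)
  for (it in seq_len(100)) {
    labels <- apply(m[, medoids, drop = FALSE], 1, which.min)
    newmed <- vapply(seq_len(k), function(c) {
      members <- which(labels == c)
      if (!length(members)) return(medoids[c])
      members[which.min(colSums(m[members, members, drop = FALSE]))]
    }, integer(1))
    if (identical(newmed, medoids)) break
    medoids <- newmed
  }
  labels <- as.integer(apply(m[, medoids, drop = FALSE], 1, which.min))
  reps <- vapply(seq_len(k), function(c)
    clusterRepresentative(m, which(labels == c)), integer(1))
  new("ClusterResult", labels = labels, medoids = as.integer(medoids),
      representatives = reps, frameIndices = as.integer(frameIdx))
}

#' Minimax cluster representative
#'
#' The representative of a cluster is the member with the lowest maximum
#' RMSD to the rest of the cluster members; ties break toward the lowest
#' frame index.
#'
#' @param map an [RMSDMap] or symmetric distance matrix.
#' @param members integer vector of member row indices.
#' @return the representative's row index.
#' @export
clusterRepresentative <- function(map, members) {
  m <- if (is(map, "RMSDMap")) map@matrix else as.matrix(map)
  members <- sort(as.integer(members))   # tie-break on lowest frame index
  if (!length(members)) stop("empty member set")
  if (length(members) == 1) return(members)
  sub <- m[members, members, drop = FALSE]
  diag(sub) <- 0
  worst <- apply(sub, 1, max)
  members[which.min(worst)]
}
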