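# Shape and orientation descriptors: radius of gyration and the angle
# between a domain's first principal axis and the membrane normal (Z).

#' Radius of gyration
#'
#' Unweighted (geometric) radius of gyration,
#' `sqrt(mean(|r_i - centroid|^2))`. Set `masses` to mass-weight.
#'
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param masses optional per-atom weights.
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1)
  if (is.null(masses)) {
    ctr <- colMeans(coords)
    return(sqrt(mean(rowSums(sweep(coords, 2, ctr)^2))))
  }
  w <- masses / sum(masses)
  ctr <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, ctr)^2)))
}

#' Per-frame radius of gyration and its range
#'
#' Rg of the selected atoms in every frame, plus the range (max - min), the
#' headline compactness-fluctuation statistic for a disordered linker.
#'
#' @param traj a [Trajectory].
#' @param sel [AtomSelection] (or expression string).
#' @param masses optional per-atom weights (aligned with the selection).
#' @return list with `series` (data.frame: `frame`, `rg`) and `range`
#'   (Angstrom).
#' @export
rgSeriesAndRange <- function(traj, sel = "all", masses = NULL) {
  if (is.character(sel)) sel <- selectAtoms(traj, sel)
  if (!length(selIndices(sel))) stop("empty selection")
  rg <- vapply(seq_len(nFrames(traj)), function(f)
    radiusOfGyration(frameCoords(traj, f, sel), masses), numeric(1))
  list(series = data.frame(frame = seq_len(nFrames(traj)), rg = rg),
       range = max(rg) - min(rg))
}

#' Angle between the first principal axis and Z
#'
#' The first principal axis of the selected atoms (largest-eigenvalue
#' eigenvector of the coordinate covariance, i.e. the gyration tensor) is
#' tracked per frame; the reported angle is to the lab Z axis (the membrane
#' normal in membrane-protein setups). The eigenvector sign is fixed by
#' continuity with the previous frame; the first frame is folded to
#' <= 90 degrees. Hydrogens are excluded by default.
#'
#' @param traj a [Trajectory].
#' @param sel [AtomSelection] or expression (default `"heavy"`).
#' @param includeHydrogens keep hydrogens in the selection.
#' @return data.frame with `frame` and `angle` (degrees).
#' @export
principalAxisZAngle <- function(traj, sel = "heavy",
                                includeHydrogens = FALSE) {
  if (is.character(sel)) sel <- selectAtoms(traj, sel)
  idx <- selIndices(sel)
  if (!includeHydrogens)
    idx <- setdiff(idx, which(atomData(traj)$element == "H"))
  if (length(idx) < 3) stop("need at least 3 atoms for a principal axis")
  sel <- new("AtomSelection", indices = sort(as.integer(idx)),
             label = sel@label)
  prev <- NULL
  ang <- vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- frameCoords(traj, f, sel)
    cv <- stats::cov(xyz)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[1] - ev$values[2] < 1e-10 * max(ev$values[1], 1))
      warning("near-degenerate (isotropic) covariance in frame ", f)
    v <- ev$vectors[, 1]
    if (is.null(prev)) {
      if (v[3] < 0) v <- -v             # fold first frame to <= 90 degrees
    } else if (sum(v * prev) < 0) v <- -v
    prev <<- v
    acos(max(-1, min(1, v[3]))) * 180 / pi
  }, numeric(1))
  data.frame(frame = seq_len(nFrames(traj)), angle = ang)
}
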