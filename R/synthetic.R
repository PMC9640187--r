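# Synthetic structures and trajectories with known ground truth. These are
# first-class generators: every analysis stage is validated against the
# parameters they embed (helix rise/twist, arc radius, rotation schedules,
# pair geometry) without requiring molecular dynamics output.

# Standard backbone stereochemistry used by the internal-coordinate builder.
BB <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231, b_N_H = 1.0,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8,
  phi = -57, psi = -47, omega = 180
)

mkAtoms <- function(name, element, resid, resname = "ALA", chain = "A") {
  data.frame(serial = seq_along(name), name = name, element = element,
             resname = rep_len(resname, length(name)),
             resid = resid, chain = rep_len(chain, length(name)),
             stringsAsFactors = FALSE)
}

# Parametric alpha-helical Calpha trace along +Z.
helixCA <- function(n, rise, twist, radius) {
  i <- seq_len(n) - 1
  phi <- i * twist * pi / 180
  cbind(radius * cos(phi), radius * sin(phi), i * rise)
}

# Internal-coordinate (NeRF) construction of an N/CA/C/O (+ amide H)
# backbone at fixed torsions. Returns coords plus atom metadata.
buildBackbone <- function(nRes, phi = BB$phi, psi = BB$psi,
                          omega = BB$omega, withH = TRUE) {
  stopifnot(nRes >= 2)
  N <- CA <- C <- O <- H <- matrix(NA_real_, nRes, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB$b_N_CA, 0, 0)
  th <- BB$a_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BB$b_CA_C * c(-cos(th), sin(th), 0)
  for (i in 2:nRes) {
    N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                        BB$b_C_N, BB$a_CA_C_N, psi)
    CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                         BB$b_N_CA, BB$a_C_N_CA, omega)
    C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                        BB$b_CA_C, BB$a_N_CA_C, phi)
  }
  for (i in seq_len(nRes)) {
    # carbonyl O anti to the next amide nitrogen (torsion psi + 180)
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], BB$b_C_O, BB$a_CA_C_O,
                        psi + 180)
    if (withH && i > 1) {
      d <- -(unitv(C[i - 1, ] - N[i, ]) + unitv(CA[i, ] - N[i, ]))
      H[i, ] <- N[i, ] + BB$b_N_H * unitv(d)
    }
  }
  list(N = N, CA = CA, C = C, O = O, H = H)
}

assembleBackboneFrame <- function(bb, nRes, withH = TRUE) {
  names_ <- c("N", "CA", "C", "O", "H")
  rows <- list(); nm <- c(); el <- c(); rid <- c()
  for (i in seq_len(nRes)) {
    for (a in names_) {
      if (a == "H" && (!withH || i == 1)) next
      rows[[length(rows) + 1]] <- bb[[a]][i, ]
      nm <- c(nm, a)
      el <- c(el, substr(a, 1, 1))
      rid <- c(rid, i)
    }
  }
  list(xyz = do.call(rbind, rows), atoms = mkAtoms(nm, el, rid))
}

#' Generate an ideal alpha-helix
#'
#' Calpha atoms lie exactly on the mathematical helix along +Z with the given
#' rise, twist and radius. With `withBackbone = TRUE` a full N/CA/C/O (+
#' amide H) backbone is built by internal-coordinate chain construction at
#' alpha-helical torsions (phi = -57, psi = -47 degrees) and rigidly
#' superposed onto the parametric Calpha trace, so that secondary-structure
#' assignment finds a helix.
#'
#' @param nRes number of residues (>= 4).
#' @param rise rise per residue, Angstrom (default 1.5).
#' @param twist twist per residue, degrees (default 100).
#' @param radius helix radius, Angstrom (default 2.3).
#' @param withBackbone build the full backbone instead of a Calpha trace.
#' @return a single-frame [Trajectory]; generator parameters are recorded in
#'   its metadata.
#' @examples
#' h <- makeIdealHelix(12)
#' helixLength(frameCoords(h))   # ~16.52 Angstrom
#' @export
makeIdealHelix <- function(nRes = 12, rise = 1.5, twist = 100, radius = 2.3,
                           withBackbone = FALSE) {
  stopifnot(nRes >= 4, rise > 0, radius > 0)
  ca <- helixCA(nRes, rise, twist, radius)
  meta <- list(kind = "ideal_helix", rise = rise, twist = twist,
               radius = radius)
  if (!withBackbone) {
    atoms <- mkAtoms(rep("CA", nRes), rep("C", nRes), seq_len(nRes))
    return(makeTrajectory(atoms, list(ca), metadata = meta))
  }
  bb <- buildBackbone(nRes)
  fr <- assembleBackboneFrame(bb, nRes)
  fit <- kabschSuperpose(bb$CA, ca)
  xyz <- sweep(fr$xyz %*% t(fit$rotation), 2, -fit$translation)
  makeTrajectory(fr$atoms, list(xyz), metadata = meta)
}

#' Generate a bent alpha-helix
#'
#' The helix is wound about a circular arc of radius `arcRadius`, so its
#' local axis points lie on a circle of that radius: the ground-truth bend
#' radius, recorded in the trajectory metadata, is `arcRadius`.
#'
#' @inheritParams makeIdealHelix
#' @param arcRadius radius of the superhelical arc, Angstrom (finite,
#'   greater than `radius`).
#' @return a single-frame Calpha-trace [Trajectory].
#' @export
makeBentHelix <- function(nRes = 30, rise = 1.5, twist = 100, radius = 2.3,
                          arcRadius = 50) {
  stopifnot(nRes >= 4)
  if (!is.finite(arcRadius))
    stop("arcRadius must be finite; use makeIdealHelix() for a straight helix")
  if (arcRadius <= radius)
    stop("arc too tight: arcRadius must exceed the helix radius")
  i <- seq_len(nRes) - 1
  alpha <- i * rise / arcRadius            # arclength angle along the arc
  phi <- i * twist * pi / 180
  path <- cbind(arcRadius * cos(alpha), 0, arcRadius * sin(alpha))
  nrm <- -cbind(cos(alpha), 0, sin(alpha)) # toward arc center
  bin <- matrix(rep(c(0, 1, 0), each = nRes), nRes, 3)
  ca <- path + radius * (cos(phi) * nrm + sin(phi) * bin)
  atoms <- mkAtoms(rep("CA", nRes), rep("C", nRes), seq_len(nRes))
  makeTrajectory(atoms, list(ca), metadata = list(
    kind = "bent_helix", rise = rise, twist = twist, radius = radius,
    bendRadius = arcRadius))
}

#' Rigid-body rotation trajectory
#'
#' Frame k is the (single-frame) base structure rotated by `angles[k]`
#' degrees about `axis` through `pivot`. Internal geometry is identical
#' across frames by construction.
#'
#' @param base a single-frame [Trajectory].
#' @param axis rotation axis (normalized internally).
#' @param angles rotation angle per output frame, degrees.
#' @param pivot point the axis passes through.
#' @return a [Trajectory] with `length(angles)` frames.
#' @export
makeRigidRotationTrajectory <- function(base, axis, angles,
                                        pivot = c(0, 0, 0)) {
  stopifnot(is(base, "Trajectory"), nFrames(base) == 1, length(angles) >= 1)
  xyz <- frameCoords(base, 1)
  frames <- lapply(angles, function(a) rotateAboutAxis(xyz, axis, a, pivot))
  makeTrajectory(base@topology@atoms, frames, metadata = c(
    base@metadata,
    list(rotationAxis = unitv(as.numeric(axis)), rotationAngles = angles,
         rotationPivot = pivot)))
}

#' Minimal two- to three-atom fixtures for clash and hydrogen-bond criteria
#'
#' `kind = "clash"` places two atoms of the given elements exactly `dist`
#' Angstrom apart in separate residues. `kind = "hbond"` builds a donor
#' heavy atom Y, its hydrogen (Y-H = 1 Angstrom) and an acceptor X with the
#' requested X-H distance and X...H-Y angle; X sits in a different residue.
#'
#' @param kind `"clash"` or `"hbond"`.
#' @param elements length-2 elements for the clash pair.
#' @param dist clash pair distance, Angstrom.
#' @param donorElement,acceptorElement polar heavy elements Y and X.
#' @param dXH acceptor-to-hydrogen distance, Angstrom.
#' @param angleXHY X...H-Y angle at the hydrogen, degrees.
#' @param residGap residue-number gap between the two partners.
#' @return a single-frame [Trajectory].
#' @export
makePairFixture <- function(kind = c("clash", "hbond"),
                            elements = c("C", "C"), dist = 1.6,
                            donorElement = "N", acceptorElement = "O",
                            dXH = 2.0, angleXHY = 180, residGap = 9) {
  kind <- match.arg(kind)
  if (kind == "clash") {
    stopifnot(length(elements) == 2, dist > 0)
    atoms <- mkAtoms(name = paste0(elements, c("1", "2")),
                     element = elements, resid = c(1L, 1L + residGap),
                     resname = "UNK")
    xyz <- rbind(c(0, 0, 0), c(dist, 0, 0))
    return(makeTrajectory(atoms, list(xyz),
                          metadata = list(kind = "clash", dist = dist)))
  }
  if (dXH <= 0 || angleXHY <= 0 || angleXHY > 180)
    stop("impossible hydrogen-bond geometry")
  Y <- c(0, 0, 0)
  H <- c(BB$b_N_H, 0, 0)
  a <- angleXHY * pi / 180
  X <- H + dXH * c(-cos(a), sin(a), 0)
  atoms <- mkAtoms(name = c(donorElement, "H", acceptorElement),
                   element = c(donorElement, "H", acceptorElement),
                   resid = c(1L, 1L, 1L + residGap), resname = "UNK")
  makeTrajectory(atoms, list(rbind(Y, H, X)), metadata = list(
    kind = "hbond", dXH = dXH, angleXHY = angleXHY))
}

#' Two-strand antiparallel beta-sheet fixture
#'
#' Two extended backbone strands (phi = -139, psi = 135 degrees) built by
#' internal-coordinate construction, the second rotated into antiparallel
#' orientation and offset so the inter-strand amide geometry hydrogen-bonds:
#' a minimal fixture whose interior residues secondary-structure assignment
#' codes as strand (E).
#'
#' @param nRes residues per strand.
#' @param separation inter-strand offset perpendicular to the strand axis,
#'   Angstrom.
#' @param slide register shift along the strand axis, Angstrom.
#' @return a single-frame [Trajectory] with chains A and B.
#' @export
makeAntiparallelSheet <- function(nRes = 8, separation = 4.0, slide = -2.0) {
  stopifnot(nRes >= 4)
  bb <- buildBackbone(nRes, phi = -139, psi = 135)
  fr <- assembleBackboneFrame(bb, nRes)
  ca <- bb$CA
  v <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
  if (sum(v * (ca[nRes, ] - ca[1, ])) < 0) v <- -v
  axis <- cross3(v, c(1, 0, 0))
  A <- sweep(fr$xyz, 2, colMeans(fr$xyz))
  if (vnorm(axis) > 1e-9)
    A <- A %*% t(rotationMatrix(axis, acos(sum(v * c(1, 0, 0))) * 180 / pi))
  B <- A %*% t(rotationMatrix(c(1, 0, 0), 180))
  B <- B %*% t(rotationMatrix(c(0, 0, 1), 180))
  B <- sweep(B, 2, -c(slide, separation, 0))
  atoms <- rbind(fr$atoms, fr$atoms)
  atoms$chain <- rep(c("A", "B"), each = nrow(fr$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  makeTrajectory(atoms, list(rbind(A, B)), metadata = list(
    kind = "antiparallel_sheet", separation = separation, slide = slide))
}

#' Self-avoiding random-coil Calpha trace
#'
#' A random walk with 3.8 Angstrom steps in which every non-consecutive
#' Calpha pair is kept at least 4.0 Angstrom apart (backtracking on dead
#' ends). Reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param nRes number of residues (>= 2).
#' @param seed integer seed.
#' @return a single-frame Calpha-trace [Trajectory].
#' @export
makeCoil <- function(nRes, seed = 1) {
  stopifnot(nRes >= 2)
  step <- 3.8; minsep <- 4.0
  withSeed(seed, {
    pts <- matrix(NA_real_, nRes, 3)
    pts[1, ] <- c(0, 0, 0)
    i <- 2L; tries <- integer(nRes)
    while (i <= nRes) {
      ok <- FALSE
      for (t in seq_len(60)) {
        u <- stats::rnorm(3)
        cand <- pts[i - 1, ] + step * unitv(u)
        prev <- if (i > 2) pts[seq_len(i - 2), , drop = FALSE] else NULL
        if (is.null(prev) ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= minsep) {
          pts[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (ok) {
        tries[i] <- 0L; i <- i + 1L
      } else {
        tries[i] <- tries[i] + 1L
        if (i > 2 && tries[i] < 20) i <- i - 1L   # backtrack and retry
        else stop("coil generation failed; try another seed")
      }
    }
    atoms <- mkAtoms(rep("CA", nRes), rep("C", nRes), seq_len(nRes),
                     resname = "GLY")
    makeTrajectory(atoms, list(pts),
                   metadata = list(kind = "coil", seed = seed))
  })
}
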