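# Kabsch-Sander secondary-structure assignment and per-residue timelines.
# This is deliberately separate from the geometric hydrogen-bond criterion in
# the contacts module: backbone H-bonds here use the electrostatic energy
# model, as in the original algorithm.

KS_COUPLING <- 27.888      # kcal/mol * Angstrom (q1*q2*332)
KS_CUTOFF <- -0.5          # kcal/mol; bond iff E < cutoff
CHAIN_BREAK_CN <- 2.5      # Angstrom; C(i)-N(i+1) beyond this is a break

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic model for a backbone N-H...O=C hydrogen bond:
#' `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, with partial
#' charges on N, H (donor) and C, O (acceptor). A bond is assigned when
#' `E < -0.5` kcal/mol. Any inter-atom distance below 0.5 Angstrom marks the
#' pair as a non-bond (clash guard, energy 0).
#'
#' @param donorN,donorH donor backbone N and amide H coordinates (length 3).
#' @param acceptorC,acceptorO acceptor backbone C and O coordinates.
#' @return energy in kcal/mol.
#' @export
ksHBondEnergy <- function(donorN, donorH, acceptorC, acceptorO) {
  rON <- vnorm(acceptorO - donorN)
  rCH <- vnorm(acceptorC - donorH)
  rOH <- vnorm(acceptorO - donorH)
  rCN <- vnorm(acceptorC - donorN)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(0)
  KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# Per-residue backbone atom indices in topology order; one row per residue.
backboneTable <- function(at) {
  key <- paste(at$chain, at$resid)
  resKeys <- unique(key)
  idx <- function(nm) vapply(resKeys, function(k) {
    w <- which(key == k & at$name == nm)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  hIdx <- vapply(resKeys, function(k) {
    w <- which(key == k & at$name %in% c("H", "HN") & at$element == "H")
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  first <- match(resKeys, key)
  data.frame(chain = at$chain[first], resid = at$resid[first],
             resname = at$resname[first],
             N = idx("N"), CA = idx("CA"), C = idx("C"), O = idx("O"),
             H = hIdx, row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign secondary structure to one frame (Kabsch-Sander)
#'
#' Backbone hydrogen bonds from [ksHBondEnergy()] define n-turns
#' (CO of residue i to NH of residue i+3/4/5); two consecutive turns make a
#' minimal helix (G/H/I for n = 3/4/5); parallel and antiparallel bridge
#' patterns define strands (E for ladders, B for isolated bridges); isolated
#' turns are T; a Calpha direction change above 70 degrees is a bend (S).
#' Code priority: H > E > G > I > B > T > S. Chain breaks are detected where
#' the peptide C-N distance exceeds 2.5 Angstrom. Amide hydrogens are taken
#' from the structure when present and otherwise reconstructed 1 Angstrom
#' from N, anti to the bisector of the C(prev)-N and CA-N bonds; residues
#' missing backbone atoms are coded `-` with a warning.
#'
#' @param traj a [Trajectory] with backbone N, CA, C, O atoms.
#' @param frame frame index.
#' @return named character vector of codes (`chain:resid` names), one per
#'   residue in topology order.
#' @export
assignDssp <- function(traj, frame = 1L) {
  at <- atomData(traj)
  bt <- backboneTable(at)
  xyz <- frameCoords(traj, frame)
  n <- nrow(bt)
  have <- !is.na(bt$N) & !is.na(bt$CA) & !is.na(bt$C) & !is.na(bt$O)
  if (any(!have))
    warning(sum(!have), " residue(s) missing backbone atoms; coded '-'")
  # chain connectivity: residue i is bonded to i+1 within the same chain
  # when C(i)-N(i+1) <= 2.5 Angstrom
  linked <- rep(FALSE, n)   # linked[i]: i connected to i+1
  for (i in seq_len(n - 1)) {
    if (bt$chain[i] == bt$chain[i + 1] && have[i] && have[i + 1])
      linked[i] <- vnorm(xyz[bt$C[i], ] - xyz[bt$N[i + 1], ]) <=
        CHAIN_BREAK_CN
  }
  # amide hydrogen per residue: explicit wins, else reconstructed
  Hxyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!have[i]) next
    if (!is.na(bt$H[i])) {
      Hxyz[i, ] <- xyz[bt$H[i], ]
    } else if (i > 1 && linked[i - 1] && bt$resname[i] != "PRO") {
      N <- xyz[bt$N[i], ]
      d <- -(unitv(xyz[bt$C[i - 1], ] - N) + unitv(xyz[bt$CA[i], ] - N))
      Hxyz[i, ] <- N + unitv(d)
    }
  }
  # hbond[i, j]: CO of residue i accepts from NH of residue j
  hb <- matrix(FALSE, n, n)
  caD <- crossDist(xyz[ifelse(have, bt$CA, 1), , drop = FALSE],
                   xyz[ifelse(have, bt$CA, 1), , drop = FALSE])
  for (i in seq_len(n)) {
    if (!have[i]) next
    for (j in seq_len(n)) {
      if (i == j || !have[j] || any(is.na(Hxyz[j, ]))) next
      if (caD[i, j] > 9) next
      e <- ksHBondEnergy(xyz[bt$N[j], ], Hxyz[j, ],
                         xyz[bt$C[i], ], xyz[bt$O[i], ])
      hb[i, j] <- e < KS_CUTOFF
    }
  }
  contiguous <- function(i, j) {
    if (i > j) return(contiguous(j, i))
    i >= 1 && j <= n && (i == j || all(linked[i:(j - 1)]))
  }
  turn <- function(i, k) i >= 1 && i + k <= n && contiguous(i, i + k) &&
    hb[i, i + k]
  codes <- rep("-", n)
  setIf <- function(idx, code, beats) {
    for (i in idx) if (codes[i] %in% beats) codes[i] <<- code
  }
  # bends first (lowest priority)
  for (i in if (n >= 5) 3:(n - 2) else integer(0)) {
    if (!contiguous(i - 2, i + 2) || !have[i]) next
    u <- xyz[bt$CA[i], ] - xyz[bt$CA[i - 2], ]
    v <- xyz[bt$CA[i + 2], ] - xyz[bt$CA[i], ]
    ang <- acos(max(-1, min(1, sum(unitv(u) * unitv(v))))) * 180 / pi
    if (ang > 70) codes[i] <- "S"
  }
  # isolated turns: residues bracketed by an n-turn get T
  for (k in 3:5) for (i in seq_len(n)) {
    if (turn(i, k)) setIf((i + 1):(i + k - 1), "T", c("-", "S"))
  }
  # bridges and ladders
  bridgeP <- matrix(FALSE, n, n); bridgeA <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3) next
    pa <- (i > 1 && contiguous(i - 1, i + 1) && i + 1 <= n &&
             hb[i - 1, j] && hb[j, i + 1]) ||
          (j > 1 && contiguous(j - 1, j + 1) && j + 1 <= n &&
             hb[j - 1, i] && hb[i, j + 1])
    ap <- (hb[i, j] && hb[j, i]) ||
          (i > 1 && j > 1 && i + 1 <= n && j + 1 <= n &&
             contiguous(i - 1, i + 1) && contiguous(j - 1, j + 1) &&
             hb[i - 1, j + 1] && hb[j - 1, i + 1])
    bridgeP[i, j] <- pa
    bridgeA[i, j] <- ap
  }
  bridged <- bridgeP | bridgeA
  inLadder <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!bridged[i, j]) next
    ext <- (i + 1 <= n && ((j + 1 <= n && bridged[i + 1, j + 1]) ||
                             (j - 1 >= 1 && bridged[i + 1, j - 1]))) ||
           (i - 1 >= 1 && ((j - 1 >= 1 && bridged[i - 1, j - 1]) ||
                             (j + 1 <= n && bridged[i - 1, j + 1])))
    if (ext) inLadder[i] <- inLadder[j] <- TRUE
  }
  hasBridge <- apply(bridged, 1, any) | apply(bridged, 2, any)
  setIf(which(hasBridge & !inLadder), "B", c("-", "S", "T"))
  # helices: two consecutive n-turns; apply in priority order I, G, then E, H
  minimalHelix <- function(k) {
    starts <- which(vapply(seq_len(n), function(i)
      i > 1 && turn(i - 1, k) && turn(i, k), logical(1)))
    unique(unlist(lapply(starts, function(i) i:(i + k - 1))))
  }
  setIf(minimalHelix(5), "I", c("-", "S", "T", "B"))
  setIf(minimalHelix(3), "G", c("-", "S", "T", "B", "I"))
  setIf(which(hasBridge & inLadder), "E", c("-", "S", "T", "B", "I", "G"))
  setIf(minimalHelix(4), "H", c("-", "S", "T", "B", "I", "G", "E"))
  names(codes) <- paste0(bt$chain, ":", bt$resid)
  codes
}

#' Secondary-structure timeline over a trajectory
#'
#' Column k of the timeline is the [assignDssp()] assignment of frame k,
#' restricted to the residues covered by `sel`. Per-residue persistence
#' summaries (fraction of frames helical H/G/I and strand E/B) are attached
#' as the `persistence` attribute.
#'
#' @param traj a [Trajectory].
#' @param sel optional [AtomSelection] (or expression) restricting residues.
#' @return an [SSETimeline].
#' @export
dsspTimeline <- function(traj, sel = NULL) {
  at <- atomData(traj)
  if (is.character(sel)) sel <- selectAtoms(traj, sel)
  keep <- if (is.null(sel)) seq_len(nrow(at)) else selIndices(sel)
  resKeys <- unique(paste0(at$chain, ":", at$resid))
  selKeys <- unique(paste0(at$chain[keep], ":", at$resid[keep]))
  rows <- which(resKeys %in% selKeys)
  nf <- nFrames(traj)
  codes <- matrix("-", length(rows), nf)
  for (f in seq_len(nf))
    codes[, f] <- assignDssp(traj, f)[rows]
  chain <- sub(":.*", "", resKeys[rows])
  resid <- as.integer(sub(".*:", "", resKeys[rows]))
  tl <- new("SSETimeline", codes = codes, resid = resid, chain = chain)
  attr(tl, "persistence") <- data.frame(
    chain = chain, resid = resid,
    helixFraction = rowMeans(matrix(codes %in% c("H", "G", "I"),
                                    nrow(codes))),
    strandFraction = rowMeans(matrix(codes %in% c("E", "B"), nrow(codes))))
  tl
}
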