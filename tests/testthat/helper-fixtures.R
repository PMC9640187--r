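# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive enumerations, independent of the implementation paths they check.

mkTraj <- hingeflex:::makeTrajectory

# Bare point-cloud trajectory: one residue per atom, carbon unless stated.
pointTraj <- function(xyz, element = "C", chain = "A",
                      resid = seq_len(nrow(xyz))) {
  xyz <- as.matrix(xyz)
  at <- data.frame(serial = seq_len(nrow(xyz)),
                   name = paste0("X", seq_len(nrow(xyz))),
                   element = rep_len(element, nrow(xyz)),
                   resname = "UNK", resid = resid,
                   chain = rep_len(chain, nrow(xyz)),
                   stringsAsFactors = FALSE)
  mkTraj(at, list(xyz))
}

wholeSel <- function(traj) selectAtoms(traj, "all")

# Elongated, effectively one-dimensional trajectory marker: a thin helix is
# a numerically safe stand-in for a rod along Z.
makeRod <- function(n = 20, length = 30) {
  pointTraj(cbind(0, 0, seq(0, length, length.out = n)))
}

# --- brute-force oracles -----------------------------------------------------

# O(N^2) clash oracle: explicit double loop and if/else threshold logic.
oracleClashes <- function(xyzA, elemA, xyzB, elemB,
                          tS = 2.10, tNO = 1.68, tC = 1.65) {
  hits <- list()
  for (i in seq_len(nrow(xyzA))) {
    for (j in seq_len(nrow(xyzB))) {
      d <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
      thr <- if (elemA[i] == "S" || elemB[j] == "S") tS
      else if (elemA[i] %in% c("N", "O") || elemB[j] %in% c("N", "O")) tNO
      else tC
      if (d < thr) hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (!length(hits)) matrix(integer(0), 0, 2) else do.call(rbind, hits)
}

# O(N^2) mutually-proximal oracle (ties to the lowest index).
oracleMutual <- function(xyzA, xyzB) {
  nA <- nrow(xyzA); nB <- nrow(xyzB)
  d <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB))
    d[i, j] <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
  hits <- list()
  for (i in seq_len(nA)) {
    j <- which.min(d[i, ])
    if (which.min(d[, j]) == i) hits[[length(hits) + 1]] <- c(i, j)
  }
  if (!length(hits)) matrix(integer(0), 0, 2) else do.call(rbind, hits)
}

# Exhaustive minimax representative.
oracleRepresentative <- function(m, members) {
  best <- NA_integer_; bestVal <- Inf
  for (i in members) {
    worst <- max(m[i, setdiff(members, i)], 0)
    if (worst < bestVal) {
      bestVal <- worst; best <- i
    }
  }
  best
}

# 1-degree brute-force rotation scan oracle (merged-system box volume).
oracleScanAngle <- function(mobileXYZ, fixedXYZ, pivot) {
  angles <- 0:359
  vols <- vapply(angles, function(a) {
    rot <- hingeflex:::rotateAboutAxis(mobileXYZ, c(0, 0, 1), a, pivot)
    enclosingBoxVolume(rbind(rot, fixedXYZ))
  }, numeric(1))
  angles[which.min(vols)]
}

angularDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# --- reference DSSP oracle (mdtraj, via the system python) -------------------

# Writes each fixture to PDB, runs mdtraj's built-in DSSP implementation in
# one python process, returns a list of frames x residues code matrices
# using the simplified H/E/C alphabet.
referenceDSSP <- function(trajs) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- vapply(seq_along(trajs), function(i) {
    p <- file.path(dir, paste0("fix", i, ".pdb"))
    writePDB(trajs[[i]], p)
    p
  }, character(1))
  outp <- file.path(dir, "dssp.txt")
  script <- file.path(dir, "dssp.py")
  writeLines(c(
    "import sys, mdtraj as md",
    "out = open(sys.argv[1], 'w')",
    "for p in sys.argv[2:]:",
    "    t = md.load(p)",
    "    d = md.compute_dssp(t, simplified=True)",
    "    for row in d:",
    "        out.write(''.join(row) + '\\n')",
    "    out.write('#\\n')",
    "out.close()"
  ), script)
  status <- system2("python", c(script, outp, paths),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("reference DSSP (python/mdtraj) failed")
  lines <- readLines(outp)
  res <- list(); cur <- character(0)
  for (ln in lines) {
    if (ln == "#") {
      res[[length(res) + 1]] <- cur; cur <- character(0)
    } else cur <- c(cur, ln)
  }
  res
}

collapseSS <- function(codes) {
  out <- ifelse(codes %in% c("H", "G", "I"), "H",
                ifelse(codes %in% c("E", "B"), "E", "C"))
  out
}
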