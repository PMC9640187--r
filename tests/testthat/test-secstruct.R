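test_that("Kabsch-Sander energy matches the closed form and is directional", {
  # collinear N(0), H(1), O(2.9), C(4.14) along X
  N <- c(0, 0, 0); H <- c(1, 0, 0); O <- c(2.9, 0, 0); C <- c(4.14, 0, 0)
  e <- ksHBondEnergy(N, H, C, O)
  closed <- 27.888 * (1 / 2.9 + 1 / 3.14 - 1 / 1.9 - 1 / 4.14)
  expect_equal(e, closed, tolerance = 1e-9)
  expect_equal(e, -2.92, tolerance = 0.005)
  expect_lt(e, -0.5)

  # acceptor group pulled far away: energy decays well above the cutoff
  far <- ksHBondEnergy(N, H, C + c(7.1, 0, 0), O + c(7.1, 0, 0))
  closedFar <- 27.888 * (1 / 10 + 1 / 10.24 - 1 / 9 - 1 / 11.24)
  expect_equal(far, closedFar, tolerance = 1e-9)
  expect_gt(far, -0.5)

  # bonding is directional between residues: donating i -> j uses different
  # atoms than j -> i
  N1 <- c(0, 0, 0); H1 <- c(-0.6, 0.8, 0); C1 <- c(1.3, 0.6, 0)
  O1 <- c(1.3, 1.8, 0)
  N2 <- c(3.5, 0, 0); H2 <- c(2.6, 0.3, 0); C2 <- c(4.6, -0.8, 0)
  O2 <- c(4.6, -2.0, 0)
  expect_false(isTRUE(all.equal(ksHBondEnergy(N2, H2, C1, O1),
                                ksHBondEnergy(N1, H1, C2, O2))))
  # clash guard: any of the four donor-acceptor distances under 0.5 A
  expect_identical(ksHBondEnergy(N, H, C, H + c(0.3, 0, 0)), 0)
})

test_that("ideal helices are assigned H over their interior", {
  for (n in c(8, 12, 16)) {
    h <- makeIdealHelix(n, withBackbone = TRUE)
    codes <- assignDssp(h)
    expect_gte(sum(codes == "H"), n - 4)
  }
})

test_that("antiparallel sheet fixtures are assigned E in the strand interior", {
  sh <- makeAntiparallelSheet(8)
  codes <- assignDssp(sh)
  perChain <- split(codes, sub(":.*", "", names(codes)))
  for (ch in perChain) expect_gte(sum(ch == "E"), 4)
})

test_that("assignments are invariant under global rigid motion", {
  h <- makeIdealHelix(12, withBackbone = TRUE)
  before <- assignDssp(h)
  moved <- hingeflex:::rotateAboutAxis(frameCoords(h), c(2, 1, 1), 118,
                                       c(3, 3, 3)) - 40
  after <- assignDssp(mkTraj(atomData(h), list(moved)))
  expect_identical(before, after)
})

test_that("residues missing backbone atoms are coded '-' with a warning", {
  co <- makeCoil(10, seed = 1)  # Calpha-only trace
  expect_warning(codes <- assignDssp(co), "missing backbone")
  expect_identical(unname(codes), rep("-", 10))
})

test_that("assignments agree with the reference DSSP implementation", {
  fixtures <- list(
    makeIdealHelix(8, withBackbone = TRUE),
    makeIdealHelix(12, withBackbone = TRUE),
    makeIdealHelix(16, withBackbone = TRUE),
    makeAntiparallelSheet(8),
    makeAntiparallelSheet(10)
  )
  # plus mildly distorted helices (multi-frame)
  set.seed(31)
  h <- makeIdealHelix(14, withBackbone = TRUE)
  frames <- lapply(1:3, function(i)
    frameCoords(h) + matrix(rnorm(3 * nAtoms(h), sd = 0.08), ncol = 3))
  fixtures <- c(fixtures, list(mkTraj(atomData(h), frames)))

  ref <- referenceDSSP(fixtures)
  agree <- 0L; total <- 0L
  for (k in seq_along(fixtures)) {
    for (f in seq_len(nFrames(fixtures[[k]]))) {
      ours <- collapseSS(assignDssp(fixtures[[k]], f))
      theirs <- strsplit(ref[[k]][f], "")[[1]]
      expect_length(ours, length(theirs))
      agree <- agree + sum(ours == theirs)
      total <- total + length(ours)
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("timelines stack per-frame assignments in residue x frame order", {
  h <- makeIdealHelix(10, withBackbone = TRUE)
  static <- mkTraj(atomData(h), replicate(5, frameCoords(h),
                                          simplify = FALSE))
  tl <- dsspTimeline(static)
  expect_identical(dim(tl@codes), c(10L, 5L))
  expect_true(all(tl@codes == tl@codes[, 1]))

  # helix frames then coil-like (scrambled) frames
  set.seed(8)
  melted <- frameCoords(h) + matrix(rnorm(3 * nAtoms(h), sd = 3), ncol = 3)
  mixed <- mkTraj(atomData(h), c(replicate(3, frameCoords(h),
                                           simplify = FALSE),
                                 replicate(3, melted, simplify = FALSE)))
  tl2 <- dsspTimeline(mixed)
  pers <- attr(tl2, "persistence")
  interior <- pers$resid >= 3 & pers$resid <= 8
  expect_true(all(pers$helixFraction[interior] <= 0.5 + 1e-9))
  expect_true(all(pers$helixFraction[interior] >= 0.5 - 1e-9))

  sel <- selectAtoms(h, "resid 2-6")
  tl3 <- dsspTimeline(static, sel)
  expect_identical(dim(tl3@codes), c(5L, 5L))
  expect_identical(tl3@resid, 2:6)
})
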