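selOn <- function(traj, idx, label = "sel")
  new("AtomSelection", indices = as.integer(idx), label = label)

test_that("clash rule applies element-dependent thresholds with S precedence", {
  cases <- list(
    list(el = c("C", "C"), d = 1.60, hit = TRUE),
    list(el = c("C", "C"), d = 1.70, hit = FALSE),
    list(el = c("S", "C"), d = 2.00, hit = TRUE),   # S precedence
    list(el = c("N", "C"), d = 2.00, hit = FALSE),
    list(el = c("N", "C"), d = 1.67, hit = TRUE),
    list(el = c("S", "N"), d = 2.09, hit = TRUE)
  )
  for (cs in cases) {
    fx <- makePairFixture("clash", elements = cs$el, dist = cs$d)
    got <- findClashes(fx, selOn(fx, 1), selOn(fx, 2))
    expect_equal(nrow(got$pairs) == 1, cs$hit,
                 label = paste(cs$el[1], cs$el[2], cs$d))
  }
  # hydrogens silently dropped; empty heavy selection errors
  hfx <- pointTraj(rbind(c(0, 0, 0), c(1, 0, 0)), element = c("H", "C"))
  expect_error(findClashes(hfx, selOn(hfx, 1), selOn(hfx, 2)), "empty")
})

test_that("clash finder equals the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:40) {
    nA <- sample(5:40, 1); nB <- sample(5:40, 1)
    elA <- sample(c("C", "N", "O", "S"), nA, replace = TRUE)
    elB <- sample(c("C", "N", "O", "S"), nB, replace = TRUE)
    xyzA <- matrix(runif(3 * nA, 0, 8), ncol = 3)
    xyzB <- matrix(runif(3 * nB, 0, 8), ncol = 3)
    tr <- pointTraj(rbind(xyzA, xyzB), element = c(elA, elB))
    got <- findClashes(tr, selOn(tr, 1:nA), selOn(tr, nA + 1:nB))$pairs
    want <- oracleClashes(xyzA, elA, xyzB, elB)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      wantKeys <- sort(paste(want[, 1], want[, 2] + nA))
      expect_identical(sort(paste(got$atomA, got$atomB)), wantKeys)
    }
  }
  # one larger instance
  nA <- 250; nB <- 250
  elA <- sample(c("C", "N", "O", "S"), nA, replace = TRUE)
  elB <- sample(c("C", "N", "O", "S"), nB, replace = TRUE)
  xyzA <- matrix(runif(3 * nA, 0, 14), ncol = 3)
  xyzB <- matrix(runif(3 * nB, 0, 14), ncol = 3)
  tr <- pointTraj(rbind(xyzA, xyzB), element = c(elA, elB))
  got <- findClashes(tr, selOn(tr, 1:nA), selOn(tr, nA + 1:nB))$pairs
  expect_equal(nrow(got), nrow(oracleClashes(xyzA, elA, xyzB, elB)))
})

test_that("clash summary counts A-side atoms and residues once", {
  # two A atoms in one residue, both clashing two B atoms
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.0, 0, 0), c(1.2, 0, 0))
  tr <- pointTraj(xyz, element = "C", resid = c(1L, 1L, 5L, 6L))
  got <- findClashes(tr, selOn(tr, 1:2), selOn(tr, 3:4))
  expect_gt(nrow(got$pairs), 2)
  expect_equal(unname(got$summary["nAtomsA"]), 2)
  expect_equal(unname(got$summary["nResiduesA"]), 1)
})

test_that("mutually-proximal contacts match exhaustive nearest-neighbor checks", {
  A <- rbind(c(0, 0, 0), c(5, 0, 0))
  B <- rbind(c(1, 0, 0), c(4, 0, 0))
  tr <- pointTraj(rbind(A, B))
  got <- mutualProximalContacts(tr, selOn(tr, 1:2), selOn(tr, 3:4))
  expect_identical(got$atomA, c(1L, 2L))
  expect_identical(got$atomB, c(3L, 4L))

  tr2 <- pointTraj(rbind(c(0, 0, 0), c(10, 0, 0), c(1, 0, 0)))
  got2 <- mutualProximalContacts(tr2, selOn(tr2, 1:2), selOn(tr2, 3))
  expect_equal(nrow(got2), 1)
  expect_identical(got2$atomA, 1L)

  set.seed(7)
  for (rep in 1:40) {
    nA <- sample(3:50, 1); nB <- sample(3:50, 1)
    xyzA <- matrix(runif(3 * nA, 0, 10), ncol = 3)
    xyzB <- matrix(runif(3 * nB, 0, 10), ncol = 3)
    tr <- pointTraj(rbind(xyzA, xyzB))
    got <- mutualProximalContacts(tr, selOn(tr, 1:nA), selOn(tr, nA + 1:nB))
    want <- oracleMutual(xyzA, xyzB)
    expect_identical(sort(paste(got$atomA, got$atomB)),
                     sort(paste(want[, 1], want[, 2] + nA)))
    expect_lte(nrow(got), min(nA, nB))
    expect_false(anyDuplicated(got$atomA) > 0)
    expect_false(anyDuplicated(got$atomB) > 0)
  }
})

test_that("hydrogen-bond criterion honors distance, angle and element thresholds", {
  hb <- makePairFixture("hbond", dXH = 2.0, angleXHY = 180)
  got <- findHBonds(hb)
  expect_equal(nrow(got), 1)
  expect_equal(got$distXH, 2.0, tolerance = 1e-9)

  expect_equal(nrow(findHBonds(makePairFixture("hbond", dXH = 2.6))), 0)
  expect_equal(nrow(findHBonds(makePairFixture("hbond", dXH = 2.0,
                                               angleXHY = 110))), 0)
  # sulfur acceptor threshold 3.15
  expect_equal(nrow(findHBonds(makePairFixture("hbond",
    acceptorElement = "S", dXH = 3.0, angleXHY = 150))), 1)
  expect_equal(nrow(findHBonds(makePairFixture("hbond",
    acceptorElement = "S", dXH = 3.2, angleXHY = 150))), 0)
  # phosphorus acceptor threshold 3.24
  expect_equal(nrow(findHBonds(makePairFixture("hbond",
    acceptorElement = "P", dXH = 3.2, angleXHY = 150))), 1)

  noH <- pointTraj(matrix(rnorm(9), 3), element = "O")
  expect_error(findHBonds(noH), "no hydrogens")
})

test_that("hydrogen bonds are invariant under global rigid motion", {
  hb <- makePairFixture("hbond", dXH = 2.3, angleXHY = 140)
  before <- findHBonds(hb)
  xyz <- frameCoords(hb)
  moved <- hingeflex:::rotateAboutAxis(xyz, c(1, 1, 0), 63,
                                       c(4, -2, 7)) + 11
  after <- findHBonds(mkTraj(atomData(hb), list(moved)))
  expect_identical(before[c("X", "H", "Y")], after[c("X", "H", "Y")])
  expect_equal(before$angle, after$angle, tolerance = 1e-9)
})

test_that("residue-pair tracks filter on separation and occupancy", {
  hb <- makePairFixture("hbond", dXH = 2.0, angleXHY = 180, residGap = 6)
  bonded <- frameCoords(hb)
  broken <- bonded; broken[3, ] <- broken[3, ] + c(10, 0, 0)
  mkTracks <- function(nOn, nOff, gapTraj = hb) {
    frames <- c(replicate(nOn, bonded, simplify = FALSE),
                replicate(nOff, broken, simplify = FALSE))
    mkTraj(atomData(gapTraj), frames)
  }
  kept <- hbondResidueTracks(mkTracks(20, 80), "all")
  expect_equal(nrow(kept$tracks), 1)
  expect_equal(kept$tracks$occupancy, 0.20)
  expect_equal(kept$tracks$firstFormed, 1L)
  expect_identical(kept$tracks$label, "intra")

  dropped <- hbondResidueTracks(mkTracks(10, 90), "all")
  expect_equal(nrow(dropped$tracks), 0)

  close_gap <- makePairFixture("hbond", dXH = 2.0, angleXHY = 180,
                               residGap = 3)
  closeB <- frameCoords(close_gap)
  frames <- replicate(10, closeB, simplify = FALSE)
  near <- hbondResidueTracks(mkTraj(atomData(close_gap), frames), "all")
  expect_equal(nrow(near$tracks), 0)  # delta resid 3 < 5, despite occupancy 1

  # occupancy is insensitive to frame order; firstFormed is not
  shuffled <- hbondResidueTracks(mkTraj(atomData(hb), c(
    replicate(40, broken, simplify = FALSE),
    replicate(20, bonded, simplify = FALSE),
    replicate(40, broken, simplify = FALSE))), "all")
  expect_equal(shuffled$tracks$occupancy, 0.20)
  expect_equal(shuffled$tracks$firstFormed, 41L)
})

test_that("track saturation flags late-forming bonds", {
  tracks <- data.frame(firstFormed = c(1L, 10L, 40L))
  got <- trackSaturation(tracks, 100)
  expect_identical(got$counts, c(2L, 1L, 0L, 0L))
  expect_true(got$saturated)

  late <- trackSaturation(data.frame(firstFormed = 90L), 100)
  expect_identical(late$counts, c(0L, 0L, 0L, 1L))
  expect_false(late$saturated)

  none <- trackSaturation(data.frame(firstFormed = integer(0)), 100)
  expect_identical(none$counts, rep(0L, 4))
  expect_true(none$saturated)
})

test_that("distance time series track pairs frame by frame", {
  xyz <- rbind(c(0, 0, 0), c(3.44, 0, 0))
  frames <- replicate(5, xyz, simplify = FALSE)
  tr <- pointTraj(xyz)
  ts <- distanceTimeseries(mkTraj(atomData(tr), frames), rbind(c(1, 2)))
  expect_equal(ts$distance, rep(3.44, 5))

  sep <- lapply(0:4, function(k) rbind(c(0, 0, 0), c(3 + k, 0, 0)))
  ts2 <- distanceTimeseries(mkTraj(atomData(tr), sep), rbind(c(1, 2)))
  expect_identical(ts2$distance, as.numeric(3:7))

  rot <- makeRigidRotationTrajectory(tr, c(0, 0, 1), c(0, 45, 90, 135))
  ts3 <- distanceTimeseries(rot, rbind(c(1, 2)))
  expect_equal(diff(range(ts3$distance)), 0, tolerance = 1e-9)

  expect_error(distanceTimeseries(tr, rbind(c(1, 99))), "invalid atom index")
})
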