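test_that("proline splitting starts a new segment at each proline", {
  seqs <- rep("LEU", 20); seqs[11] <- "PRO"
  spans <- splitOnProline(1:20, seqs, minLen = 4)
  expect_identical(spans, list(1:10, 11:20))

  seqs2 <- rep("LEU", 20); seqs2[3] <- "PRO"
  expect_message(spans2 <- splitOnProline(1:20, seqs2, minLen = 4),
                 "discarding")
  expect_identical(spans2, list(3:20))

  expect_identical(splitOnProline(5:24, rep("ALA", 20), 4), list(5:24))
})

test_that("helix axis fitting recovers direction and axis line", {
  h <- makeIdealHelix(12)
  d <- fitHelixAxis(frameCoords(h))
  expect_gt(sum(d@axisDir * c(0, 0, 1)), 0.999)
  # local axis points lie on the true axis (the Z axis) within 0.1 A
  offAxis <- sqrt(d@localAxisPoints[, 1]^2 + d@localAxisPoints[, 2]^2)
  expect_lt(max(offAxis), 0.1)

  # equivariance under a known rotation
  R <- rotationMatrix(c(1, 1, 0), 35)
  rot <- mkTraj(atomData(h), list(frameCoords(h) %*% t(R)))
  d2 <- fitHelixAxis(frameCoords(rot))
  expect_equal(d2@axisDir, as.vector(R %*% c(0, 0, 1)), tolerance = 1e-3)

  expect_error(fitHelixAxis(frameCoords(h)[1:4, ]), "at least 5")
})

test_that("helix length is the end-to-end Calpha distance", {
  h <- makeIdealHelix(12)
  expect_equal(helixLength(frameCoords(h)), 16.52, tolerance = 0.01)
  expect_equal(helixLength(rbind(c(0, 0, 0), c(0, 0, 3.8))), 3.8)
  moved <- hingeflex:::rotateAboutAxis(frameCoords(h), c(1, 0, 1), 71) + 4
  expect_equal(helixLength(moved), helixLength(frameCoords(h)),
               tolerance = 1e-9)
})

test_that("bend radius recovers generator arc radii and caps straight helices", {
  expect_gte(bendRadius(frameCoords(makeIdealHelix(30))), 1000)
  for (arc in c(20, 50, 100)) {
    fit <- bendRadius(frameCoords(makeBentHelix(30, arcRadius = arc)))
    expect_lt(abs(fit - arc) / arc, 0.10, label = paste("arc", arc))
  }
  # monotone: tighter arcs give smaller fitted radii
  fits <- vapply(c(20, 50, 100), function(a)
    bendRadius(frameCoords(makeBentHelix(30, arcRadius = a))), numeric(1))
  expect_true(all(diff(fits) > 0))

  # algebraic fit on exact circle points
  th <- seq(0, 1.8, length.out = 12)
  circ <- cbind(20 * cos(th), 20 * sin(th), 0)
  expect_equal(hingeflex:::circleFitRadius(circ), 20, tolerance = 1e-3)

  # raw-Calpha variant is contaminated by the helical winding
  bent <- frameCoords(makeBentHelix(30, arcRadius = 50))
  raw <- bendRadius(bent, useRawCA = TRUE)
  smooth <- bendRadius(bent)
  expect_gt(abs(raw - 50), abs(smooth - 50))
})

test_that("helix pair metrics cover parallel, crossing and antiparallel axes", {
  mkdesc <- function(shift = c(0, 0, 0), R = diag(3), n = 12) {
    ca <- frameCoords(makeIdealHelix(n)) %*% t(R)
    fitHelixAxis(sweep(ca, 2, -shift))
  }
  d1 <- mkdesc()
  d2 <- mkdesc(shift = c(10, 0, 0))
  pm <- helixPairMetrics(d1, d2)
  expect_equal(pm$closestApproach, 10, tolerance = 1e-3)
  expect_equal(pm$centerDistance, 10, tolerance = 1e-3)
  expect_equal(pm$angle, 0, tolerance = 0.2)

  # perpendicular, crossing 5 A away from the first helix mid-axis
  d3 <- mkdesc(shift = c(-8, 5, 8), R = rotationMatrix(c(0, 1, 0), 90))
  pm2 <- helixPairMetrics(d1, d3)
  expect_equal(pm2$angle, 90, tolerance = 0.2)
  expect_equal(pm2$closestApproach, 5, tolerance = 0.1)

  d4 <- mkdesc(shift = c(6, 0, 0), R = rotationMatrix(c(1, 0, 0), 180))
  expect_equal(helixPairMetrics(d1, d4)$angle, 180, tolerance = 0.2)

  # symmetry and ordering invariants
  expect_equal(helixPairMetrics(d3, d1)$angle, pm2$angle)
  for (d in list(d2, d3, d4)) {
    m <- helixPairMetrics(d1, d)
    expect_lte(m$closestApproach, m$centerDistance + 1e-9)
  }
})

test_that("significance flag marks references outside the representative range", {
  expect_identical(significanceFlag(5.0, c(5.5, 6.0, 6.2)), "S")
  expect_identical(significanceFlag(5.8, c(5.5, 6.0, 6.2)), "n")
  expect_identical(significanceFlag(5.5, c(5.5, 6.0, 6.2)), "n")  # boundary
  expect_identical(significanceFlag(6.5, c(5.5, 6.0, 6.2)), "S")
  expect_error(significanceFlag(1, numeric(0)), "no representative")
})

test_that("helix tables report per-helix and pairwise changes with flags", {
  base <- makeIdealHelix(40, withBackbone = TRUE)
  at <- atomData(base)
  at$resname[at$resid == 21] <- "PRO"   # split helix "2" into 2.1/2.2
  xyz <- frameCoords(base)
  ref <- mkTraj(at, list(xyz))
  # representatives: identical to reference
  traj <- mkTraj(at, replicate(3, xyz, simplify = FALSE))
  defs <- data.frame(name = c("1", "2"), chain = "A",
                     first = c(1L, 11L), last = c(10L, 40L))
  rep1 <- helixTableReport(ref, traj, 1:3, defs)
  expect_identical(rep1$helices$name, c("1", "2.1", "2.2"))
  expect_equal(rep1$helices$lengthChange, rep(0, 3), tolerance = 1e-9)
  expect_identical(rep1$helices$lengthFlag, rep("n", 3))
  expect_identical(dim(rep1$angle), c(3L, 3L))

  # uniformly stretched representatives flag a significant length change
  stretched <- replicate(3, {
    x <- xyz; x[, 3] <- x[, 3] * 1.1; x
  }, simplify = FALSE)
  rep2 <- helixTableReport(ref, mkTraj(at, stretched), 1:3, defs)
  expect_identical(rep2$helices$lengthFlag, rep("S", 3))
  expect_true(all(rep2$helices$lengthChange > 0))
})
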