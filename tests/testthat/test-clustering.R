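test_that("Kabsch superposition recovers rigid motions and proper rotations", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabschSuperpose(P, P)$rmsd, 0, tolerance = 1e-10)

  R <- rotationMatrix(c(0, 0, 1), 90)
  Q <- sweep(P %*% t(R), 2, -c(3, -1, 2))
  fit <- kabschSuperpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(sweep(P %*% t(fit$rotation), 2, -fit$translation), Q,
               tolerance = 1e-9, ignore_attr = TRUE)

  # reflection must not be used even when it would fit better
  Pm <- P; Pm[, 3] <- -Pm[, 3]
  expect_equal(det(kabschSuperpose(P, Pm)$rotation), 1, tolerance = 1e-9)

  # agreement with an independent implementation on noisy pairs
  for (i in 1:10) {
    A <- matrix(rnorm(24), 8, 3)
    B <- A %*% t(rotationMatrix(rnorm(3), runif(1, 0, 180))) +
      matrix(rnorm(24, sd = 0.3), 8, 3)
    ours <- kabschSuperpose(A, B)$rmsd
    theirs <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_lt(abs(ours - theirs), 6e-4)   # bio3d reports 3 decimals
  }
  expect_error(kabschSuperpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabschSuperpose(line, line), "degenerate")
})

test_that("RMSD maps are zero for internally rigid ensembles", {
  rod <- makeIdealHelix(10)
  same <- mkTraj(atomData(rod), replicate(6, frameCoords(rod),
                                          simplify = FALSE))
  m <- rmsdMap(same, "all")
  expect_equal(max(m@matrix), 0, tolerance = 1e-10)

  rot <- makeRigidRotationTrajectory(rod, c(0, 1, 0), seq(0, 100, by = 20))
  m2 <- rmsdMap(rot, "all")
  expect_equal(max(m2@matrix), 0, tolerance = 1e-8)
})

test_that("separate fit and measure selections expose relative motion", {
  # domain A static at the origin region, domain B rotates about Z
  A <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(1, 1, 1))
  B <- rbind(c(10, 0, 0), c(12, 0, 0), c(10, 2, 0), c(10, 0, 2))
  rotB <- hingeflex:::rotateAboutAxis(B, c(0, 0, 1), 90)
  tr <- mkTraj(pointTraj(rbind(A, B))@topology@atoms,
               list(rbind(A, B), rbind(A, rotB)))
  selA <- new("AtomSelection", indices = 1:5, label = "A")
  selB <- new("AtomSelection", indices = 6:9, label = "B")
  m <- rmsdMap(tr, measureSel = selB, fitSel = selA)
  direct <- sqrt(sum((B - rotB)^2) / nrow(B))
  expect_equal(m@matrix[1, 2], direct, tolerance = 1e-9)
  # fitting on the moving part itself hides the motion
  m2 <- rmsdMap(tr, measureSel = selB)
  expect_equal(m2@matrix[1, 2], 0, tolerance = 1e-9)
})

test_that("RMSD map rows are invariant to rigid motion of single frames", {
  set.seed(11)
  co <- makeCoil(15, seed = 2)
  frames <- lapply(1:4, function(i)
    frameCoords(co) + matrix(rnorm(45, sd = 0.4), ncol = 3))
  tr <- mkTraj(atomData(co), frames)
  m1 <- rmsdMap(tr, "all")@matrix
  moved <- frames
  moved[[3]] <- hingeflex:::rotateAboutAxis(moved[[3]], c(1, 2, 3), 50,
                                            c(1, 1, 1)) + 5
  m2 <- rmsdMap(mkTraj(atomData(co), moved), "all")@matrix
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("even frame sampling uses the documented stride formula", {
  expect_identical(evenFrameIndices(10, 10), 1:10)
  expect_identical(evenFrameIndices(9, 3), c(1L, 5L, 9L))
  expect_identical(evenFrameIndices(100, 5),
                   as.integer(round(1 + (0:4) * 99 / 4)))
  expect_error(evenFrameIndices(5, 6), "cannot sample")
})

test_that("k-medoids recovers planted blocks and is deterministic", {
  set.seed(21)
  blockMap <- function(sizes, within = 0.4, between = 10) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    m <- matrix(between + runif(n * n), n, n)
    for (c in seq_along(sizes)) {
      i <- which(lab == c)
      m[i, i] <- within * matrix(runif(length(i)^2), length(i))
    }
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    list(m = m, lab = lab)
  }
  bm <- blockMap(c(6, 6))
  got <- kmedoidCluster(bm$m, 2)
  expect_equal(length(unique(paste(got@labels, bm$lab))), 2)

  # exhaustive-medoid oracle on 12 frames: compare total cost
  best <- Inf
  for (i in 1:11) for (j in (i + 1):12) {
    cost <- sum(pmin(bm$m[, i], bm$m[, j]))
    if (cost < best) best <- cost
  }
  ourCost <- sum(bm$m[cbind(seq_len(12), got@medoids[got@labels])])
  expect_equal(ourCost, best, tolerance = 1e-9)

  expect_identical(kmedoidCluster(bm$m, 2)@labels, got@labels)

  # independent cross-check: PAM agrees on well-separated blocks
  pam <- cluster::pam(stats::as.dist(bm$m), 2, diss = TRUE)
  expect_equal(length(unique(paste(got@labels, pam$clustering))), 2)

  # k = n: every frame its own cluster, zero cost
  gotN <- kmedoidCluster(bm$m, 12)
  expect_identical(sort(gotN@medoids), 1:12)
  expect_error(kmedoidCluster(bm$m, 13), "k must lie")
})

test_that("representatives minimize the maximum within-cluster distance", {
  m <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3)
  expect_identical(clusterRepresentative(m, 1:3), 1L)
  expect_identical(clusterRepresentative(m, 7), 7L)
  set.seed(5)
  for (i in 1:25) {
    r <- matrix(runif(100), 10, 10)
    r <- (r + t(r)) / 2; diag(r) <- 0
    members <- sort(sample(10, sample(2:10, 1)))
    expect_identical(clusterRepresentative(r, members),
                     oracleRepresentative(r, members))
    # independence of member ordering
    expect_identical(clusterRepresentative(r, rev(members)),
                     oracleRepresentative(r, members))
  }
})
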