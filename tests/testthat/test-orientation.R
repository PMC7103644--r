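test_that("inertia tensor matches closed forms and the double-loop oracle", {
  # single mass at the COM: all relative positions vanish
  expect_equal(inertiaTensor(matrix(c(2, 3, 4), 1, 3), 5)$matrix,
               matrix(0, 3, 3))
  # two unit masses at (+-1, 0, 0)
  expect_equal(inertiaTensor(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, 1))$matrix,
               diag(c(0, 2, 2)))
  set.seed(5)
  for (i in 1:50) {
    M <- sample(3:100, 1)
    coords <- matrix(rnorm(3 * M, sd = 2), M, 3)
    masses <- runif(M, 0.5, 20)
    got <- inertiaTensor(coords, masses)
    ref <- bruteInertia(coords, masses)
    expect_lt(max(abs(got$matrix - ref)) / max(abs(ref)), 1e-12)
    expect_equal(got$center, colSums(coords * masses) / sum(masses))
    expect_equal(got$matrix, t(got$matrix))
    expect_true(all(eigen(got$matrix, symmetric = TRUE)$values > -1e-10))
  }
  expect_error(inertiaTensor(rbind(c(1, 0, 0), c(-1, 0, 0)), c(0, 0)),
               "total mass")
})

test_that("principal axes diagonalize the tensor with the declared conventions", {
  pa <- principalAxes(diag(c(3, 1, 2)))
  expect_equal(pa$moments, c(1, 2, 3))
  expect_equal(abs(pa$axes), diag(3)[, c(2, 3, 1)], tolerance = 1e-12)
  expect_true(all(diag(crossprod(diag(3), pa$axes))[1:2] >= 0))
  expect_equal(det(pa$axes), 1, tolerance = 1e-12)
  expect_false(pa$degenerate)
  expect_true(principalAxes(diag(c(1, 1, 1)))$degenerate)
  expect_error(principalAxes(matrix(1:9, 3, 3)), "symmetric")

  set.seed(8)
  for (i in 1:25) {
    R <- randomRotation()
    mom <- sort(runif(3, 1, 10))
    I <- R %*% diag(mom) %*% t(R)
    pa <- principalAxes(I)
    # axes equal R's columns up to the sign convention
    expect_equal(abs(colSums(pa$axes * R)), c(1, 1, 1), tolerance = 1e-8)
    expect_equal(pa$moments, mom, tolerance = 1e-8)
    # reconstruction U Lambda U^T = I
    rec <- pa$axes %*% diag(pa$moments) %*% t(pa$axes)
    expect_lt(norm(rec - I, "F") / norm(I, "F"), 1e-10)
    # sign continuity against a previous frame
    pa2 <- principalAxes(I, previous = pa$axes)
    expect_true(all(colSums(pa2$axes * pa$axes) >= 0))
  }
})

test_that("direction cosine matrix is the rotation between bases", {
  P <- diag(3)
  expect_equal(directionCosineMatrix(P), diag(3))
  R90 <- rotZ(90)
  expect_equal(directionCosineMatrix(R90), R90, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    P <- randomRotation()
    D <- directionCosineMatrix(P)
    expect_lt(max(abs(crossprod(D) - diag(3))), 1e-12)
    expect_equal(det(D), 1, tolerance = 1e-12)
    # rotating axes and reference together leaves the DCM unchanged
    Q <- randomRotation()
    expect_equal(directionCosineMatrix(Q %*% P, Q %*% diag(3)), D,
                 tolerance = 1e-10)
  }
  expect_error(directionCosineMatrix(matrix(1, 3, 3)), "orthonormal")
})

test_that("intrinsic-ZYX decomposition inverts composition away from lock", {
  tb <- taitBryanZYX(diag(3))
  expect_equal(c(tb$yaw, tb$pitch, tb$roll), c(0, 0, 0))
  expect_false(tb$gimbal)
  # pitch 0 when the long axis lies in the membrane plane (axes = reference)
  expect_equal(taitBryanZYX(directionCosineMatrix(diag(3)))$pitch, 0)
  set.seed(21)
  for (i in 1:500) {
    a <- runif(1, -179.9, 179.9); b <- runif(1, -85, 85)
    cc <- runif(1, -179.9, 179.9)
    tb <- taitBryanZYX(eulerZYX(a, b, cc))
    expect_equal(c(tb$yaw, tb$pitch, tb$roll), c(a, b, cc),
                 tolerance = 1e-9)
  }
  # gimbal lock: flagged, roll zeroed, still composition-consistent
  for (s in c(90, -90)) {
    R <- eulerZYX(35, s, 25)
    tb <- taitBryanZYX(R)
    expect_true(tb$gimbal)
    expect_equal(tb$roll, 0)
    expect_equal(tb$pitch, s)
    expect_lt(max(abs(eulerZYX(tb$yaw, tb$pitch, tb$roll) - R)), 1e-9)
  }
  expect_error(taitBryanZYX(matrix(1, 3, 3)), "orthonormal")
})

test_that("orientation series recovers programmed rigid-body schedules", {
  # static body: constant angles
  rb0 <- makeRigidBody(nParticles = 60,
                       schedule = pitchRampSchedule(0, 0, 5), seed = 2)
  os0 <- orientationSeries(rb0$trajectory, atomSelect(rb0$trajectory, "all"))
  expect_true(all(abs(angles(os0)$pitch) < 1e-9))
  expect_true(all(abs(angles(os0)$yaw) < 1e-9))

  # pitch ramp: per-frame recovery to numerical precision (noiseless)
  rb <- makeRigidBody(nParticles = 120,
                      schedule = pitchRampSchedule(0, 60, 80), seed = 3)
  os <- orientationSeries(rb$trajectory, atomSelect(rb$trajectory, "all"))
  expect_lt(max(abs(angles(os)$pitch - rb$truth$pitch)), 1e-6)
  # continuity: no frame-to-frame pitch jump above 90 degrees
  expect_lt(max(abs(diff(angles(os)$pitch))), 90)

  # both reference modes coincide when frame 0 is reference-aligned
  os2 <- orientationSeries(rb$trajectory, atomSelect(rb$trajectory, "all"),
                           referenceMode = "firstFrame")
  expect_equal(angles(os2)$pitch, angles(os)$pitch, tolerance = 1e-8)

  # global-rotation equivariance in firstFrame mode: rotating every frame
  # by one rotation leaves relative angles unchanged
  Q <- rotZ(40) %*% rotY(25)
  tr <- rb$trajectory
  for (f in seq_len(nFrames(tr)))
    tr@coords[, , f] <- frameCoords(tr, f) %*% t(Q)
  os3 <- orientationSeries(tr, atomSelect(tr, "all"),
                           referenceMode = "firstFrame")
  expect_equal(angles(os3)$pitch, angles(os2)$pitch, tolerance = 1e-6)
})

test_that("angle histograms are normalized, pooled frame-wise, order-invariant", {
  h <- angleHistogram(rep(0, 50), binWidth = 5, range = c(0, 90))
  expect_equal(h$mass[1], 1)
  expect_equal(sum(h$mass), 1)
  expect_equal(h$binLow[1], 0); expect_equal(h$binHigh[1], 5)

  set.seed(4)
  s1 <- runif(300, -40, 40); s2 <- runif(120, -40, 40)
  pooled <- angleHistogram(list(s1, s2), binWidth = 2)
  concat <- angleHistogram(c(s1, s2), binWidth = 2)
  expect_equal(pooled$mass, concat$mass)
  swapped <- angleHistogram(list(s2, s1), binWidth = 2)
  expect_equal(pooled$mass, swapped$mass)
  expect_equal(sum(pooled$count), 420)

  # uniform angles: flat within sampling noise
  set.seed(9)
  u <- angleHistogram(runif(20000, -90, 90), binWidth = 10)
  expect_true(all(abs(u$mass - 1 / nrow(u)) < 3 * sqrt(1 / nrow(u) / 20000)))
  expect_error(angleHistogram(numeric(0)), "no angle")
})

test_that("heat-map tables stack runs and resample mismatched grids", {
  mk <- function(p) {
    rb <- makeRigidBody(nParticles = 30,
                        schedule = pitchRampSchedule(p, p, 4), seed = 1)
    orientationSeries(rb$trajectory, atomSelect(rb$trajectory, "all"))
  }
  runs <- lapply(c(10, 20, 30), mk)
  tab <- angleHeatmapTable(runs)
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(unname(tab[, 1]), c(10, 20, 30), tolerance = 1e-6)
  expect_true(all(abs(tab - rowMeans(tab)) < 1e-6))

  one <- angleHeatmapTable(runs[1])
  expect_equal(dim(one), c(1L, 4L))
  expect_equal(unname(one[1, ]), angles(runs[[1]])$pitch)

  # different stride: nearest-frame resampling onto the first grid
  rbFast <- makeRigidBody(nParticles = 30,
                          schedule = pitchRampSchedule(0, 30, 7), seed = 1,
                          dt = 0.5)
  osF <- orientationSeries(rbFast$trajectory,
                           atomSelect(rbFast$trajectory, "all"))
  tab2 <- angleHeatmapTable(list(runs[[1]], osF))
  expect_equal(dim(tab2), c(2L, 4L))
  # nearest frames of the 0.5-ps series at t = 0,1,2,3 are frames 1,3,5,7
  expect_equal(unname(tab2[2, ]), angles(osF)$pitch[c(1, 3, 5, 7)])
})
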