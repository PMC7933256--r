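test_that("patient frame matches canonical axes for canonical landmarks", {
  s <- icosphere(2, radius = 32)
  sphere <- fitSphereIcp(s)
  fr <- buildPatientFrame(s, sphere, canonicalLandmarks(32))
  expect_equal(fr@superior, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr@posterior, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr@lateral, c(-1, 0, 0), tolerance = 1e-9)
})

test_that("patient frames are orthonormal and right-handed for random
           valid landmark sets", {
  set.seed(17)
  s <- icosphere(2, radius = 30)
  sphere <- fitSphereIcp(s)
  for (i in 1:20) {
    R <- randomRotation()
    lm <- applyToLandmarks(canonicalLandmarks(30), R)
    mesh <- transformMesh(s, R)
    fr <- buildPatientFrame(mesh, fitSphereIcp(mesh), lm)
    ax <- rbind(fr@superior, fr@posterior, fr@lateral)
    expect_lt(max(abs(ax %*% t(ax) - diag(3))), 1e-9)
    expect_equal(det(ax), 1, tolerance = 1e-9)
    ## equivariance: axes are the rotated canonical axes
    expect_equal(fr@superior, drop(R %*% c(0, 0, 1)), tolerance = 1e-9)
    expect_equal(fr@posterior, drop(R %*% c(0, 1, 0)), tolerance = 1e-9)
  }
})

test_that("degenerate landmark geometry raises errors", {
  s <- icosphere(2, radius = 32)
  sphere <- fitSphereIcp(s)
  lm <- canonicalLandmarks(32)
  bad <- LandmarkSet(lm@pvOstia, lm@laaOstium, sphereCenter(sphere))
  expect_error(buildPatientFrame(s, sphere, bad), "coincides")
  ## PV centroid along the superior axis: posterior direction undefined
  bad2 <- LandmarkSet(rbind(c(0.1, 0, 40), c(-0.1, 0, 40)),
                      lm@laaOstium, lm@inferiorReference)
  expect_error(buildPatientFrame(s, sphere, bad2), "parallel")
})

test_that("default bands label canonical directions as expected and
           partition the surface", {
  expect_equal(segmentOfAngles(0, 0), "roof")
  expect_equal(segmentOfAngles(170, 0), "inferior_posterior")
  expect_equal(segmentOfAngles(75, 0), "posterior")
  expect_equal(segmentOfAngles(75, 120), "septum")
  expect_equal(segmentOfAngles(75, -120), "lateral")
  expect_equal(segmentOfAngles(130, 135), "inferior_septum")
  expect_equal(segmentOfAngles(130, -135), "lateral")

  s <- icosphere(3, radius = 32)
  sphere <- fitSphereIcp(s)
  fr <- buildPatientFrame(s, sphere, canonicalLandmarks(32))
  field <- deviationField(s, sphere)
  lab <- partitionSurface(s, sphere, fr, field)
  counts <- table(segmentLabels(lab))
  expect_true(all(counts[segmentNames()] > 0))
  expect_equal(sum(counts[segmentNames()]), sum(includedMask(field)))

  expect_error(partitionSurface(s, sphere, fr, field,
                                bands = list(roofTheta = 120,
                                             inferiorTheta = 100,
                                             posteriorHalfWidth = 60,
                                             inferiorPosteriorHalfWidth = 90)),
               "band")
})

test_that("segmental deviation recovers a roof-band offset exactly when the
           sphere is held fixed", {
  s <- icosphere(3, radius = 32)
  fixedSphere <- new("FittedSphere", center = c(0, 0, 0), radius = 32,
                     iterations = 1L, converged = TRUE)
  fr <- buildPatientFrame(s, fixedSphere, canonicalLandmarks(32))
  ang <- frameAngles(fr, meshVertices(s))
  roofIdx <- segmentOfAngles(ang$theta, ang$phi) == "roof"
  v <- meshVertices(s)
  u <- v / sqrt(rowSums(v^2))
  v[roofIdx, ] <- u[roofIdx, ] * 35
  m <- SurfaceMesh(v, meshFaces(s))
  field <- deviationField(m, fixedSphere)
  lab <- partitionSurface(m, fixedSphere, fr, field)
  segD <- segmentalDeviation(field, lab)
  D <- setNames(segD$D, segD$segment)
  expect_equal(unname(D["roof"]), 3, tolerance = 1e-9)
  expect_lt(max(abs(D[setdiff(segmentNames(), "roof")])), 1e-9)

  ## all-zero case on the pristine sphere
  f0 <- deviationField(s, fixedSphere)
  D0 <- segmentalDeviation(f0, partitionSurface(s, fixedSphere, fr, f0))$D
  expect_lt(max(abs(D0)), 1e-12)
})

test_that("segment deviations combine to the whole-surface signed mean", {
  g <- generateLaMesh(syntheticSpec(seed = 31))
  sphere <- fitSphereIcp(g$mesh)
  field <- deviationField(g$mesh, sphere)
  fr <- buildPatientFrame(g$mesh, sphere, g$landmarks)
  lab <- partitionSurface(g$mesh, sphere, fr, field)
  segD <- segmentalDeviation(field, lab)
  combined <- sum(segD$D * segD$area) / sum(segD$area)
  inc <- includedMask(field)
  whole <- sum(field@weight[inc] * deviations(field)[inc]) /
    sum(field@weight[inc])
  expect_equal(combined, whole, tolerance = 1e-12)
})

test_that("labels and segment deviations are equivariant under rigid motion", {
  g <- generateLaMesh(syntheticSpec(seed = 33))
  sphere <- fitSphereIcp(g$mesh)
  field <- deviationField(g$mesh, sphere)
  fr <- buildPatientFrame(g$mesh, sphere, g$landmarks)
  lab1 <- segmentLabels(partitionSurface(g$mesh, sphere, fr, field))
  D1 <- segmentalDeviation(field,
                           partitionSurface(g$mesh, sphere, fr, field))$D

  set.seed(34)
  R <- randomRotation(); tr <- c(-15, 60, 4)
  mesh2 <- transformMesh(g$mesh, R, tr)
  lm2 <- applyToLandmarks(g$landmarks, R, tr)
  sphere2 <- fitSphereIcp(mesh2)
  field2 <- deviationField(mesh2, sphere2)
  fr2 <- buildPatientFrame(mesh2, sphere2, lm2)
  lab2 <- segmentLabels(partitionSurface(mesh2, sphere2, fr2, field2))
  D2 <- segmentalDeviation(field2,
                           partitionSurface(mesh2, sphere2, fr2, field2))$D
  expect_identical(as.character(lab1), as.character(lab2))
  expect_equal(D2, D1, tolerance = 1e-9)
})

test_that("the pipeline recovers injected per-segment amplitudes against
           fit-adjusted ground truth", {
  set.seed(35)
  for (k in 1:5) {
    a <- setNames(stats::runif(6, -4, 4), segmentNames())
    g <- generateLaMesh(syntheticSpec(amplitudes = a, noiseSd = 0.3,
                                      seed = 400 + k))
    m <- analyzeShape(g$mesh, g$landmarks)
    D <- unlist(m[paste0("D_", segmentNames())])
    truth <- g$truth$fitAdjustedD
    expect_true(all(abs(D - truth) <= pmax(0.3, 0.15 * abs(truth))),
                info = paste("seed", 400 + k))
  }
})
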