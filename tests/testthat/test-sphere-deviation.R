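test_that("algebraic fit recovers exact spheres and circumspheres", {
  ## regular tetrahedron inscribed in a known circumsphere
  ctr <- c(4, -7, 2); r <- 13
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  fit <- fitSphereAlgebraic(sweep(dirs * r, 2, ctr, "+"))
  expect_equal(sphereCenter(fit), ctr, tolerance = 1e-9)
  expect_equal(sphereRadius(fit), r, tolerance = 1e-9)

  set.seed(5)
  pts <- spherePoints(500, center = c(-20, 4, 9), radius = 27)
  fit2 <- fitSphereAlgebraic(pts)
  expect_equal(sphereCenter(fit2), c(-20, 4, 9), tolerance = 1e-9)
  expect_equal(sphereRadius(fit2), 27, tolerance = 1e-9)

  expect_error(fitSphereAlgebraic(cbind(stats::runif(10),
                                        stats::runif(10), 1)), "coplanar")
})

test_that("algebraic fit is locally optimal in the algebraic residual", {
  set.seed(6)
  pts <- spherePoints(300, radius = 20) + stats::rnorm(900, sd = 0.8)
  fit <- fitSphereAlgebraic(pts)
  algRes <- function(ctr, r) {
    sum((rowSums(sweep(pts, 2, ctr)^2) - r^2)^2)
  }
  best <- algRes(sphereCenter(fit), sphereRadius(fit))
  for (i in 1:100) {
    ctr2 <- sphereCenter(fit) + stats::rnorm(3, sd = 0.1)
    r2 <- sphereRadius(fit) + stats::rnorm(1, sd = 0.1)
    expect_gte(algRes(ctr2, r2), best)
  }
})

test_that("ICP fit recovers exact and noisy sphere parameters", {
  set.seed(8)
  s <- transformMesh(icosphere(3, radius = 24), randomRotation(),
                     c(10, 20, -5))
  fit <- fitSphereIcp(s)
  expect_true(fit@converged)
  expect_equal(sphereCenter(fit), c(10, 20, -5), tolerance = 24 * 1e-9)
  expect_equal(sphereRadius(fit), 24, tolerance = 24 * 1e-9)

  pts <- spherePoints(10000, center = c(3, -1, 2), radius = 30) +
    stats::rnorm(30000, sd = 0.5)
  fitn <- fitSphereIcp(pts)
  expect_lt(sqrt(sum((sphereCenter(fitn) - c(3, -1, 2))^2)), 0.05)
  expect_lt(abs(sphereRadius(fitn) - 30), 0.05)
})

test_that("ICP and algebraic fits coincide on zero-residual meshes and agree
           to second order on deformed atria", {
  set.seed(9)
  for (i in 1:10) {
    m <- transformMesh(icosphere(sample(2:3, 1), radius = stats::runif(1, 15, 45)),
                       randomRotation(), stats::rnorm(3, sd = 30))
    fi <- fitSphereIcp(m)
    fa <- fitSphereAlgebraic(meshVertices(m))
    expect_lt(sqrt(sum((sphereCenter(fi) - sphereCenter(fa))^2)),
              1e-6 * sphereRadius(fi))
    expect_lt(abs(sphereRadius(fi) - sphereRadius(fa)),
              1e-6 * sphereRadius(fi))
  }
  ## residual-bearing surfaces: the two estimators differ at second order
  ## in S/AR (documented estimator relationship), never more
  for (i in 1:5) {
    g <- generateLaMesh(syntheticSpec(seed = 30 + i))
    fi <- fitSphereIcp(g$mesh)
    fa <- fitSphereAlgebraic(meshVertices(g$mesh))
    S <- meanAbsDeviation(deviationField(g$mesh, fi))
    bound <- 3 * (S / sphereRadius(fi))^2 * sphereRadius(fi)
    expect_lt(abs(sphereRadius(fi) - sphereRadius(fa)), bound)
    expect_lt(sqrt(sum((sphereCenter(fi) - sphereCenter(fa))^2)), bound)
  }
})

test_that("deviation field is definitional and exclusion follows the mode", {
  s <- icosphere(3, radius = 32)
  sphere <- fitSphereIcp(s)
  field <- deviationField(s, sphere)
  expect_lt(max(abs(deviations(field))), 1e-9)
  expect_lt(meanAbsDeviation(field), 1e-9)
  expect_true(all(includedMask(field)))

  ## displace four chosen vertices to known radial offsets {+2, +11, -12, +9}
  v <- meshVertices(s); u <- v / sqrt(rowSums(v^2))
  idx <- c(10, 80, 200, 400)
  off <- c(2, 11, -12, 9)
  v[idx, ] <- u[idx, ] * (32 + off)
  m2 <- SurfaceMesh(v, meshFaces(s))
  fixedSphere <- new("FittedSphere", center = c(0, 0, 0), radius = 32,
                     iterations = 1L, converged = TRUE)
  fOut <- deviationField(m2, fixedSphere, exclusionMode = "outward")
  expect_equal(deviations(fOut)[idx], off, tolerance = 1e-9)
  expect_equal(unname(includedMask(fOut)[idx]), c(TRUE, FALSE, TRUE, TRUE))
  fAbs <- deviationField(m2, fixedSphere, exclusionMode = "absolute")
  expect_equal(unname(includedMask(fAbs)[idx]), c(TRUE, FALSE, FALSE, TRUE))

  tiny <- new("FittedSphere", center = c(0, 0, 0), radius = 1,
              iterations = 1L, converged = TRUE)
  expect_error(deviationField(m2, tiny, exclusionThreshold = 5),
               "all vertices excluded")
})

test_that("sphericity index follows LAS = 1 - S/AR", {
  mkField <- function(S) new("DeviationField", deviation = 0, included = TRUE,
                             weight = 1, S = S)
  sph <- function(r) new("FittedSphere", center = c(0, 0, 0), radius = r,
                         iterations = 1L, converged = TRUE)
  expect_equal(sphericity(mkField(0), sph(30))$LAS, 1)
  expect_equal(sphericity(mkField(30), sph(30))$LAS, 0)
  ## cohort-mean radius 32 mm and mean deviation 6 mm give LAS 0.8125
  expect_equal(sphericity(mkField(6), sph(32))$LAS, 0.8125)
})

test_that("AR, S scale with the mesh while LAS is invariant; rigid motion
           changes nothing", {
  g <- generateLaMesh(syntheticSpec(seed = 21))
  base <- analyzeShape(g$mesh, g$landmarks)
  k <- 1.75; R <- randomRotation(); tr <- c(40, -10, 25)
  mesh2 <- transformMesh(g$mesh, R, tr, k)
  lm2 <- applyToLandmarks(g$landmarks, R, tr, k)
  cfg <- atriaConfig(exclusionThreshold = 10 * k)  # threshold is in mm
  sc <- analyzeShape(mesh2, lm2, cfg)
  expect_equal(sc$AR, k * base$AR, tolerance = 1e-9)
  expect_equal(sc$S, k * base$S, tolerance = 1e-9)
  expect_equal(sc$LAS, base$LAS, tolerance = 1e-9)

  rm2 <- analyzeShape(transformMesh(g$mesh, R, tr),
                      applyToLandmarks(g$landmarks, R, tr))
  expect_equal(rm2$AR, base$AR, tolerance = 1e-9)
  expect_equal(rm2$S, base$S, tolerance = 1e-9)
  expect_equal(rm2$LAS, base$LAS, tolerance = 1e-9)
})

test_that("a uniform inflation is absorbed entirely by the refitted sphere", {
  ## exact identity for the unweighted fit: moving every vertex by +c along
  ## its ray from the fitted centre leaves the stationarity conditions
  ## unchanged up to the radius shift (area weights would change under the
  ## non-uniform stretch, perturbing the weighted fit at O(c d / R^2))
  g <- generateLaMesh(syntheticSpec(seed = 23, noiseSd = 0))
  v <- meshVertices(g$mesh)
  ones <- rep(1, nrow(v))
  sphere1 <- fitSphereIcp(g$mesh, weights = ones)
  d1 <- deviations(deviationField(g$mesh, sphere1, areaWeighted = FALSE))
  cc <- 4.5
  u <- sweep(v, 2, sphereCenter(sphere1))
  u <- u / sqrt(rowSums(u^2))
  inflated <- SurfaceMesh(v + cc * u, meshFaces(g$mesh))
  sphere2 <- fitSphereIcp(inflated, weights = ones)
  d2 <- deviations(deviationField(inflated, sphere2, areaWeighted = FALSE))
  expect_equal(sphereRadius(sphere2), sphereRadius(sphere1) + cc,
               tolerance = 1e-7)
  expect_equal(sphereCenter(sphere2), sphereCenter(sphere1),
               tolerance = 1e-7)
  expect_equal(d2, d1, tolerance = 1e-6)
})

test_that("S is monotone in the deformation amplitude for a fixed sphere", {
  base <- icosphere(3, radius = 32)
  u <- meshVertices(base) / 32
  set.seed(3)
  pattern <- stats::rnorm(nVertices(base), sd = 1)
  fixedSphere <- new("FittedSphere", center = c(0, 0, 0), radius = 32,
                     iterations = 1L, converged = TRUE)
  Svals <- vapply(seq(0, 3, by = 0.5), function(t) {
    m <- SurfaceMesh(u * (32 + t * pattern), meshFaces(base))
    meanAbsDeviation(deviationField(m, fixedSphere, exclusionThreshold = Inf))
  }, numeric(1))
  expect_true(all(diff(Svals) >= -1e-12))
})
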