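## Synthetic left-atrium generator with analytic ground truth.
##
## An atrium is emulated as an icosphere of base radius R carrying smooth
## per-segment radial bumps (cosine-squared angular falloff), optional
## outward pulmonary-vein / appendage stub protrusions (to exercise the
## 10 mm exclusion rule), and isotropic Gaussian surface noise. The
## generator emits consistent landmarks and a ground-truth record whose
## "fit-adjusted" segmental deviations are computed against an independent
## geometric sphere fit (quasi-Newton minimisation of the radial residual,
## a different algorithm from the pipeline's ICP), so recovery tests compare
## the pipeline with what a best-fit-sphere analysis can in principle
## recover: the fit absorbs the mean inflation into AR and first-moment
## deformation into the centre.

## canonical frame of the generator: superior +z, posterior +y
.canonicalFrame <- function(origin = c(0, 0, 0)) {
  new("PatientFrame", origin = as.numeric(origin),
      superior = c(0, 0, 1), posterior = c(0, 1, 0),
      lateral = c(-1, 0, 0))
}

## unit direction at polar angle theta and azimuth phi (degrees) in a frame;
## phi is positive toward the septal (anti-lateral) side, as in frameAngles()
.dirFromAngles <- function(frame, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  outer(cos(th), frame@superior) +
    outer(sin(th) * cos(ph), frame@posterior) -
    outer(sin(th) * sin(ph), frame@lateral)
}

## angular centres of the six segment bumps (theta, phi in degrees)
.segmentBumpCenters <- function() {
  m <- rbind(roof = c(10, 0), posterior = c(75, 0), septum = c(75, 120),
             inferior_septum = c(130, 135), inferior_posterior = c(130, 0),
             lateral = c(85, -120))
  m[segmentNames(), , drop = FALSE]
}

## PV ostia and LAA directions (theta, phi): PVs posterior, LAA anterolateral
.pvStubAngles <- function() rbind(c(60, 30), c(60, -30), c(95, 35), c(95, -35))
.laaStubAngles <- function() c(55, -135)

## smooth radial profile: cos^2(pi/2 * alpha/alpha0) inside alpha < alpha0
.bumpProfile <- function(alphaDeg, falloffDeg) {
  x <- alphaDeg / falloffDeg
  ifelse(x < 1, cos(pi * x / 2)^2, 0)
}

## angle (degrees) between unit rows of u and a single unit vector w
.angleToDeg <- function(u, w) {
  acos(pmin(pmax(drop(u %*% w), -1), 1)) * 180 / pi
}

#' Specification of one synthetic atrium
#'
#' Defaults emulate the study conditions the method targets: base radius
#' 32 mm (cohort mean best-fit radius), per-segment amplitudes matching the
#' cohort mean wall deviations, 0.3 mm surface noise, and a logistic model
#' tying per-segment low-voltage probability to deformation magnitude.
#'
#' @param baseRadius sphere radius, mm.
#' @param amplitudes named signed per-segment bump amplitudes, mm (order
#'   \code{segmentNames()}).
#' @param falloff angular falloff of each bump, degrees.
#' @param noiseSd isotropic radial surface noise SD, mm.
#' @param subdivision icosphere subdivision level (>= 2).
#' @param pvStubs pulmonary-vein stub protrusions exceeding the 10 mm
#'   exclusion threshold: TRUE for all four, or a count 0-4.
#' @param laaStub add an appendage stub protrusion.
#' @param stubHeight stub height, mm.
#' @param lvaBeta0,lvaBeta1 logistic intercept and slope (per mm of
#'   |amplitude|) of the low-voltage label model.
#' @param seed integer RNG seed; the whole patient is reproducible from it.
#' @return list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(baseRadius = 32,
                          amplitudes = c(roof = -0.9, posterior = -0.6,
                                         septum = -1.6, inferior_septum = 3.2,
                                         inferior_posterior = 0.8,
                                         lateral = 2.8),
                          falloff = 65, noiseSd = 0.3, subdivision = 3L,
                          pvStubs = FALSE, laaStub = FALSE, stubHeight = 15,
                          lvaBeta0 = -5, lvaBeta1 = 1.2, seed = 1L) {
  stopifnot(baseRadius > 0, subdivision >= 2L, noiseSd >= 0, falloff > 0,
            stubHeight >= 0)
  amplitudes <- amplitudes[segmentNames()]
  if (anyNA(amplitudes))
    stop("amplitudes must be named with all of segmentNames()")
  if (any(abs(amplitudes) >= baseRadius))
    stop("bump amplitudes must stay below the base radius ",
         "(self-intersecting surface)")
  structure(list(baseRadius = baseRadius, amplitudes = amplitudes,
                 falloff = falloff, noiseSd = noiseSd,
                 subdivision = as.integer(subdivision), pvStubs = pvStubs,
                 laaStub = laaStub, stubHeight = stubHeight,
                 lvaBeta0 = lvaBeta0, lvaBeta1 = lvaBeta1,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

## per-vertex bump field (mm): partition-of-unity blend of per-segment
## cosine kernels, so each segment deforms as a whole wall and equal
## amplitudes reduce exactly to uniform inflation (absorbed by the fit)
.bumpField <- function(u, amplitudes, falloff, frame = .canonicalFrame()) {
  centers <- .segmentBumpCenters()
  K <- vapply(seq_len(nrow(centers)), function(s) {
    w <- drop(.dirFromAngles(frame, centers[s, 1], centers[s, 2]))
    .bumpProfile(.angleToDeg(u, w), falloff)
  }, numeric(nrow(u)))
  K <- matrix(K, nrow = nrow(u))
  tot <- rowSums(K)
  ## directions outside every kernel (possible for narrow falloff) take the
  ## nearest segment centre
  bad <- tot < 1e-9
  if (any(bad)) {
    ctrDirs <- .dirFromAngles(frame, centers[, 1], centers[, 2])
    nearest <- max.col(u[bad, , drop = FALSE] %*% t(ctrDirs))
    K[cbind(which(bad), nearest)] <- 1
    tot[bad] <- 1
  }
  drop((K / tot) %*% as.numeric(amplitudes))
}

## stub field (mm): outward protrusions at the PV ostia / LAA directions
.stubField <- function(u, spec, frame = .canonicalFrame(), capDeg = 12) {
  g <- numeric(nrow(u))
  ang <- NULL
  nPv <- if (isTRUE(spec$pvStubs)) 4L else as.integer(spec$pvStubs)
  if (nPv > 0L) ang <- .pvStubAngles()[seq_len(min(nPv, 4L)), , drop = FALSE]
  if (spec$laaStub) ang <- rbind(ang, .laaStubAngles())
  if (is.null(ang)) return(g)
  for (s in seq_len(nrow(ang))) {
    w <- drop(.dirFromAngles(frame, ang[s, 1], ang[s, 2]))
    g <- g + spec$stubHeight * .bumpProfile(.angleToDeg(u, w), capDeg)
  }
  g
}

## independent geometric least-squares sphere fit by quasi-Newton descent
## (oracle for ground truth; deliberately not the package's ICP route)
.geometricSphereOracle <- function(v, w) {
  w <- w / sum(w)
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(v, 2L, p[1:3])^2))
    sum(w * (d - p[4])^2)
  }
  grad <- function(p) {
    dv <- sweep(v, 2L, p[1:3])
    d <- sqrt(rowSums(dv^2))
    res <- d - p[4]
    c(-2 * colSums(w * res * dv / d), -2 * sum(w * res))
  }
  ctr0 <- colMeans(v)
  r0 <- mean(sqrt(rowSums(sweep(v, 2L, ctr0)^2)))
  fit <- stats::optim(c(ctr0, r0), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(center = fit$par[1:3], radius = fit$par[4])
}

#' Generate one synthetic atrium with landmarks and ground truth
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{mesh} ([SurfaceMesh-class]), \code{landmarks}
#'   ([LandmarkSet-class]) and \code{truth}, a list holding the injected
#'   amplitudes, the fit-adjusted expected segmental deviations
#'   \code{fitAdjustedD} (named, mm), the true cutting plane, the
#'   low-voltage labels and their count, and the oracle sphere.
#' @export
generateLaMesh <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  frame <- .canonicalFrame()
  base <- icosphere(spec$subdivision, radius = 1, name = "synthetic_la")
  u <- meshVertices(base)
  R <- spec$baseRadius

  f <- .bumpField(u, spec$amplitudes, spec$falloff, frame)
  g <- .stubField(u, spec, frame)
  noise <- if (spec$noiseSd > 0) stats::rnorm(nrow(u), 0, spec$noiseSd)
    else numeric(nrow(u))
  radii <- R + f + g + noise
  if (min(radii) <= 0.1 * R)
    stop("generateLaMesh: deformation too large, surface self-intersects")
  mesh <- SurfaceMesh(u * radii, meshFaces(base), name = "synthetic_la",
                      mergeTol = 1e-12)

  ## landmarks at wall level (stub height excluded: an ostium sits at the
  ## wall, the stub rises from it)
  pvAng <- .pvStubAngles()
  pvDir <- .dirFromAngles(frame, pvAng[, 1], pvAng[, 2])
  pvR <- R + .bumpField(pvDir, spec$amplitudes, spec$falloff, frame)
  laaDir <- drop(.dirFromAngles(frame, .laaStubAngles()[1],
                                .laaStubAngles()[2]))
  laaR <- R + .bumpField(matrix(laaDir, 1L), spec$amplitudes, spec$falloff,
                         frame)
  landmarks <- LandmarkSet(pvOstia = pvDir * pvR,
                           laaOstium = laaDir * laaR,
                           inferiorReference = c(0, 0, -(R + 15)))

  ## ground truth on the noiseless, stub-free deformed surface
  vTrue <- u * (R + f)
  wTrue <- vertexAreas(SurfaceMesh(vTrue, meshFaces(base), mergeTol = 1e-12))
  oracle <- .geometricSphereOracle(vTrue, wTrue)
  resid <- sqrt(rowSums(sweep(vTrue, 2L, oracle$center)^2)) - oracle$radius
  ## label the true surface in the patient frame an ideal noiseless analysis
  ## would build: same landmark construction, anchored on the oracle sphere
  oracleSphere <- new("FittedSphere", center = oracle$center,
                      radius = oracle$radius, iterations = 1L,
                      converged = TRUE)
  meshTrue <- SurfaceMesh(vTrue, meshFaces(base), mergeTol = 1e-12)
  frameTrue <- suppressWarnings(
    buildPatientFrame(meshTrue, oracleSphere, landmarks))
  ang <- frameAngles(frameTrue, vTrue)
  segs <- segmentOfAngles(ang$theta, ang$phi)
  fitD <- vapply(segmentNames(), function(s) {
    idx <- segs == s
    sum(wTrue[idx] * resid[idx]) / sum(wTrue[idx])
  }, numeric(1))

  cutPoint <- 0.5 * (colMeans(pvDir * pvR) + laaDir * laaR)
  truth <- list(
    amplitudes = spec$amplitudes,
    fitAdjustedD = fitD,
    oracleSphere = oracle,
    cuttingPlane = Plane(c(0, -1, 0), cutPoint),
    lvaLabels = generateLvaLabels(spec$amplitudes, spec$lvaBeta0,
                                  spec$lvaBeta1),
    seed = spec$seed)
  truth$lvaSegmentCount <- sum(truth$lvaLabels)
  list(mesh = mesh, landmarks = landmarks, truth = truth)
}

#' Per-segment low-voltage labels from deformation amplitudes
#'
#' label_s ~ Bernoulli(plogis(beta0 + beta1 * |a_s|)), independent across
#' segments given the amplitudes.
#'
#' @param amplitudes 6 signed amplitudes, mm.
#' @param beta0,beta1 logistic intercept and slope; \code{beta1 = Inf} gives
#'   the indicator of |a_s| > 0.
#' @param seed optional seed; omitted, the current RNG stream is used.
#' @return named integer vector of 0/1 labels.
#' @export
generateLvaLabels <- function(amplitudes, beta0, beta1, seed = NULL) {
  stopifnot(length(amplitudes) == 6L)
  if (!is.null(seed)) set.seed(seed)
  eta <- beta0 + beta1 * abs(as.numeric(amplitudes))
  eta[is.nan(eta)] <- beta0  # Inf * 0 at zero amplitude
  p <- stats::plogis(eta)
  lab <- stats::rbinom(6L, 1L, p)
  names(lab) <- segmentNames()
  lab
}

#' Cohort-level sampling distribution of synthetic atria
#'
#' Per-patient base radius and signed segment amplitudes are drawn from
#' normal distributions whose defaults match the study cohort summary
#' (radius 32 +/- 4 mm; segment deviations e.g. roof -0.9 +/- 3 mm).
#'
#' @param radiusMean,radiusSd base radius distribution, mm.
#' @param amplitudeMean,amplitudeSd named per-segment amplitude means and
#'   SDs, mm.
#' @param amplitudeCor equicorrelation of the segment amplitudes within a
#'   patient via a shared global-remodelling factor; 0 (independent walls)
#'   by default, available for sensitivity analyses since diffuse
#'   remodelling plausibly couples walls.
#' @param noiseSd surface noise SD, mm.
#' @param subdivision icosphere subdivision level.
#' @param lvaBeta0,lvaBeta1 low-voltage label model coefficients.
#' @return list of class \code{"cohortDistribution"}.
#' @export
cohortDistribution <- function(radiusMean = 32, radiusSd = 4,
                               amplitudeMean = c(roof = -0.9,
                                                 posterior = -0.6,
                                                 septum = -1.6,
                                                 inferior_septum = 3.2,
                                                 inferior_posterior = 0.8,
                                                 lateral = 2.8),
                               amplitudeSd = c(roof = 3, posterior = 2,
                                               septum = 2,
                                               inferior_septum = 3,
                                               inferior_posterior = 2,
                                               lateral = 3),
                               amplitudeCor = 0,
                               noiseSd = 0.3, subdivision = 3L,
                               lvaBeta0 = -5, lvaBeta1 = 1.2) {
  amplitudeMean <- amplitudeMean[segmentNames()]
  amplitudeSd <- amplitudeSd[segmentNames()]
  stopifnot(!anyNA(amplitudeMean), !anyNA(amplitudeSd), radiusMean > 0,
            radiusSd >= 0, all(amplitudeSd >= 0),
            amplitudeCor >= 0, amplitudeCor < 1)
  structure(list(radiusMean = radiusMean, radiusSd = radiusSd,
                 amplitudeMean = amplitudeMean, amplitudeSd = amplitudeSd,
                 amplitudeCor = amplitudeCor,
                 noiseSd = noiseSd, subdivision = as.integer(subdivision),
                 lvaBeta0 = lvaBeta0, lvaBeta1 = lvaBeta1),
            class = "cohortDistribution")
}

## deterministic per-patient child seed: adding patients never perturbs
## earlier ones (counter-based splitting below 2^31)
.childSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) * 7919 + i * 104729) %% 2147483629)
}

## draw a 6 x n matrix of per-patient segment amplitudes with a shared
## global-remodelling factor (equicorrelation amplitudeCor across segments)
.drawAmplitudes <- function(n, dist) {
  rho <- dist$amplitudeCor
  z <- stats::rnorm(n)                       # shared factor per patient
  eps <- matrix(stats::rnorm(6L * n), 6L)    # segment-specific parts
  std <- sqrt(rho) * matrix(z, 6L, n, byrow = TRUE) + sqrt(1 - rho) * eps
  A <- dist$amplitudeMean + dist$amplitudeSd * std
  rownames(A) <- segmentNames()
  A
}

#' Generate a synthetic cohort of atria
#'
#' Draws per-patient base radii and segment amplitudes from \code{dist},
#' builds each mesh, and (optionally) writes the standard cohort directory
#' layout \code{patient_XXX/\{mesh.ply, landmarks.json, lva_labels.csv,
#' truth.json\}} plus a root \code{manifest.csv}.
#'
#' @param n number of patients (>= 2); 24 matches the study cohort size.
#' @param seed master seed; each patient derives a child seed from it.
#' @param dist a [cohortDistribution()].
#' @param dir optional output directory; kept in memory when NULL.
#' @param pvStubs,laaStub forwarded to each patient's [syntheticSpec()].
#' @return invisible list of per-patient lists (as [generateLaMesh()]),
#'   with attribute \code{"manifest"} (data.frame).
#' @export
generateCohort <- function(n = 24L, seed = 1L, dist = cohortDistribution(),
                           dir = NULL, pvStubs = FALSE, laaStub = FALSE) {
  stopifnot(n >= 2L, inherits(dist, "cohortDistribution"))
  patients <- vector("list", n)
  ids <- sprintf("patient_%03d", seq_len(n))
  for (i in seq_len(n)) {
    s <- .childSeed(seed, i)
    set.seed(s)
    R <- max(dist$radiusMean / 2,
             stats::rnorm(1, dist$radiusMean, dist$radiusSd))
    a <- .drawAmplitudes(1L, dist)[, 1L]
    names(a) <- segmentNames()
    a <- pmax(pmin(a, 0.5 * R), -0.5 * R)
    spec <- syntheticSpec(baseRadius = R, amplitudes = a,
                          noiseSd = dist$noiseSd,
                          subdivision = dist$subdivision,
                          pvStubs = pvStubs, laaStub = laaStub,
                          lvaBeta0 = dist$lvaBeta0, lvaBeta1 = dist$lvaBeta1,
                          seed = .childSeed(s, 1L))
    patients[[i]] <- generateLaMesh(spec)
    patients[[i]]$id <- ids[i]
  }
  manifest <- data.frame(
    patient = ids,
    baseRadius = vapply(patients, function(p)
      p$truth$oracleSphere$radius, numeric(1)),
    lvaSegmentCount = vapply(patients, function(p)
      p$truth$lvaSegmentCount, numeric(1)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      pdir <- file.path(dir, ids[i])
      dir.create(pdir, showWarnings = FALSE)
      p <- patients[[i]]
      writeMesh(p$mesh, file.path(pdir, "mesh.ply"))
      writeLandmarks(p$landmarks, file.path(pdir, "landmarks.json"))
      utils::write.csv(data.frame(segment = segmentNames(),
                                  lva = as.integer(p$truth$lvaLabels)),
                       file.path(pdir, "lva_labels.csv"), row.names = FALSE)
      jsonlite::write_json(list(
        amplitudes = as.list(p$truth$amplitudes),
        fitAdjustedD = as.list(p$truth$fitAdjustedD),
        lvaSegmentCount = p$truth$lvaSegmentCount,
        seed = p$truth$seed), file.path(pdir, "truth.json"),
        auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(patients, "manifest") <- manifest
  invisible(patients)
}

## ---------------------------------------------------------------------------
## Metric-level cohort sampler (linearised) for statistical calibration
## ---------------------------------------------------------------------------

## response operator of the deviation analysis on a reference icosphere:
## column s holds the per-vertex residual field of a unit bump in segment s
## after first-order absorption of the best-fit sphere (radius takes the
## area-weighted mean, the centre takes 3x the first direction moment)
.metricOperator <- local({
  cache <- NULL
  function(subdivision = 3L, falloff = 40) {
    key <- paste(subdivision, falloff)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$val)
    frame <- .canonicalFrame()
    base <- icosphere(subdivision, radius = 1)
    u <- meshVertices(base)
    w <- vertexAreas(base); w <- w / sum(w)
    B <- vapply(seq_len(6L), function(s) {
      a <- numeric(6L); names(a) <- segmentNames(); a[s] <- 1
      .bumpField(u, a, falloff, frame)
    }, numeric(nrow(u)))
    Q <- B
    for (s in 1:6) {
      m0 <- sum(w * B[, s])
      m1 <- colSums(w * B[, s] * u) * 3
      Q[, s] <- B[, s] - m0 - drop(u %*% m1)
    }
    ang <- frameAngles(frame, u)
    segs <- segmentOfAngles(ang$theta, ang$phi)
    M <- t(vapply(segmentNames(), function(sg) {
      idx <- segs == sg
      colSums(w[idx] * Q[idx, , drop = FALSE]) / sum(w[idx])
    }, numeric(6)))
    meanGain <- vapply(1:6, function(s) sum(w * B[, s]), numeric(1))
    val <- list(u = u, w = w, Q = Q, M = M, meanGain = meanGain,
                segs = segs)
    cache <<- list(key = key, val = val)
    val
  }
})

#' Fast metric-level synthetic cohort table (no meshes)
#'
#' Draws per-patient amplitudes from \code{dist} and maps them to shape
#' metrics through the linearised response of the deviation analysis
#' (bump field minus first-order best-fit-sphere absorption), adding a small
#' segmental measurement noise. Intended for statistical calibration
#' studies (type-I error, power) where thousands of cohorts are needed and
#' running full mesh pipelines would add nothing: the mapping from
#' amplitudes to D is the analytically expected pipeline response.
#'
#' @param n patients per cohort.
#' @param seed master seed.
#' @param dist a [cohortDistribution()]; set \code{lvaBeta1 = 0} for null
#'   cohorts.
#' @param measurementSd SD of additive segmental measurement noise, mm.
#' @return A CohortTable data.frame (one row per patient) with columns
#'   patient, LAV, LA_A, LA_P, ASI, AR, S, LAS, D_<segment>,
#'   lva_<segment>, lva_segment_count.
#' @export
generateCohortTable <- function(n = 24L, seed = 1L,
                                dist = cohortDistribution(),
                                measurementSd = 0.05) {
  stopifnot(n >= 2L, inherits(dist, "cohortDistribution"))
  op <- .metricOperator(dist$subdivision, 65)
  set.seed(as.integer(seed %% 2147483629))
  R <- pmax(dist$radiusMean / 2,
            stats::rnorm(n, dist$radiusMean, dist$radiusSd))
  A <- .drawAmplitudes(n, dist)  # 6 x n, column = patient
  resid <- op$Q %*% A                       # vertex x patient residual field
  S <- colSums(op$w * abs(resid))
  D <- op$M %*% A + matrix(stats::rnorm(6L * n, 0, measurementSd), 6L)
  AR <- R + drop(crossprod(A, op$meanGain))
  LAS <- 1 - S / AR
  ## direction-space split along the canonical anterior/posterior axis;
  ## adequate at metric level (exact for a plane through the centre)
  anterior <- op$u[, 2] < 0
  rad3 <- (matrix(R, nrow(op$u), n, byrow = TRUE) +
             (op$Q %*% A))^3
  VA <- colSums(op$w[anterior] * rad3[anterior, , drop = FALSE]) / 3
  VT <- colSums(op$w * rad3) / 3
  LAV <- VT * 4 * pi / 1000                 # w sums to 1 over 4*pi steradian
  ASI <- VA / VT
  labels <- vapply(seq_len(n), function(i)
    generateLvaLabels(A[, i], dist$lvaBeta0, dist$lvaBeta1), numeric(6))
  tab <- data.frame(patient = sprintf("patient_%03d", seq_len(n)),
                    LAV = LAV, LA_A = LAV * ASI, LA_P = LAV * (1 - ASI),
                    ASI = ASI, AR = AR, S = S, LAS = LAS)
  Dt <- t(D); colnames(Dt) <- paste0("D_", segmentNames())
  Lt <- t(labels); colnames(Lt) <- paste0("lva_", segmentNames())
  tab <- cbind(tab, as.data.frame(Dt), as.data.frame(Lt))
  tab$lva_segment_count <- rowSums(Lt)
  tab
}
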