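## Patient-aligned anatomical frame and the six-segment surface partition
## (roof, posterior, septum, inferior septum, inferior posterior, lateral).
## The frame is built from landmarks the method presupposes: the superior
## axis points from the inferior reference (e.g. mitral annulus centre)
## toward the sphere centre; the posterior axis toward the pulmonary veins;
## the lateral axis completes the right-handed frame and is checked against
## the appendage, which sits anterolateral.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (near-zero) direction vector")
  v / n
}

#' Build the patient anatomical frame from landmarks
#'
#' @param mesh the [SurfaceMesh-class] (used only for sanity checks).
#' @param sphere the fitted [FittedSphere-class]; its centre is the frame
#'   origin.
#' @param landmarks a [LandmarkSet-class].
#' @return A [PatientFrame-class]. The lateral axis is flipped (with a
#'   warning, recording mirrored anatomy) if the LA appendage would
#'   otherwise get a negative lateral coordinate.
#' @export
buildPatientFrame <- function(mesh, sphere, landmarks) {
  ctr <- sphere@center
  zv <- ctr - landmarks@inferiorReference
  if (sqrt(sum(zv^2)) < 1e-9)
    stop("buildPatientFrame: inferior reference coincides with sphere centre")
  zhat <- .unit(zv)
  pv <- pvCentroid(landmarks) - ctr
  pperp <- pv - sum(pv * zhat) * zhat
  if (sqrt(sum(pperp^2)) < 1e-9)
    stop("buildPatientFrame: PV direction parallel to superior axis")
  phat <- .unit(pperp)
  lhat <- .crossVec(zhat, phat)
  laa <- landmarks@laaOstium - ctr
  if (sum(laa * phat) >= 0)
    warning("buildPatientFrame: LAA ostium not on the anterior side of the ",
            "PV axis; check landmarks", call. = FALSE)
  if (sum(laa * lhat) < 0) {
    warning("buildPatientFrame: mirrored anatomy; lateral axis flipped ",
            "to keep the LAA lateral coordinate positive", call. = FALSE)
    lhat <- -lhat
  }
  new("PatientFrame", origin = ctr, superior = zhat, posterior = phat,
      lateral = lhat)
}

#' Polar/azimuthal coordinates of directions in a patient frame
#'
#' @param frame a [PatientFrame-class].
#' @param points n x 3 matrix of points (mm).
#' @return data.frame with \code{theta} (polar angle from the superior axis,
#'   degrees, 0..180) and \code{phi} (azimuth from the posterior axis about
#'   the superior axis, positive toward the septal/anti-lateral side,
#'   degrees, -180..180).
#' @export
frameAngles <- function(frame, points) {
  d <- sweep(as.matrix(points), 2L, frame@origin)
  r <- sqrt(rowSums(d^2))
  zc <- drop(d %*% frame@superior) / r
  theta <- acos(pmin(pmax(zc, -1), 1)) * 180 / pi
  pc <- drop(d %*% frame@posterior)
  lc <- drop(d %*% frame@lateral)
  ## septal side = +phi = anti-lateral: measure the angle toward -lateral
  phi <- atan2(-lc, pc) * 180 / pi
  data.frame(theta = theta, phi = phi)
}

#' Default angular band configuration of the six-segment partition
#'
#' The partition is defined on the unit sphere of directions about the
#' fitted-sphere centre: polar bands split roof / mid / inferior, azimuthal
#' sectors split posterior, septal and lateral walls. All boundaries are
#' plain config values (degrees) so segments can be re-mapped without code
#' changes.
#'
#' @return list with \code{roofTheta} (default 45), \code{inferiorTheta}
#'   (105), \code{posteriorHalfWidth} (60, mid band) and
#'   \code{inferiorPosteriorHalfWidth} (90, inferior band).
#' @export
defaultSegmentBands <- function() {
  list(roofTheta = 45, inferiorTheta = 105,
       posteriorHalfWidth = 60, inferiorPosteriorHalfWidth = 90)
}

.checkBands <- function(b) {
  ok <- is.list(b) &&
    all(c("roofTheta", "inferiorTheta", "posteriorHalfWidth",
          "inferiorPosteriorHalfWidth") %in% names(b)) &&
    b$roofTheta > 0 && b$roofTheta < b$inferiorTheta &&
    b$inferiorTheta < 180 &&
    b$posteriorHalfWidth > 0 && b$posteriorHalfWidth < 180 &&
    b$inferiorPosteriorHalfWidth > 0 && b$inferiorPosteriorHalfWidth < 180
  if (!ok) stop("invalid segment band configuration: bands must cover the ",
                "sphere without overlap (0 < roofTheta < inferiorTheta < 180,",
                " half-widths in (0, 180))")
  invisible(b)
}

#' Label segment membership of directions given as (theta, phi) angles
#'
#' @param theta,phi angles in degrees as returned by [frameAngles()].
#' @param bands band configuration, see [defaultSegmentBands()].
#' @return character vector of segment names.
#' @export
segmentOfAngles <- function(theta, phi, bands = defaultSegmentBands()) {
  .checkBands(bands)
  lab <- character(length(theta))
  roof <- theta < bands$roofTheta
  inf <- theta >= bands$inferiorTheta
  mid <- !roof & !inf
  lab[roof] <- "roof"
  lab[mid & abs(phi) < bands$posteriorHalfWidth] <- "posterior"
  lab[mid & phi >= bands$posteriorHalfWidth] <- "septum"
  lab[mid & phi <= -bands$posteriorHalfWidth] <- "lateral"
  lab[inf & abs(phi) < bands$inferiorPosteriorHalfWidth] <- "inferior_posterior"
  lab[inf & phi >= bands$inferiorPosteriorHalfWidth] <- "inferior_septum"
  lab[inf & phi <= -bands$inferiorPosteriorHalfWidth] <- "lateral"
  lab
}

#' Partition the LA surface into the six anatomical segments
#'
#' Every vertex included by the deviation field receives exactly one
#' segment label from its direction about the sphere centre; excluded
#' vertices keep the label \code{"excluded"}.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param sphere the fitted [FittedSphere-class].
#' @param frame a [PatientFrame-class].
#' @param field optional [DeviationField-class]; its mask defines
#'   exclusions. Without it all vertices are included.
#' @param bands band configuration, see [defaultSegmentBands()].
#' @return A [SegmentLabeling-class].
#' @export
partitionSurface <- function(mesh, sphere, frame, field = NULL,
                             bands = defaultSegmentBands()) {
  ang <- frameAngles(frame, mesh@vertices)
  lab <- segmentOfAngles(ang$theta, ang$phi, bands)
  if (!is.null(field)) {
    stopifnot(length(field@included) == nrow(mesh@vertices))
    lab[!field@included] <- "excluded"
  }
  new("SegmentLabeling",
      labels = factor(lab, levels = c(segmentNames(), "excluded")))
}

#' Segmental mean wall deviation D
#'
#' D of a segment is the area-weighted mean of the signed deviations d_i
#' over the segment's included vertices (signed: inward remodelling gives
#' negative D). A segment with zero included area yields NA with a warning.
#'
#' @param field a [DeviationField-class].
#' @param labeling a [SegmentLabeling-class] on the same mesh.
#' @return data.frame with columns \code{segment}, \code{D} (mm),
#'   \code{area} (included area, mm^2) and \code{nVertices}.
#' @export
segmentalDeviation <- function(field, labeling) {
  stopifnot(length(field@deviation) == length(labeling@labels))
  segs <- segmentNames()
  D <- area <- nv <- numeric(length(segs))
  for (k in seq_along(segs)) {
    idx <- labeling@labels == segs[k] & field@included
    nv[k] <- sum(idx)
    if (nv[k] == 0L) {
      warning("segmentalDeviation: segment '", segs[k],
              "' has no included vertices; D recorded as NA", call. = FALSE)
      D[k] <- NA_real_; area[k] <- 0
    } else {
      w <- field@weight[idx]
      area[k] <- sum(w)
      D[k] <- sum(w * field@deviation[idx]) / area[k]
    }
  }
  data.frame(segment = segs, D = D, area = area, nVertices = as.integer(nv))
}
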