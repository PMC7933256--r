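## Anterior/posterior volume split and the asymmetry index ASI = LA-A/LAV.
## The cutting plane is parallel to the posterior wall (total-least-squares
## plane of the posterior segment) and passes between the PV ostia and the
## LA appendage ostium; its normal points anteriorly (toward the LAA), so
## the positive-side clip volume is the anterior part LA-A.

#' Total-least-squares plane of the posterior wall
#'
#' @param mesh a [SurfaceMesh-class].
#' @param labeling a [SegmentLabeling-class] of the mesh.
#' @param landmarks optional [LandmarkSet-class]; when given, the normal is
#'   oriented toward the LAA ostium (anterior); otherwise toward the mesh
#'   vertex centroid, which lies anterior to the posterior wall.
#' @return A [Plane-class] with anteriorly oriented normal.
#' @export
posteriorPlane <- function(mesh, labeling, landmarks = NULL) {
  idx <- labeling@labels == "posterior"
  if (!any(idx))
    stop("posteriorPlane: posterior segment is empty")
  hint <- if (is.null(landmarks)) colMeans(mesh@vertices)
    else landmarks@laaOstium
  fitPlane(mesh@vertices[idx, , drop = FALSE], hint = hint)
}

#' Anterior/posterior cutting plane between the PV ostia and the LAA
#'
#' Keeps the posterior plane's normal and places the plane at a point
#' interpolated between the PV-ostia centroid and the LAA ostium
#' (\code{offset} = 0 at the PV centroid, 1 at the LAA; default 0.5, the
#' midpoint). The normal is flipped if needed so the LAA lies on the
#' positive (anterior) side.
#'
#' @param posterior the posterior-wall [Plane-class].
#' @param landmarks a [LandmarkSet-class].
#' @param offset interpolation scalar in [0, 1].
#' @return A [Plane-class].
#' @export
cuttingPlane <- function(posterior, landmarks, offset = 0.5) {
  stopifnot(offset >= 0, offset <= 1)
  pvc <- pvCentroid(landmarks)
  pt <- (1 - offset) * pvc + offset * landmarks@laaOstium
  n <- posterior@normal
  if (sum(n * (landmarks@laaOstium - pt)) < 0) n <- -n
  Plane(n, pt)
}

#' Asymmetry index from the cutting plane
#'
#' Splits the closed mesh volume into the anterior part LA-A (positive side
#' of the plane) and the posterior part LA-P and reports ASI = LA-A / LAV.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param plane the cutting [Plane-class] (normal pointing anteriorly).
#' @return list with \code{LAV}, \code{LA_A}, \code{LA_P} (mL), \code{ASI}
#'   (fraction in [0, 1]) and \code{plane}.
#' @export
asymmetryIndex <- function(mesh, plane) {
  parts <- clipVolumesByPlane(mesh, plane)
  lav <- sum(parts)
  list(LAV = lav, LA_A = unname(parts["positive"]),
       LA_P = unname(parts["negative"]),
       ASI = unname(parts["positive"]) / lav, plane = plane)
}
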