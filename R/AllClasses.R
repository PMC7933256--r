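#' @import methods
NULL

#' Canonical names of the six left-atrial wall segments
#'
#' Order is fixed throughout the package: roof, posterior, septum,
#' inferior septum, inferior posterior, lateral.
#'
#' @return Character vector of length 6.
#' @export
segmentNames <- function() {
  c("roof", "posterior", "septum",
    "inferior_septum", "inferior_posterior", "lateral")
}

## ---------------------------------------------------------------------------
## SurfaceMesh
## ---------------------------------------------------------------------------

#' SurfaceMesh: a triangulated surface in millimetre coordinates
#'
#' Central container for all geometry. Vertices are an n x 3 numeric matrix
#' (mm); faces an m x 3 integer matrix of 1-based vertex indices. The
#' \code{closed} slot records whether every edge is shared by exactly two
#' consistently oriented faces; volume operations refuse open meshes.
#'
#' @slot vertices numeric matrix, n x 3, coordinates in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot name identifier string.
#' @slot closed logical flag set at validation time.
#'
#' @seealso [SurfaceMesh()], [meshVolume()], [readMesh()]
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 name = "character", closed = "logical"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
    if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
    if (anyNA(v)) return("vertex coordinates contain NA")
    if (nrow(f) > 0L) {
      idx <- as.vector(f)
      if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(v)))
        return("face indices out of range")
      if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
        return("degenerate face (repeated vertex index)")
    }
    TRUE
  })

#' Construct and validate a SurfaceMesh
#'
#' Duplicate vertices closer than \code{mergeTol} mm are merged (STL writers
#' duplicate vertices per facet), zero-area faces are dropped, and, when the
#' mesh is closed, face winding is flipped once if the signed volume is
#' negative so that normals point outward. A non-watertight mesh is accepted
#' with a warning; volume operations on it raise an error later.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param name identifier string.
#' @param mergeTol vertex merge tolerance in mm.
#' @return A validated [SurfaceMesh-class] object.
#' @export
SurfaceMesh <- function(vertices, faces, name = "mesh", mergeTol = 1e-9) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")

  m <- .mergeVertices(vertices, faces, tol = mergeTol)
  vertices <- m$vertices; faces <- m$faces
  ## drop degenerate faces (repeated index or numerically zero area)
  if (nrow(faces) > 0L) {
    rep_idx <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    faces <- faces[!rep_idx, , drop = FALSE]
    a <- .faceAreas(vertices, faces)
    faces <- faces[a > 1e-14, , drop = FALSE]
  }
  closed <- .isEdgeClosed(faces)
  obj <- new("SurfaceMesh", vertices = vertices, faces = faces,
             name = as.character(name)[1L], closed = closed)
  if (closed && .signedVolumeMm3(vertices, faces) < 0) {
    obj@faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  if (!closed)
    warning("mesh '", obj@name, "' is not watertight; volume operations ",
            "will refuse it", call. = FALSE)
  obj
}

#' @describeIn SurfaceMesh-class vertex coordinate matrix (mm)
#' @param x,object a SurfaceMesh
#' @export
meshVertices <- function(x) x@vertices

#' @describeIn SurfaceMesh-class face index matrix
#' @export
meshFaces <- function(x) x@faces

#' @describeIn SurfaceMesh-class number of vertices
#' @export
nVertices <- function(x) nrow(x@vertices)

#' @describeIn SurfaceMesh-class number of faces
#' @export
nFaces <- function(x) nrow(x@faces)

#' @describeIn SurfaceMesh-class TRUE if every edge is shared by exactly two
#'   consistently oriented faces
#' @export
isClosed <- function(x) x@closed

#' @export
setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh '%s': %d vertices, %d faces, %s\n",
              object@name, nrow(object@vertices), nrow(object@faces),
              if (object@closed) "closed" else "open"))
})

## ---------------------------------------------------------------------------
## Plane
## ---------------------------------------------------------------------------

#' Plane: an oriented plane in 3-space
#'
#' @slot normal unit normal vector (length 3).
#' @slot point a point on the plane, mm.
#' @export
setClass("Plane",
  representation(normal = "numeric", point = "numeric"),
  validity = function(object) {
    if (length(object@normal) != 3L || length(object@point) != 3L)
      return("normal and point must have length 3")
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-12)
      return("normal must have unit length")
    TRUE
  })

#' Construct a Plane (the normal is normalised)
#' @param normal normal vector (any nonzero length).
#' @param point a point on the plane (mm).
#' @return A [Plane-class] object.
#' @export
Plane <- function(normal, point) {
  normal <- as.numeric(normal); point <- as.numeric(point)
  nl <- sqrt(sum(normal^2))
  if (!is.finite(nl) || nl < 1e-300) stop("plane normal must be nonzero")
  new("Plane", normal = normal / nl, point = point)
}

#' @export
setMethod("show", "Plane", function(object) {
  cat(sprintf("Plane: normal (%.4f, %.4f, %.4f) through (%.2f, %.2f, %.2f) mm\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@point[1], object@point[2], object@point[3]))
})

#' Signed distances of points from a plane
#' @param plane a [Plane-class].
#' @param points n x 3 matrix or length-3 vector.
#' @return numeric vector of signed distances (positive on the normal side).
#' @export
planeDistance <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  drop(points %*% plane@normal) - sum(plane@normal * plane@point)
}

## ---------------------------------------------------------------------------
## FittedSphere
## ---------------------------------------------------------------------------

#' FittedSphere: patient-specific best-fit sphere
#'
#' Holds the centre and the average radius AR (mm) together with iteration
#' diagnostics of the ICP fit (an algebraic fit reports 1 iteration).
#'
#' @slot center sphere centre, mm.
#' @slot radius average radius AR, mm; positive.
#' @slot iterations iterations used.
#' @slot converged TRUE if the last centre shift and radius change were both
#'   below tolerance.
#' @export
setClass("FittedSphere",
  representation(center = "numeric", radius = "numeric",
                 iterations = "integer", converged = "logical"),
  validity = function(object) {
    if (length(object@center) != 3L) return("center must have length 3")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0) return("radius must be a positive scalar")
    TRUE
  })

#' @describeIn FittedSphere-class sphere centre (mm)
#' @param x a FittedSphere
#' @export
sphereCenter <- function(x) x@center

#' @describeIn FittedSphere-class average radius AR (mm)
#' @export
sphereRadius <- function(x) x@radius

#' @export
setMethod("show", "FittedSphere", function(object) {
  cat(sprintf(
    "FittedSphere: center (%.3f, %.3f, %.3f) mm, AR %.3f mm (%d iter, %s)\n",
    object@center[1], object@center[2], object@center[3], object@radius,
    object@iterations,
    if (object@converged) "converged" else "NOT converged"))
})

## ---------------------------------------------------------------------------
## DeviationField
## ---------------------------------------------------------------------------

#' DeviationField: per-vertex signed radial deviation from the fitted sphere
#'
#' For vertex i, \code{deviation[i] = |v_i - center| - AR}; positive values
#' are outward (convex), negative inward (concave). Vertices beyond the
#' exclusion threshold (pulmonary veins, appendage) carry \code{included =
#' FALSE} and no weight in any summary. \code{S} is the (area-weighted) mean
#' of |d_i| over included vertices.
#'
#' @slot deviation signed deviations, mm.
#' @slot included inclusion mask.
#' @slot weight per-vertex area weight, mm^2 (all 1 when unweighted).
#' @slot S mean absolute deviation over included vertices, mm.
#' @export
setClass("DeviationField",
  representation(deviation = "numeric", included = "logical",
                 weight = "numeric", S = "numeric"),
  validity = function(object) {
    n <- length(object@deviation)
    if (length(object@included) != n || length(object@weight) != n)
      return("deviation, included and weight must have equal length")
    if (length(object@S) != 1L || object@S < 0)
      return("S must be a nonnegative scalar")
    TRUE
  })

#' @describeIn DeviationField-class signed per-vertex deviations (mm)
#' @param x a DeviationField
#' @export
deviations <- function(x) x@deviation

#' @describeIn DeviationField-class logical inclusion mask
#' @export
includedMask <- function(x) x@included

#' @describeIn DeviationField-class mean absolute deviation S (mm)
#' @export
meanAbsDeviation <- function(x) x@S

#' @export
setMethod("show", "DeviationField", function(object) {
  cat(sprintf(
    "DeviationField: %d vertices (%d included), S = %.4f mm, range [%.2f, %.2f] mm\n",
    length(object@deviation), sum(object@included), object@S,
    min(object@deviation), max(object@deviation)))
})

## ---------------------------------------------------------------------------
## LandmarkSet
## ---------------------------------------------------------------------------

#' LandmarkSet: anatomical landmarks anchoring the patient frame
#'
#' @slot pvOstia 2-4 x 3 matrix of pulmonary-vein ostia centroids (mm).
#' @slot laaOstium LA appendage ostium centroid (mm).
#' @slot inferiorReference inferior reference point, e.g. mitral annulus
#'   centre (mm).
#' @export
setClass("LandmarkSet",
  representation(pvOstia = "matrix", laaOstium = "numeric",
                 inferiorReference = "numeric"),
  validity = function(object) {
    if (ncol(object@pvOstia) != 3L || nrow(object@pvOstia) < 2L ||
        nrow(object@pvOstia) > 4L)
      return("pvOstia must be a 2-4 x 3 matrix")
    if (length(object@laaOstium) != 3L ||
        length(object@inferiorReference) != 3L)
      return("laaOstium and inferiorReference must have length 3")
    pvc <- colMeans(object@pvOstia)
    if (sqrt(sum((pvc - object@laaOstium)^2)) < 1e-9 ||
        sqrt(sum((pvc - object@inferiorReference)^2)) < 1e-9 ||
        sqrt(sum((object@laaOstium - object@inferiorReference)^2)) < 1e-9)
      return("pv centroid, laaOstium and inferiorReference must be distinct")
    TRUE
  })

#' Construct a LandmarkSet
#' @param pvOstia 2-4 x 3 matrix of PV ostia centroids (mm).
#' @param laaOstium length-3 LAA ostium centroid (mm).
#' @param inferiorReference length-3 inferior reference point (mm).
#' @return A [LandmarkSet-class].
#' @export
LandmarkSet <- function(pvOstia, laaOstium, inferiorReference) {
  pvOstia <- as.matrix(pvOstia)
  storage.mode(pvOstia) <- "double"
  new("LandmarkSet", pvOstia = pvOstia,
      laaOstium = as.numeric(laaOstium),
      inferiorReference = as.numeric(inferiorReference))
}

#' @describeIn LandmarkSet-class centroid of the PV ostia (mm)
#' @param x a LandmarkSet
#' @export
pvCentroid <- function(x) colMeans(x@pvOstia)

#' @export
setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d PV ostia, LAA ostium, inferior reference\n",
              nrow(object@pvOstia)))
})

## ---------------------------------------------------------------------------
## PatientFrame
## ---------------------------------------------------------------------------

#' PatientFrame: orthonormal anatomical axes anchored at the sphere centre
#'
#' superior points from the inferior reference toward the sphere centre,
#' posterior toward the pulmonary veins, lateral completes the frame
#' (lateral = superior x posterior), oriented so the LA appendage sits
#' anterolateral (negative posterior, positive lateral coordinate).
#'
#' @slot origin frame origin (sphere centre), mm.
#' @slot superior,posterior,lateral unit axes.
#' @export
setClass("PatientFrame",
  representation(origin = "numeric", superior = "numeric",
                 posterior = "numeric", lateral = "numeric"),
  validity = function(object) {
    ax <- rbind(object@superior, object@posterior, object@lateral)
    if (any(abs(rowSums(ax^2) - 1) > 1e-9))
      return("axes must be unit vectors")
    g <- abs(ax %*% t(ax) - diag(3))
    if (max(g) > 1e-9) return("axes must be orthonormal")
    TRUE
  })

#' @export
setMethod("show", "PatientFrame", function(object) {
  cat(sprintf(
    "PatientFrame at (%.2f, %.2f, %.2f) mm (det %+.0f)\n",
    object@origin[1], object@origin[2], object@origin[3],
    det(rbind(object@superior, object@posterior, object@lateral))))
})

## ---------------------------------------------------------------------------
## SegmentLabeling
## ---------------------------------------------------------------------------

#' SegmentLabeling: per-vertex anatomical segment labels
#'
#' Factor with levels \code{segmentNames()} plus \code{"excluded"}; every
#' included vertex carries exactly one segment label.
#'
#' @slot labels factor of length nVertices(mesh).
#' @export
setClass("SegmentLabeling",
  representation(labels = "factor"),
  validity = function(object) {
    expect <- c(segmentNames(), "excluded")
    if (!identical(levels(object@labels), expect))
      return("labels must be a factor with levels segmentNames() + 'excluded'")
    if (anyNA(object@labels)) return("labels contain NA")
    TRUE
  })

#' @describeIn SegmentLabeling-class per-vertex label factor
#' @param x a SegmentLabeling
#' @export
segmentLabels <- function(x) x@labels

#' @export
setMethod("show", "SegmentLabeling", function(object) {
  tb <- table(object@labels)
  cat("SegmentLabeling:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
})
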