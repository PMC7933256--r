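## Patient-specific best-fit sphere.
##
## fitSphereIcp() is the pipeline fit: it alternates (a) radial
## closest-point correspondence between the surface vertices and the current
## sphere (the closest sphere point to vertex v is c + r*(v-c)/|v-c|) with
## (b) the closed-form similarity update (rotation is a gauge freedom for a
## sphere, so the effective parameters are the centre and the scale/radius).
## Its fixed point is the geometric least-squares sphere, i.e. it minimises
## the area-weighted sum of squared radial residuals (|v-c| - r)^2.
##
## fitSphereAlgebraic() is the independent direct oracle: expanding
## |p - c|^2 = r^2 gives a system linear in (c, |c|^2 - r^2), solved in one
## least-squares step. On zero-residual data both estimators recover the
## exact sphere; with residuals they agree to first order and differ only at
## second order in the residual-to-radius ratio.

#' Best-fit sphere by iterative closest point registration
#'
#' @param mesh a [SurfaceMesh-class] (or an n x 3 vertex matrix).
#' @param init optional list with elements \code{center} and \code{radius};
#'   defaults to the area-weighted vertex centroid and the mean
#'   centre-to-vertex distance.
#' @param tolerance relative convergence tolerance: iteration stops when the
#'   centre shift and the radius change both fall below
#'   \code{tolerance * radius} (a dimensionless criterion, so the fit is
#'   exactly equivariant under uniform scaling).
#' @param maxIterations iteration cap; non-convergence returns the last
#'   iterate with \code{converged = FALSE} and a warning.
#' @param weights optional per-vertex weights; defaults to barycentric
#'   vertex areas when a mesh is given (mesh-resolution invariance), equal
#'   weights for a bare point matrix.
#' @return A [FittedSphere-class].
#' @export
fitSphereIcp <- function(mesh, init = NULL, tolerance = 1e-9,
                         maxIterations = 100L, weights = NULL) {
  if (is(mesh, "SurfaceMesh")) {
    v <- mesh@vertices
    if (is.null(weights)) weights <- vertexAreas(mesh)
  } else {
    v <- as.matrix(mesh)
  }
  if (is.null(weights)) weights <- rep(1, nrow(v))
  .assertNonCoplanar(v, "fitSphereIcp")
  w <- weights / sum(weights)

  wmean <- function(m) drop(crossprod(m, w))
  if (is.null(init)) {
    ctr <- wmean(v)
    rad <- sum(w * sqrt(rowSums(sweep(v, 2L, ctr)^2)))
  } else {
    ctr <- as.numeric(init$center); rad <- as.numeric(init$radius)
  }

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIterations)) {
    dv <- sweep(v, 2L, ctr)
    d <- sqrt(rowSums(dv^2))
    if (any(d < 1e-12))
      stop("fitSphereIcp: a vertex coincides with the sphere centre")
    u <- dv / d                      # correspondence directions
    vbar <- wmean(v); ubar <- wmean(u)
    denom <- 1 - sum(ubar^2)
    if (denom < 1e-12)
      stop("fitSphereIcp: degenerate correspondence (coplanar directions)")
    radNew <- (sum(w * rowSums(u * v)) - sum(ubar * vbar)) / denom
    ctrNew <- vbar - radNew * ubar
    shift <- sqrt(sum((ctrNew - ctr)^2)); dr <- abs(radNew - rad)
    ctr <- ctrNew; rad <- radNew
    if (shift < tolerance * abs(rad) && dr < tolerance * abs(rad)) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("fitSphereIcp: no convergence in ", maxIterations, " iterations",
            call. = FALSE)
  if (rad <= 0) stop("fitSphereIcp: non-positive radius")
  new("FittedSphere", center = ctr, radius = rad,
      iterations = iter, converged = converged)
}

#' Direct algebraic least-squares sphere fit (independent oracle)
#'
#' Solves the linear system obtained by expanding |p - c|^2 = r^2 in the
#' unknowns (c, |c|^2 - r^2).
#'
#' @param points n x 3 matrix, n >= 4, non-coplanar.
#' @return A [FittedSphere-class] (1 iteration, converged).
#' @export
fitSphereAlgebraic <- function(points) {
  p <- as.matrix(points)
  .assertNonCoplanar(p, "fitSphereAlgebraic")
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  x <- qr.coef(qr(A), b)
  ctr <- x[1:3]
  r2 <- x[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("fitSphereAlgebraic: degenerate solution")
  new("FittedSphere", center = as.numeric(ctr), radius = sqrt(r2),
      iterations = 1L, converged = TRUE)
}

.assertNonCoplanar <- function(p, fun) {
  if (nrow(p) < 4L) stop(fun, ": need at least 4 points")
  x <- sweep(p, 2L, colMeans(p))
  sv <- svd(x, nu = 0L)
  if (sv$d[3] < 1e-9 * max(sv$d[1], 1e-300))
    stop(fun, ": points are coplanar or degenerate")
  invisible(TRUE)
}
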