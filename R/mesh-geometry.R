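## Core mesh geometry: validation helpers, volumes, plane clipping,
## total-least-squares planes, vertex areas, icosphere construction.
## Units: coordinates mm, areas mm^2; volumes are converted mm^3 -> mL in
## .mm3ToMl(), the single place the conversion happens.

.mm3ToMl <- function(v) v / 1000

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.faceAreas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- .rowCross(e1, e2)
  0.5 * sqrt(rowSums(cr^2))
}

## merge vertices closer than tol (grid snap keying); remap faces
.mergeVertices <- function(vertices, faces, tol = 1e-9) {
  if (nrow(vertices) == 0L) return(list(vertices = vertices, faces = faces))
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3L))
}

## TRUE iff every undirected edge is used exactly twice, once per direction
.isEdgeClosed <- function(faces) {
  if (nrow(faces) == 0L) return(FALSE)
  from <- as.vector(t(faces))
  to <- as.vector(t(faces[, c(2L, 3L, 1L), drop = FALSE]))
  dir_key <- paste(from, to)
  if (anyDuplicated(dir_key)) return(FALSE)
  und_key <- paste(pmin(from, to), pmax(from, to))
  all(table(und_key) == 2L)
}

.signedVolumeMm3 <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(0)
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  sum(rowSums(a * .rowCross(b, cc))) / 6
}

.requireClosed <- function(mesh, op) {
  if (!isClosed(mesh))
    stop(op, ": mesh '", mesh@name, "' is not watertight", call. = FALSE)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem (signed tetrahedron) volume. The constructor has
#' already oriented faces outward, so the result is positive.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @return Volume in mL.
#' @examples
#' cube <- unitCubeMesh()
#' meshVolume(cube)  # 0.001 mL = 1 mm^3
#' @export
meshVolume <- function(mesh) {
  .requireClosed(mesh, "meshVolume")
  .mm3ToMl(abs(.signedVolumeMm3(mesh@vertices, mesh@faces)))
}

#' Volumes of the two parts of a closed mesh split by a plane
#'
#' Each triangle is clipped against the plane (Sutherland-Hodgman) and the
#' clipped pieces are fanned into tetrahedra against an apex placed on the
#' plane itself. Because the cross-section cap is coplanar with the apex its
#' tetrahedra have zero volume, so the split is exact for any section
#' geometry and the two parts sum to the total volume by construction.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param plane a [Plane-class].
#' @return Named numeric: \code{positive} (normal side) and \code{negative}
#'   volumes, mL.
#' @export
clipVolumesByPlane <- function(mesh, plane) {
  .requireClosed(mesh, "clipVolumesByPlane")
  v <- mesh@vertices; f <- mesh@faces
  q <- plane@point
  s <- planeDistance(plane, v)
  sv <- matrix(s[f], ncol = 3L)
  onPos <- sv >= 0
  npos <- rowSums(onPos)

  ## faces fully on one side: tetrahedra against apex q
  vq <- sweep(v, 2L, q)
  tet_all <- rowSums(vq[f[, 1], , drop = FALSE] *
                       .rowCross(vq[f[, 2], , drop = FALSE],
                                 vq[f[, 3], , drop = FALSE])) / 6
  vol_pos <- sum(tet_all[npos == 3L])
  total <- sum(tet_all)

  cross_idx <- which(npos == 1L | npos == 2L)
  for (k in cross_idx) {
    tri <- v[f[k, ], , drop = FALSE]
    d <- sv[k, ]
    poly <- .clipTriToHalfspace(tri, d)
    if (is.null(poly) || nrow(poly) < 3L) next
    p0 <- poly[1L, ] - q
    for (j in 2:(nrow(poly) - 1L)) {
      vol_pos <- vol_pos + sum(p0 * .crossVec(poly[j, ] - q, poly[j + 1L, ] - q)) / 6
    }
  }
  pos <- .mm3ToMl(vol_pos)
  tot <- .mm3ToMl(total)
  c(positive = pos, negative = tot - pos)
}

.crossVec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## clip one triangle (3 x 3 matrix, rows = vertices) to the halfspace d >= 0
.clipTriToHalfspace <- function(tri, d) {
  out <- matrix(0, 0L, 3L)
  for (i in 1:3) {
    j <- if (i == 3L) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di >= 0) out <- rbind(out, tri[i, ])
    if ((di > 0 && dj < 0) || (di < 0 && dj > 0)) {
      t <- di / (di - dj)
      out <- rbind(out, tri[i, ] + t * (tri[j, ] - tri[i, ]))
    }
  }
  out
}

#' Total-least-squares plane through a point cloud
#'
#' The normal is the principal direction of smallest variance of the centred
#' points; the plane passes through their centroid. The normal sign is
#' chosen to point toward \code{hint} when given.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @param hint optional length-3 point; the normal is oriented toward it.
#' @return A [Plane-class].
#' @export
fitPlane <- function(points, hint = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("fitPlane: need at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x, nu = 0L)
  if (sv$d[1] < 1e-300 || sv$d[2] < 1e-9 * sv$d[1])
    stop("fitPlane: points are collinear or degenerate")
  n <- sv$v[, 3L]
  if (!is.null(hint) && sum(n * (as.numeric(hint) - ctr)) < 0) n <- -n
  Plane(n, ctr)
}

#' Barycentric (lumped) per-vertex area weights
#'
#' Each face contributes one third of its area to each of its vertices.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return numeric vector of vertex areas, mm^2.
#' @export
vertexAreas <- function(mesh) {
  a <- .faceAreas(mesh@vertices, mesh@faces)
  w <- numeric(nrow(mesh@vertices))
  for (col in 1:3) {
    acc <- tapply(rep(a / 3, 1L), mesh@faces[, col], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + as.numeric(acc)
  }
  w
}

#' Geodesic icosphere
#'
#' Icosahedron subdivided \code{subdivisions} times with vertices projected
#' onto the sphere. Subdivision preserves the icosahedron's central
#' symmetry, so any plane through the centre splits the enclosed volume
#' exactly in half.
#'
#' @param subdivisions nonnegative integer; 3 gives 642 vertices.
#' @param radius sphere radius, mm.
#' @param center length-3 centre, mm.
#' @param name mesh name.
#' @return A closed [SurfaceMesh-class].
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0),
                      name = "icosphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e1 <- ekey(f[, 1], f[, 2]); e2 <- ekey(f[, 2], f[, 3])
    e3 <- ekey(f[, 3], f[, 1])
    allk <- unique(c(e1, e2, e3))
    ab <- do.call(rbind, strsplit(allk, " "))
    ai <- as.integer(ab[, 1]); bi <- as.integer(ab[, 2])
    mid <- (v[ai, , drop = FALSE] + v[bi, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    m1 <- nv + match(e1, allk); m2 <- nv + match(e2, allk)
    m3 <- nv + match(e3, allk)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  v <- sweep(v * radius, 2L, as.numeric(center), "+")
  SurfaceMesh(v, f, name = name, mergeTol = 1e-12)
}

#' Axis-aligned unit cube mesh (1 mm side), for tests and examples
#' @return A closed [SurfaceMesh-class] with 8 vertices and 12 faces.
#' @export
unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  ## 12 triangles, outward orientation fixed by the constructor
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  SurfaceMesh(v, f, name = "unit_cube")
}

#' Apply a rigid motion (and optional uniform scale) to a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector, mm.
#' @param scale positive uniform scale factor.
#' @return Transformed [SurfaceMesh-class].
#' @export
transformMesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                          scale = 1) {
  v <- (scale * mesh@vertices) %*% t(rotation)
  v <- sweep(v, 2L, as.numeric(translation), "+")
  new("SurfaceMesh", vertices = v, faces = mesh@faces, name = mesh@name,
      closed = mesh@closed)
}

## random rotation matrix (uniform via QR of gaussian), used in tests
.randomRotation <- function() {
  m <- matrix(stats::rnorm(9), 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
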