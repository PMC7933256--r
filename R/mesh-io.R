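## Readers/writers for the three mesh formats segmentation tools export:
## STL (ASCII and binary), PLY (ASCII) and OBJ. Coordinates are taken as mm.
## Readers feed the SurfaceMesh() constructor, which merges the per-facet
## duplicate vertices STL produces and validates/orients the result.

.meshFormatFromPath <- function(path, format = NULL) {
  if (!is.null(format)) return(tolower(format))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "obj"))
    stop("cannot infer mesh format from extension '", ext,
         "'; pass format = 'stl'/'ply'/'obj'")
  ext
}

#' Read a triangulated surface mesh
#'
#' Supports ASCII/binary STL, ASCII PLY and OBJ. The result is validated:
#' duplicate vertices are merged, degenerate faces dropped, outward
#' orientation restored for closed meshes; a non-watertight mesh is returned
#' with a warning.
#'
#' @param path file path.
#' @param format optional "stl", "ply" or "obj"; inferred from the
#'   extension otherwise.
#' @return A [SurfaceMesh-class].
#' @export
readMesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- .meshFormatFromPath(path, format)
  parsed <- switch(format,
    stl = .readSTL(path),
    ply = .readPLY(path),
    obj = .readOBJ(path),
    stop("unsupported mesh format: ", format))
  SurfaceMesh(parsed$vertices, parsed$faces,
              name = tools::file_path_sans_ext(basename(path)))
}

#' Write a triangulated surface mesh
#'
#' ASCII output in all three formats. For PLY an optional per-vertex scalar
#' (e.g. the signed deviation field) is stored as a float property
#' \code{quality}, readable by standard mesh viewers for colour mapping.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path.
#' @param format optional "stl", "ply" or "obj".
#' @param scalar optional numeric per-vertex scalar (PLY only).
#' @return \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, format = NULL, scalar = NULL) {
  format <- .meshFormatFromPath(path, format)
  switch(format,
    stl = .writeSTL(mesh, path),
    ply = .writePLY(mesh, path, scalar),
    obj = .writeOBJ(mesh, path),
    stop("unsupported mesh format: ", format))
  invisible(path)
}

## ---------------------------------------------------------------------- STL

.readSTL <- function(path) {
  if (.isBinarySTL(path)) .readSTLBinary(path) else .readSTLAscii(path)
}

.isBinarySTL <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = min(84, sz))
  if (length(head) < 84) return(FALSE)
  ntri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
  ## binary iff the triangle count matches the file size exactly
  isTRUE(sz == 84 + 50 * as.numeric(ntri))
}

.readSTLAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3 in ", path)
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE)
  v <- matrix(nums, ncol = 3L, byrow = TRUE)
  ntri <- nrow(v) / 3L
  f <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

.readSTLBinary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", size = 4L, endian = "little")
  v <- matrix(0, 3L * ntri, 3L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    v[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  f <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

.writeSTL <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- .rowCross(e1, e2)
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", mesh@name), con)
  for (k in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[f[k, ], 1], v[f[k, ], 2], v[f[k, ], 3]),
      "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh@name), con)
}

## ---------------------------------------------------------------------- PLY

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header without end_header in ", path)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header missing vertex/face counts")
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY body in ", path)
  vnum <- scan(text = body[seq_len(nv)], quiet = TRUE)
  ncolv <- length(vnum) / nv
  v <- matrix(vnum, nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(frows, function(r) {
    r <- as.numeric(r)
    if (r[1] != 3) stop("PLY face with ", r[1], " vertices; only triangles")
    r[2:4] + 1
  }, numeric(3)))
  list(vertices = v, faces = f)
}

.writePLY <- function(mesh, path, scalar = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment atriamorph surface '%s'", mesh@name),
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nrow(v))
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalar)) {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3],
                       scalar), con)
  }
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

## ---------------------------------------------------------------------- OBJ

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ file without vertices or faces: ", path)
  v <- matrix(scan(text = sub("^v\\s+", "", vlines), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- t(vapply(strsplit(sub("^f\\s+", "", flines), "\\s+"), function(r) {
    if (length(r) != 3L) stop("OBJ face with ", length(r),
                              " vertices; only triangles are supported")
    as.numeric(sub("/.*$", "", r))
  }, numeric(3)))
  list(vertices = v, faces = f)
}

.writeOBJ <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# atriamorph surface '%s'", mesh@name), con)
  v <- mesh@vertices; f <- mesh@faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
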