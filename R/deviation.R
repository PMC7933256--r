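## Signed radial deviation mapping and the sphericity index LAS = 1 - S/AR.
## The deviation of vertex i is measured along the ray from the sphere
## centre through the vertex: d_i = |v_i - center| - AR. Positive values are
## outward/convex, negative inward/concave. Vertices protruding beyond the
## exclusion threshold (pulmonary veins and appendage stumps) are masked and
## carry no weight in S or in any segmental statistic.

#' Signed radial deviation field from the fitted sphere
#'
#' @param mesh a [SurfaceMesh-class].
#' @param sphere a [FittedSphere-class].
#' @param exclusionThreshold exclusion distance in mm (default 10).
#' @param exclusionMode "outward" excludes vertices with d_i >
#'   \code{exclusionThreshold} (protrusions such as PVs and LAA point
#'   outward); "absolute" excludes |d_i| > threshold.
#' @param areaWeighted use barycentric vertex areas as weights for S
#'   (mesh-resolution invariance); unweighted otherwise.
#' @return A [DeviationField-class].
#' @export
deviationField <- function(mesh, sphere, exclusionThreshold = 10,
                           exclusionMode = c("outward", "absolute"),
                           areaWeighted = TRUE) {
  exclusionMode <- match.arg(exclusionMode)
  d <- sqrt(rowSums(sweep(mesh@vertices, 2L, sphere@center)^2)) -
    sphere@radius
  included <- if (exclusionMode == "outward") d <= exclusionThreshold
    else abs(d) <= exclusionThreshold
  if (!any(included))
    stop("deviationField: all vertices excluded at threshold ",
         exclusionThreshold, " mm")
  w <- if (areaWeighted) vertexAreas(mesh) else rep(1, nrow(mesh@vertices))
  wi <- w * included
  S <- sum(wi * abs(d)) / sum(wi)
  new("DeviationField", deviation = as.numeric(d), included = included,
      weight = w, S = S)
}

#' Sphericity from the deviation field: LAS = 1 - S/AR
#'
#' @param field a [DeviationField-class] derived from \code{sphere}.
#' @param sphere the [FittedSphere-class] the field was computed against.
#' @return list with \code{AR} (mm), \code{S} (mm), \code{LAS} (fraction;
#'   multiply by 100 for percent).
#' @export
sphericity <- function(field, sphere) {
  list(AR = sphere@radius, S = field@S,
       LAS = 1 - field@S / sphere@radius)
}

#' Export the deviation field for visual QC
#'
#' PLY output stores d_i as the per-vertex \code{quality} property (colour
#' map: red convex, blue concave); CSV output has columns vertex, deviation
#' and included.
#'
#' @param field a [DeviationField-class].
#' @param mesh the matching [SurfaceMesh-class].
#' @param path output path ending in .ply or .csv.
#' @return \code{path}, invisibly.
#' @export
exportDeviation <- function(field, mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    writeMesh(mesh, path, scalar = field@deviation)
  } else if (ext == "csv") {
    utils::write.csv(data.frame(vertex = seq_along(field@deviation),
                                deviation = field@deviation,
                                included = field@included),
                     path, row.names = FALSE)
  } else stop("exportDeviation: unsupported extension '", ext, "'")
  invisible(path)
}
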