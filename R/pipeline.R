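## Per-patient and cohort orchestration. runPatient() sequences the whole
## shape analysis (read -> validate -> sphere fit -> deviation + exclusion
## -> frame -> partition -> segmental D -> posterior plane -> cutting plane
## -> volumes/ASI) and returns a single metrics record with provenance.
## runCohort() maps it over a cohort directory with crash isolation, joins
## low-voltage labels and runs the association battery.

#' Landmark file I/O (JSON)
#'
#' Schema: \code{\{"pv_ostia": [[x,y,z],...], "laa_ostium": [x,y,z],
#' "inferior_reference": [x,y,z]\}}, coordinates in mm.
#'
#' @param path JSON file path.
#' @return A [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmarks file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pv_ostia", "laa_ostium", "inferior_reference")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("landmarks file ", path, " missing fields: ",
         paste(miss, collapse = ", "))
  LandmarkSet(pvOstia = matrix(as.numeric(t(j$pv_ostia)), ncol = 3L,
                               byrow = TRUE),
              laaOstium = as.numeric(j$laa_ostium),
              inferiorReference = as.numeric(j$inferior_reference))
}

#' @rdname readLandmarks
#' @param landmarks a [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(pv_ostia = unname(apply(landmarks@pvOstia, 1L, as.numeric,
                                 simplify = FALSE)),
         laa_ostium = as.numeric(landmarks@laaOstium),
         inferior_reference = as.numeric(landmarks@inferiorReference)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Analysis configuration with study defaults
#'
#' One document covering every tunable of the pipeline. Defaults reproduce
#' the method's stated choices: 10 mm outward exclusion, area-weighted S,
#' no refit after exclusion, the default segment bands, cutting plane at
#' the PV-LAA midpoint, equal-variance Student contrast, no multiplicity
#' correction.
#'
#' @param ... overrides of the default fields.
#' @return list of class \code{"atriaConfig"}.
#' @export
atriaConfig <- function(...) {
  cfg <- list(
    exclusionThreshold = 10, exclusionMode = "outward",
    areaWeighted = TRUE, refitPasses = 0L,
    sphereTolerance = 1e-9, sphereMaxIterations = 100L,
    bands = defaultSegmentBands(), planeOffset = 0.5,
    welch = FALSE, bhCorrect = FALSE, alpha = 0.05)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$refitPasses < 0L || cfg$refitPasses > 5L)
    stop("refitPasses must be in 0..5")
  structure(cfg, class = "atriaConfig")
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, patient, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s | stage %s] %s", patient, name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full shape analysis for one patient
#'
#' @param meshPath closed surface mesh (STL/PLY/OBJ, mm), PVs/LAA trimmed
#'   or left as protrusions for the exclusion rule.
#' @param landmarksPath landmark JSON (see [readLandmarks()]).
#' @param config an [atriaConfig()].
#' @param patientId identifier used in reports and error messages.
#' @return one-row data.frame: patient, LAV, LA_A, LA_P (mL), ASI
#'   (fraction), AR, S (mm), LAS (fraction), D_<segment> (mm),
#'   excludedAreaFraction; provenance (software version, config hash, input
#'   checksums) in attribute \code{"provenance"}.
#' @export
runPatient <- function(meshPath, landmarksPath, config = atriaConfig(),
                       patientId = NULL) {
  if (is.null(patientId))
    patientId <- tools::file_path_sans_ext(basename(meshPath))
  mesh <- .stage("read_mesh", patientId, readMesh(meshPath))
  landmarks <- .stage("read_landmarks", patientId, readLandmarks(landmarksPath))
  m <- .analyzeShape(mesh, landmarks, config, patientId)
  attr(m, "provenance") <- list(
    software = sprintf("atriamorph %s",
                       as.character(utils::packageVersion("atriamorph"))),
    configHash = .configHash(config),
    inputs = c(mesh = unname(tools::md5sum(meshPath)),
               landmarks = unname(tools::md5sum(landmarksPath))))
  m
}

#' Shape analysis on in-memory objects
#'
#' Same sequence as [runPatient()] without the file layer; used by the
#' synthetic validation studies.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param landmarks a [LandmarkSet-class].
#' @param config an [atriaConfig()].
#' @param patientId identifier.
#' @return one-row metrics data.frame (see [runPatient()]).
#' @export
analyzeShape <- function(mesh, landmarks, config = atriaConfig(),
                         patientId = "patient") {
  .analyzeShape(mesh, landmarks, config, patientId)
}

.analyzeShape <- function(mesh, landmarks, config, patientId) {
  stopifnot(inherits(config, "atriaConfig"))
  sphere <- .stage("fit_sphere", patientId,
    fitSphereIcp(mesh, tolerance = config$sphereTolerance,
                 maxIterations = config$sphereMaxIterations))
  field <- .stage("deviation_field", patientId,
    deviationField(mesh, sphere, config$exclusionThreshold,
                   config$exclusionMode, config$areaWeighted))
  ## optional refit on included vertices only (off by default)
  for (pass in seq_len(config$refitPasses)) {
    idx <- field@included
    sphere <- .stage("refit_sphere", patientId,
      fitSphereIcp(mesh@vertices[idx, , drop = FALSE],
                   tolerance = config$sphereTolerance,
                   maxIterations = config$sphereMaxIterations,
                   weights = field@weight[idx]))
    field <- .stage("deviation_field", patientId,
      deviationField(mesh, sphere, config$exclusionThreshold,
                     config$exclusionMode, config$areaWeighted))
  }
  frame <- .stage("patient_frame", patientId,
    buildPatientFrame(mesh, sphere, landmarks))
  labeling <- .stage("partition", patientId,
    partitionSurface(mesh, sphere, frame, field, config$bands))
  segD <- .stage("segmental_deviation", patientId,
    segmentalDeviation(field, labeling))
  post <- .stage("posterior_plane", patientId,
    posteriorPlane(mesh, labeling, landmarks))
  cut <- .stage("cutting_plane", patientId,
    cuttingPlane(post, landmarks, config$planeOffset))
  asym <- .stage("asymmetry", patientId, asymmetryIndex(mesh, cut))
  sph <- sphericity(field, sphere)

  exclFrac <- sum(field@weight[!field@included]) / sum(field@weight)
  out <- data.frame(patient = patientId, LAV = asym$LAV, LA_A = asym$LA_A,
                    LA_P = asym$LA_P, ASI = asym$ASI, AR = sph$AR,
                    S = sph$S, LAS = sph$LAS)
  D <- segD$D; names(D) <- paste0("D_", segD$segment)
  out <- cbind(out, as.data.frame(as.list(D)))
  out$excludedAreaFraction <- exclFrac
  out
}

#' Run the shape analysis over a cohort directory
#'
#' Expects subdirectories \code{patient_*} each holding \code{mesh.ply} (or
#' .stl/.obj) and \code{landmarks.json}; low-voltage labels come either
#' from a cohort CSV (columns patient, segment, lva) or from per-patient
#' \code{lva_labels.csv}. Patients failing any stage are excluded with a
#' warning, never aborting the cohort.
#'
#' @param cohortDir cohort root directory.
#' @param labelsCsv optional cohort-level label CSV.
#' @param config an [atriaConfig()].
#' @param outDir optional results directory (metrics CSV, association
#'   report, run log).
#' @return list with \code{table} (CohortTable data.frame), \code{report}
#'   (associationReport or NULL), \code{failures} (named character).
#' @export
runCohort <- function(cohortDir, labelsCsv = NULL, config = atriaConfig(),
                      outDir = NULL) {
  pdirs <- sort(list.dirs(cohortDir, recursive = FALSE))
  pdirs <- pdirs[grepl("^patient_", basename(pdirs))]
  if (length(pdirs) < 2L)
    stop("runCohort: need at least 2 patient_* directories in ", cohortDir)

  labels <- NULL
  if (!is.null(labelsCsv)) {
    lab <- utils::read.csv(labelsCsv, stringsAsFactors = FALSE)
    stopifnot(all(c("patient", "segment", "lva") %in% names(lab)))
    labels <- lab
  }

  rows <- list(); failures <- character(0); log <- character(0)
  for (pd in pdirs) {
    id <- basename(pd)
    meshFile <- Filter(file.exists,
                       file.path(pd, c("mesh.ply", "mesh.stl", "mesh.obj")))
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    res <- tryCatch(
      withCallingHandlers({
        if (length(meshFile) == 0L) stop("no mesh file")
        runPatient(meshFile[1], file.path(pd, "landmarks.json"), config, id)
      }, warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    for (w in warns) log <- c(log, sprintf("%s warning: %s", id, w))
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      log <- c(log, sprintf("%s FAILED (%.2fs): %s", id, dt,
                            conditionMessage(res)))
      warning("runCohort: patient ", id, " failed and was excluded: ",
              conditionMessage(res), call. = FALSE)
    } else {
      rows[[id]] <- res
      log <- c(log, sprintf("%s ok (%.2fs)", id, dt))
    }
  }
  if (length(rows) == 0L) stop("runCohort: every patient failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  ## join labels
  lvaCols <- paste0("lva_", segmentNames())
  for (cl in lvaCols) tab[[cl]] <- NA_integer_
  for (i in seq_len(nrow(tab))) {
    id <- tab$patient[i]
    if (!is.null(labels)) {
      li <- labels[labels$patient == id, ]
      if (nrow(li)) tab[i, paste0("lva_", li$segment)] <- li$lva
    } else {
      f <- file.path(cohortDir, id, "lva_labels.csv")
      if (file.exists(f)) {
        li <- utils::read.csv(f)
        tab[i, paste0("lva_", li$segment)] <- li$lva
      }
    }
  }
  noLab <- apply(is.na(tab[, lvaCols]), 1L, any)
  if (any(noLab))
    warning("runCohort: no low-voltage labels for ",
            paste(tab$patient[noLab], collapse = ", "),
            "; excluded from the association stage", call. = FALSE)
  tab$lva_segment_count <- rowSums(tab[, lvaCols])

  report <- NULL
  assoc <- tab[!noLab, , drop = FALSE]
  if (nrow(assoc) >= 3L)
    report <- tryCatch(
      lvaAssociation(assoc, welch = config$welch,
                     bhCorrect = config$bhCorrect, alpha = config$alpha),
      error = function(e) { warning("association stage failed: ",
                                    conditionMessage(e), call. = FALSE); NULL })

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(outDir, "cohort_metrics.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(outDir, "run_log.txt"))
    if (!is.null(report)) writeAssociationReport(report, outDir)
    jsonlite::write_json(
      list(patients = nrow(tab), failed = length(failures),
           configHash = .configHash(config)),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  }
  list(table = tab, report = report, failures = failures)
}
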