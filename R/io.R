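# File I/O for the standard text formats used by the pipeline: Gmsh MSH v2.2
# ASCII and legacy VTK for volume meshes, NOFF for surfaces with normals,
# legacy VTK PolyData for scalar surface maps, TSV for sensors/dipoles and
# full-precision TSV (+ JSON metadata sidecar) for leadfields and recordings.
# All coordinates on disk are mm. Readers reject truncated files.

.fmt <- function(x) sprintf("%.17g", x)

.checkLines <- function(lines, need, path) {
  if (length(lines) < need)
    stop("truncated file: ", path, " (expected at least ", need, " lines)")
}

#' Write a labeled tetrahedral mesh as Gmsh MSH v2.2 ASCII
#'
#' Element labels are stored as the physical tag of 4-node tetrahedra
#' (element type 4); compartment names go into $PhysicalNames.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param path output file.
#' @export
writeMshMesh <- function(mesh, path) {
  nodes <- nodePositions(mesh)
  el <- meshElements(mesh)
  lab <- elementLabels(mesh)
  nm <- labelNames(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$PhysicalNames",
               as.character(length(nm)),
               sprintf("3 %d \"%s\"", seq_along(nm), nm),
               "$EndPhysicalNames", "$Nodes", as.character(nrow(nodes))), con)
  writeLines(paste(seq_len(nrow(nodes)), .fmt(nodes[, 1]), .fmt(nodes[, 2]),
                   .fmt(nodes[, 3])), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(el))), con)
  writeLines(paste(seq_len(nrow(el)), 4L, 2L, lab, lab,
                   el[, 1], el[, 2], el[, 3], el[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a labeled tetrahedral mesh from Gmsh MSH v2.2 ASCII
#'
#' Only 4-node tetrahedra (type 4) are retained; the physical tag becomes the
#' compartment label.
#'
#' @param path input file.
#' @return a [LabeledTetMesh-class].
#' @export
readMshMesh <- function(path) {
  lines <- readLines(path)
  sect <- function(tag) {
    s <- which(lines == paste0("$", tag)); e <- which(lines == paste0("$End", tag))
    if (length(s) != 1 || length(e) != 1 || e <= s)
      stop("truncated or malformed MSH file: ", path, " (missing $", tag, ")")
    lines[(s + 1):(e - 1)]
  }
  nms <- character(0)
  if (any(lines == "$PhysicalNames")) {
    pn <- sect("PhysicalNames")
    k <- as.integer(pn[1])
    .checkLines(pn, k + 1, path)
    for (i in seq_len(k)) {
      parts <- strsplit(pn[i + 1], " ")[[1]]
      id <- as.integer(parts[2])
      nms[id] <- gsub("\"", "", paste(parts[-(1:2)], collapse = " "))
    }
  }
  nd <- sect("Nodes")
  n <- as.integer(nd[1])
  .checkLines(nd, n + 1, path)
  nodes <- matrix(as.numeric(unlist(strsplit(nd[1 + seq_len(n)], " +"))),
                  ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE]
  ee <- sect("Elements")
  m <- as.integer(ee[1])
  .checkLines(ee, m + 1, path)
  rows <- strsplit(ee[1 + seq_len(m)], " +")
  keep <- vapply(rows, function(r) as.integer(r[2]) == 4L, TRUE)
  rows <- rows[keep]
  ntags <- vapply(rows, function(r) as.integer(r[3]), 0L)
  lab <- as.integer(vapply(rows, function(r) r[4], ""))
  el <- t(vapply(seq_along(rows), function(i)
    as.integer(rows[[i]][(4 + ntags[i]):(7 + ntags[i])]), integer(4)))
  if (!length(nms)) nms <- .defaultShellNames(max(lab))
  v <- .tetVolumes(nodes, el)
  el[v < 0, c(3, 4)] <- el[v < 0, c(4, 3)]
  new("LabeledTetMesh", nodes = nodes, elements = el, labels = lab,
      labelNames = nms[seq_len(max(lab))])
}

#' Write a mesh as legacy VTK ASCII unstructured grid
#'
#' Compartment labels are written as the integer cell-data field
#' `compartment`.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param path output file (conventionally .vtk).
#' @export
writeVtkMesh <- function(mesh, path) {
  nodes <- nodePositions(mesh)
  el <- meshElements(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "sensmap volume mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  writeLines(paste(.fmt(nodes[, 1]), .fmt(nodes[, 2]), .fmt(nodes[, 3])), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), 5L * nrow(el)), con)
  writeLines(paste(4L, el[, 1] - 1L, el[, 2] - 1L, el[, 3] - 1L, el[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(as.character(rep(10L, nrow(el))), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(el)),
               "SCALARS compartment int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(elementLabels(mesh)), con)
  invisible(path)
}

#' Write a surface with per-vertex normals in NOFF format
#' @param surface a [TriSurface-class].
#' @param path output file.
#' @export
writeOffSurface <- function(surface, path) {
  v <- surfaceVertices(surface); nrm <- surfaceNormals(surface)
  f <- surfaceFaces(surface)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("NOFF", paste(nrow(v), nrow(f), 0L)), con)
  writeLines(paste(.fmt(v[, 1]), .fmt(v[, 2]), .fmt(v[, 3]),
                   .fmt(nrm[, 1]), .fmt(nrm[, 2]), .fmt(nrm[, 3])), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read a NOFF surface
#' @param path input file.
#' @return a [TriSurface-class].
#' @export
readOffSurface <- function(path) {
  lines <- readLines(path)
  .checkLines(lines, 2, path)
  if (lines[1] != "NOFF") stop("not a NOFF file: ", path)
  counts <- as.integer(strsplit(lines[2], " +")[[1]])
  nv <- counts[1]; nf <- counts[2]
  .checkLines(lines, 2 + nv + nf, path)
  vv <- matrix(as.numeric(unlist(strsplit(lines[2 + seq_len(nv)], " +"))),
               ncol = 6, byrow = TRUE)
  ff <- matrix(as.integer(unlist(strsplit(lines[2 + nv + seq_len(nf)], " +"))),
               ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  new("TriSurface", vertices = vv[, 1:3, drop = FALSE], faces = ff,
      normals = .normalizeRows(vv[, 4:6, drop = FALSE]))
}

#' Export per-vertex scalar maps on a surface as legacy VTK PolyData
#'
#' @param surface a [TriSurface-class].
#' @param scalars named list of per-vertex numeric vectors (finite; filter
#'   sentinels first).
#' @param path output file.
#' @export
writeSurfaceMap <- function(surface, scalars, path) {
  v <- surfaceVertices(surface); f <- surfaceFaces(surface)
  if (!length(names(scalars)) || any(names(scalars) == ""))
    stop("scalars must be a named list")
  for (nm in names(scalars)) {
    s <- scalars[[nm]]
    if (length(s) != nrow(v)) stop("scalar '", nm, "' length must equal vertex count")
    if (any(!is.finite(s))) stop("scalar '", nm, "' contains non-finite values")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "sensmap surface map", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  writeLines(paste(.fmt(v[, 1]), .fmt(v[, 2]), .fmt(v[, 3])), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(.fmt(scalars[[nm]]), con)
  }
  invisible(path)
}

#' Read back a VTK PolyData surface map
#' @param path input file.
#' @return list with `vertices`, `faces` and `scalars` (named list).
#' @export
readSurfaceMap <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)
  if (!length(ip)) stop("truncated VTK PolyData file: ", path)
  nv <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  .checkLines(lines, ip + nv, path)
  v <- matrix(as.numeric(unlist(strsplit(lines[ip + seq_len(nv)], " +"))),
              ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS ", lines)
  nf <- as.integer(strsplit(lines[ig], " +")[[1]][2])
  .checkLines(lines, ig + nf, path)
  f <- matrix(as.integer(unlist(strsplit(lines[ig + seq_len(nf)], " +"))),
              ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  scalars <- list()
  for (is in grep("^SCALARS ", lines)) {
    nm <- strsplit(lines[is], " +")[[1]][2]
    .checkLines(lines, is + 1 + nv, path)
    scalars[[nm]] <- as.numeric(lines[is + 1 + seq_len(nv)])
  }
  list(vertices = v, faces = f, scalars = scalars)
}

#' Write sensors as TSV (label, x_mm, y_mm, z_mm, ox, oy, oz, type)
#' @param sensors a [SensorSet-class].
#' @param path output file.
#' @export
writeSensorsTsv <- function(sensors, path) {
  e <- electrodePositions(sensors); c3 <- coilPositions(sensors)
  o <- coilOrientations(sensors)
  df <- rbind(
    data.frame(label = sensors@eegLabels, x_mm = e[, 1], y_mm = e[, 2],
               z_mm = e[, 3], ox = NA_real_, oy = NA_real_, oz = NA_real_,
               type = "eeg"),
    data.frame(label = sensors@megLabels, x_mm = c3[, 1], y_mm = c3[, 2],
               z_mm = c3[, 3], ox = o[, 1], oy = o[, 2], oz = o[, 3],
               type = "meg"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dipole set as TSV
#' @param dipoles a [DipoleSet-class].
#' @param path output file.
#' @export
writeDipolesTsv <- function(dipoles, path) {
  p <- dipolePositions(dipoles); o <- dipoleOrientations(dipoles)
  df <- data.frame(x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3],
                   ox = o[, 1], oy = o[, 2], oz = o[, 3],
                   group = dipoleGroups(dipoles), class = dipoleClass(dipoles),
                   region = dipoleRegions(dipoles),
                   depth_mm = dipoleDepths(dipoles),
                   angle_deg = dipoleAngles(dipoles))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dipole set from TSV
#' @param path input file.
#' @return a [DipoleSet-class].
#' @export
readDipolesTsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("x_mm", "y_mm", "z_mm", "ox", "oy", "oz", "group", "class", "region")
  if (!all(need %in% names(df)))
    stop("truncated or malformed dipole TSV: ", path)
  d <- dipoleSet(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
                 as.matrix(df[, c("ox", "oy", "oz")]),
                 group = df$group, classTag = df$class, region = df$region)
  if ("depth_mm" %in% names(df)) d@depth <- as.numeric(df$depth_mm)
  if ("angle_deg" %in% names(df)) d@angle <- as.numeric(df$angle_deg)
  d
}

# generic full-precision matrix TSV with JSON metadata sidecar
.writeMatrixTsv <- function(mat, path, meta = list()) {
  meta$nrow <- nrow(mat); meta$ncol <- ncol(mat)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(mat)), function(i)
    paste(sprintf("%.17g", mat[i, ]), collapse = "\t"), ""), con)
  invisible(path)
}

.readMatrixTsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(path)
  if (length(lines) != meta$nrow) stop("truncated matrix TSV: ", path)
  mat <- matrix(as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE))),
                nrow = meta$nrow, byrow = TRUE)
  if (ncol(mat) != meta$ncol) stop("truncated matrix TSV: ", path)
  list(matrix = mat, meta = meta)
}

#' Write a leadfield to full-precision TSV with a JSON metadata sidecar
#'
#' The round trip through [readLeadfieldTsv()] is bit-exact.
#'
#' @param lf a [Leadfield-class].
#' @param path output file (a `path.json` sidecar is written alongside).
#' @param configHash optional provenance hash stored in the sidecar.
#' @export
writeLeadfieldTsv <- function(lf, path, configHash = NULL) {
  md <- S4Vectors::metadata(lf)
  .writeMatrixTsv(leadfieldMatrix(lf), path,
                  meta = list(modality = md$modality, units = md$units,
                              config_hash = configHash))
  utils::write.table(as.data.frame(SummarizedExperiment::colData(lf)),
                     paste0(path, ".dipoles.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a leadfield written by [writeLeadfieldTsv()]
#' @param path input file.
#' @return a list with `matrix`, `meta` and `dipoles` (data.frame).
#' @export
readLeadfieldTsv <- function(path) {
  out <- .readMatrixTsv(path)
  out$dipoles <- utils::read.delim(paste0(path, ".dipoles.tsv"))
  out
}

#' Write a baseline recording as full-precision TSV + JSON sidecar
#' @param baseline a [BaselineRecording-class].
#' @param path output file.
#' @export
writeBaselineTsv <- function(baseline, path) {
  .writeMatrixTsv(baseline@samples, path,
                  meta = c(list(modality = baseline@channelModality),
                           baseline@meta))
  invisible(path)
}

#' Read a baseline recording written by [writeBaselineTsv()]
#' @param path input file.
#' @return a [BaselineRecording-class].
#' @export
readBaselineTsv <- function(path) {
  out <- .readMatrixTsv(path)
  new("BaselineRecording", samples = out$matrix,
      channelModality = out$meta$modality,
      meta = out$meta[setdiff(names(out$meta),
                              c("modality", "nrow", "ncol"))])
}
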