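# Central S4 containers. Geometry is stored in mm (anatomical convention);
# functions that need SI convert internally.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' LabeledTetMesh: tetrahedral volume conductor with compartment labels
#'
#' @slot nodes numeric matrix (n x 3), node positions in mm.
#' @slot elements integer matrix (m x 4), node indices per tetrahedron,
#'   ordered for positive signed volume.
#' @slot labels integer vector (m), compartment id per element
#'   (innermost = 1, increasing outwards).
#' @slot labelNames character, compartment name per id.
#' @exportClass LabeledTetMesh
setClass("LabeledTetMesh",
  representation(nodes = "matrix", elements = "matrix",
                 labels = "integer", labelNames = "character"))

setValidity("LabeledTetMesh", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
  if (ncol(object@elements) != 4L) msg <- c(msg, "elements must be m x 4")
  if (length(object@labels) != nrow(object@elements))
    msg <- c(msg, "one label per element required")
  if (nrow(object@elements) > 0) {
    rng <- range(object@elements)
    if (rng[1] < 1L || rng[2] > nrow(object@nodes))
      msg <- c(msg, "element node indices out of range")
    v <- .tetVolumes(object@nodes, object@elements)
    if (any(v <= 0)) msg <- c(msg, sprintf("%d tetrahedra with non-positive volume", sum(v <= 0)))
    if (!all(unique(object@labels) %in% seq_along(object@labelNames)))
      msg <- c(msg, "labels without a name in labelNames")
  }
  if (length(msg)) msg else TRUE
})

#' @noRd
.tetVolumes <- function(nodes, elements) {
  a <- nodes[elements[, 2], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 3], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
  c3 <- nodes[elements[, 4], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
  rowSums(a * .rowCross(b, c3)) / 6
}

#' ConductivityField: per-element symmetric conductivity tensors
#'
#' Tensors are stored row-wise in compressed form (xx, yy, zz, xy, xz, yz),
#' in S/m. `variant` records the head-model variant the field realises.
#'
#' @exportClass ConductivityField
setClass("ConductivityField",
  representation(tensors = "matrix", variant = "character"))

setValidity("ConductivityField", function(object) {
  tn <- object@tensors
  if (ncol(tn) != 6L) return("tensors must be m x 6 (xx, yy, zz, xy, xz, yz)")
  # Sylvester's criterion on every element tensor
  d1 <- tn[, 1]
  d2 <- tn[, 1] * tn[, 2] - tn[, 4]^2
  d3 <- tn[, 1] * (tn[, 2] * tn[, 3] - tn[, 6]^2) -
        tn[, 4] * (tn[, 4] * tn[, 3] - tn[, 6] * tn[, 5]) +
        tn[, 5] * (tn[, 4] * tn[, 6] - tn[, 2] * tn[, 5])
  if (any(d1 <= 0) || any(d2 <= 0) || any(d3 <= 0))
    return("all conductivity tensors must be symmetric positive definite")
  TRUE
})

#' TriSurface: closed triangulated surface with outward vertex normals
#' @exportClass TriSurface
setClass("TriSurface",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix"))

setValidity("TriSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (!identical(dim(object@normals), dim(object@vertices)))
    msg <- c(msg, "one normal per vertex required")
  nv <- nrow(object@vertices)
  f <- object@faces
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nv) msg <- c(msg, "face indices out of range")
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    key <- (pmin(e[, 1], e[, 2]) - 1) * nv + pmax(e[, 1], e[, 2])
    if (!all(table(key) == 2L))
      msg <- c(msg, "surface is not a closed 2-manifold (every edge must be shared by exactly 2 faces)")
    if (.surfaceVolume(object@vertices, f) <= 0)
      msg <- c(msg, "faces must be consistently outward-oriented (positive enclosed volume)")
    if (any(abs(.rowNorms(object@normals) - 1) > 1e-8))
      msg <- c(msg, "vertex normals must be unit norm")
  }
  if (length(msg)) msg else TRUE
})

#' SensorSet: point electrodes and oriented point coils
#'
#' Electrode positions coincide with scalp-surface mesh nodes (`electrodeNodes`
#' holds the node indices); coils sit strictly outside the scalp with unit
#' orientation axes.
#'
#' @exportClass SensorSet
setClass("SensorSet",
  representation(electrodes = "matrix", electrodeNodes = "integer",
                 coils = "matrix", coilOrientations = "matrix",
                 eegLabels = "character", megLabels = "character"))

setValidity("SensorSet", function(object) {
  msg <- character()
  if (nrow(object@electrodes) != length(object@electrodeNodes))
    msg <- c(msg, "one mesh node index per electrode required")
  if (!identical(dim(object@coils), dim(object@coilOrientations)))
    msg <- c(msg, "one orientation per coil required")
  if (nrow(object@coils) > 0 &&
      any(abs(.rowNorms(object@coilOrientations) - 1) > 1e-9))
    msg <- c(msg, "coil orientations must be unit norm")
  if (length(object@eegLabels) != nrow(object@electrodes) ||
      length(object@megLabels) != nrow(object@coils))
    msg <- c(msg, "channel label counts must match sensor counts")
  if (length(msg)) msg else TRUE
})

#' BaselineRecording: per-channel baseline noise samples
#'
#' Samples are channels x time; EEG channels in uV, MEG channels in fT.
#' @exportClass BaselineRecording
setClass("BaselineRecording",
  representation(samples = "matrix", channelModality = "character",
                 meta = "list"))

setValidity("BaselineRecording", function(object) {
  msg <- character()
  if (length(object@channelModality) != nrow(object@samples))
    msg <- c(msg, "one modality tag per channel required")
  if (!all(object@channelModality %in% c("eeg", "meg")))
    msg <- c(msg, "channel modality must be 'eeg' or 'meg'")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' DipoleSet: point dipoles with grouping, class and covariates
#'
#' Co-located dipoles with different orientations share a `group` id
#' (cortical vertices mapping to the same element centroid; subcortical
#' Cartesian triplets). `element` optionally caches the host element in a
#' head mesh; `depth` (mm) and `angle` (degrees) are filled by
#' [sourceDepths()] / [sourceAngles()].
#'
#' @exportClass DipoleSet
setClass("DipoleSet",
  representation(positions = "matrix", orientations = "matrix",
                 group = "integer", classTag = "character",
                 region = "character", element = "integer",
                 depth = "numeric", angle = "numeric"))

setValidity("DipoleSet", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (!identical(dim(object@orientations), dim(object@positions)))
    msg <- c(msg, "one orientation per dipole required")
  if (n > 0 && any(abs(.rowNorms(object@orientations) - 1) > 1e-9))
    msg <- c(msg, "dipole orientations must be unit norm (tolerance 1e-9)")
  for (s in c("group", "classTag", "region", "element", "depth", "angle"))
    if (length(slot(object, s)) != n) msg <- c(msg, sprintf("slot '%s' must have one entry per dipole", s))
  if (n > 0) {
    if (any(!is.na(object@depth) & object@depth < 0)) msg <- c(msg, "depths must be >= 0")
    if (any(!is.na(object@angle) & (object@angle < 0 | object@angle > 180)))
      msg <- c(msg, "angles must lie in [0, 180] degrees")
    if (!all(object@classTag %in% c("cortical", "subcortical")))
      msg <- c(msg, "class tag must be 'cortical' or 'subcortical'")
  }
  if (length(msg)) msg else TRUE
})

#' SphereModel: concentric-sphere volume conductor
#'
#' @slot center numeric length-3, mm.
#' @slot radii numeric, strictly increasing shell radii in mm.
#' @slot conductivities numeric, isotropic conductivity per shell in S/m.
#' @exportClass SphereModel
setClass("SphereModel",
  representation(center = "numeric", radii = "numeric",
                 conductivities = "numeric"))

setValidity("SphereModel", function(object) {
  msg <- character()
  if (length(object@center) != 3L) msg <- c(msg, "center must be length 3")
  if (is.unsorted(object@radii, strictly = TRUE) || any(object@radii <= 0))
    msg <- c(msg, "radii must be strictly increasing and positive")
  if (length(object@conductivities) != length(object@radii))
    msg <- c(msg, "one conductivity per shell required")
  if (any(object@conductivities <= 0)) msg <- c(msg, "conductivities must be positive")
  if (length(msg)) msg else TRUE
})

#' StiffnessSystem: assembled FEM stiffness matrix with solver settings
#'
#' The matrix is symmetric positive semi-definite with nullspace spanned by
#' the constant vector (pure-Neumann problem); entries are in S*m (SI).
#' @exportClass StiffnessSystem
setClass("StiffnessSystem",
  representation(K = "Matrix", solver = "list"))

#' TransferMatrix: sensors x nodes adjoint solutions
#' @exportClass TransferMatrix
setClass("TransferMatrix",
  representation(mat = "matrix", modality = "character"))

setValidity("TransferMatrix", function(object) {
  if (!object@modality %in% c("eeg", "meg")) return("modality must be 'eeg' or 'meg'")
  TRUE
})

#' Leadfield: sensors x sources forward solutions per unit dipole moment
#'
#' Extends SummarizedExperiment: the single assay `"leadfield"` holds the
#' sensors x dipoles matrix (EEG in uV/nAm after average referencing, MEG in
#' fT/nAm), `rowData` the sensor table and `colData` the dipole covariates.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass Leadfield
setClass("Leadfield", contains = "SummarizedExperiment")

setValidity("Leadfield", function(object) {
  msg <- character()
  if (!"leadfield" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'leadfield' missing")
  md <- S4Vectors::metadata(object)
  if (is.null(md$modality) || !md$modality %in% c("eeg", "meg"))
    msg <- c(msg, "metadata()$modality must be 'eeg' or 'meg'")
  if (length(msg)) msg else TRUE
})
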