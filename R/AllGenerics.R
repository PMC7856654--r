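# Generics and accessor methods. Slot access from user code should go through
# these.

#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))
#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))
#' @export
setGeneric("elementLabels", function(x) standardGeneric("elementLabels"))
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))
#' @export
setGeneric("elementVolumes", function(x) standardGeneric("elementVolumes"))
#' @export
setGeneric("elementCentroids", function(x) standardGeneric("elementCentroids"))

#' @export
setGeneric("surfaceVertices", function(x) standardGeneric("surfaceVertices"))
#' @export
setGeneric("surfaceFaces", function(x) standardGeneric("surfaceFaces"))
#' @export
setGeneric("surfaceNormals", function(x) standardGeneric("surfaceNormals"))

#' @export
setGeneric("electrodePositions", function(x) standardGeneric("electrodePositions"))
#' @export
setGeneric("coilPositions", function(x) standardGeneric("coilPositions"))
#' @export
setGeneric("coilOrientations", function(x) standardGeneric("coilOrientations"))
#' @export
setGeneric("nEeg", function(x) standardGeneric("nEeg"))
#' @export
setGeneric("nMeg", function(x) standardGeneric("nMeg"))

#' @export
setGeneric("dipolePositions", function(x) standardGeneric("dipolePositions"))
#' @export
setGeneric("dipoleOrientations", function(x) standardGeneric("dipoleOrientations"))
#' @export
setGeneric("nDipoles", function(x) standardGeneric("nDipoles"))
#' @export
setGeneric("dipoleGroups", function(x) standardGeneric("dipoleGroups"))
#' @export
setGeneric("dipoleClass", function(x) standardGeneric("dipoleClass"))
#' @export
setGeneric("dipoleRegions", function(x) standardGeneric("dipoleRegions"))
#' @export
setGeneric("dipoleDepths", function(x) standardGeneric("dipoleDepths"))
#' @export
setGeneric("dipoleAngles", function(x) standardGeneric("dipoleAngles"))

#' @export
setGeneric("conductivityTensors", function(x) standardGeneric("conductivityTensors"))
#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))

#' @export
setGeneric("leadfieldMatrix", function(x) standardGeneric("leadfieldMatrix"))
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

setMethod("nodePositions", "LabeledTetMesh", function(x) x@nodes)
setMethod("meshElements", "LabeledTetMesh", function(x) x@elements)
setMethod("elementLabels", "LabeledTetMesh", function(x) x@labels)
setMethod("labelNames", "LabeledTetMesh", function(x) x@labelNames)
setMethod("elementVolumes", "LabeledTetMesh", function(x) .tetVolumes(x@nodes, x@elements))
setMethod("elementCentroids", "LabeledTetMesh", function(x) {
  (x@nodes[x@elements[, 1], , drop = FALSE] + x@nodes[x@elements[, 2], , drop = FALSE] +
   x@nodes[x@elements[, 3], , drop = FALSE] + x@nodes[x@elements[, 4], , drop = FALSE]) / 4
})

setMethod("surfaceVertices", "TriSurface", function(x) x@vertices)
setMethod("surfaceFaces", "TriSurface", function(x) x@faces)
setMethod("surfaceNormals", "TriSurface", function(x) x@normals)

setMethod("electrodePositions", "SensorSet", function(x) x@electrodes)
setMethod("coilPositions", "SensorSet", function(x) x@coils)
setMethod("coilOrientations", "SensorSet", function(x) x@coilOrientations)
setMethod("nEeg", "SensorSet", function(x) nrow(x@electrodes))
setMethod("nMeg", "SensorSet", function(x) nrow(x@coils))

setMethod("dipolePositions", "DipoleSet", function(x) x@positions)
setMethod("dipoleOrientations", "DipoleSet", function(x) x@orientations)
setMethod("nDipoles", "DipoleSet", function(x) nrow(x@positions))
setMethod("dipoleGroups", "DipoleSet", function(x) x@group)
setMethod("dipoleClass", "DipoleSet", function(x) x@classTag)
setMethod("dipoleRegions", "DipoleSet", function(x) x@region)
setMethod("dipoleDepths", "DipoleSet", function(x) x@depth)
setMethod("dipoleAngles", "DipoleSet", function(x) x@angle)

setMethod("conductivityTensors", "ConductivityField", function(x) x@tensors)
setMethod("modelVariant", "ConductivityField", function(x) x@variant)

setMethod("leadfieldMatrix", "Leadfield",
          function(x) SummarizedExperiment::assay(x, "leadfield"))
setMethod("modality", "Leadfield", function(x) S4Vectors::metadata(x)$modality)
setMethod("modality", "TransferMatrix", function(x) x@modality)

#' Combine two DipoleSets
#' @export
setMethod("c", "DipoleSet", function(x, ...) {
  more <- list(...)
  for (y in more) {
    off <- if (length(x@group)) max(x@group) else 0L
    x <- new("DipoleSet",
             positions = rbind(x@positions, y@positions),
             orientations = rbind(x@orientations, y@orientations),
             group = c(x@group, y@group + off),
             classTag = c(x@classTag, y@classTag),
             region = c(x@region, y@region),
             element = c(x@element, y@element),
             depth = c(x@depth, y@depth),
             angle = c(x@angle, y@angle))
  }
  x
})

#' Subset a DipoleSet
#' @export
setMethod("[", "DipoleSet", function(x, i, j, ..., drop = FALSE) {
  new("DipoleSet",
      positions = x@positions[i, , drop = FALSE],
      orientations = x@orientations[i, , drop = FALSE],
      group = x@group[i], classTag = x@classTag[i], region = x@region[i],
      element = x@element[i], depth = x@depth[i], angle = x@angle[i])
})

#' @export
setMethod("show", "LabeledTetMesh", function(object) {
  cat(sprintf("LabeledTetMesh: %d nodes, %d tetrahedra, %d compartment(s)\n",
              nrow(object@nodes), nrow(object@elements), length(object@labelNames)))
  tab <- table(factor(object@labelNames[object@labels], levels = object@labelNames))
  for (nm in names(tab)) cat(sprintf("  %-12s %d elements\n", nm, tab[[nm]]))
})

#' @export
setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface: %d vertices, %d faces, enclosed volume %.1f mm^3\n",
              nrow(object@vertices), nrow(object@faces),
              .surfaceVolume(object@vertices, object@faces)))
})

#' @export
setMethod("show", "SensorSet", function(object) {
  cat(sprintf("SensorSet: %d electrodes (EEG), %d coils (MEG)\n",
              nEeg(object), nMeg(object)))
})

#' @export
setMethod("show", "DipoleSet", function(object) {
  cat(sprintf("DipoleSet: %d dipoles (%d cortical, %d subcortical), %d groups\n",
              nDipoles(object), sum(object@classTag == "cortical"),
              sum(object@classTag == "subcortical"),
              length(unique(object@group))))
})

#' @export
setMethod("show", "ConductivityField", function(object) {
  cat(sprintf("ConductivityField: variant %s, %d element tensors\n",
              object@variant, nrow(object@tensors)))
})
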