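# Dipole source spaces: cortical dipoles from a folded surface, subcortical
# Cartesian triplets from region meshes, and the depth/angle covariates with
# their five-bin clustering.

#' Construct a DipoleSet
#'
#' @param positions n x 3 mm.
#' @param orientations n x 3 unit vectors.
#' @param group integer co-location group ids (default: each dipole its own).
#' @param classTag "cortical" or "subcortical" (recycled).
#' @param region region names (subcortical), NA otherwise.
#' @param element optional host element indices in a head mesh.
#' @return a [DipoleSet-class].
#' @export
dipoleSet <- function(positions, orientations, group = NULL,
                      classTag = "cortical", region = NA_character_,
                      element = NA_integer_) {
  positions <- .asMatrix3(positions, "positions")
  orientations <- .normalizeRows(.asMatrix3(orientations, "orientations"))
  n <- nrow(positions)
  if (is.null(group)) group <- seq_len(n)
  new("DipoleSet", positions = positions, orientations = orientations,
      group = as.integer(rep_len(group, n)),
      classTag = rep_len(classTag, n), region = rep_len(region, n),
      element = as.integer(rep_len(element, n)),
      depth = rep(NA_real_, n), angle = rep(NA_real_, n))
}

#' Cortical dipoles from a white-matter-style surface
#'
#' Each surface vertex is projected into the centroid of the closest
#' gray-matter element (Euclidean distance between vertex and element
#' centroids) and oriented along the vertex normal. Several vertices may map
#' to the same centroid, yielding co-located dipoles with different
#' orientations; these share a group id.
#'
#' @param surface a [TriSurface-class] inside the mesh.
#' @param mesh a [LabeledTetMesh-class].
#' @param grayLabel compartment name or id regarded as gray matter (default
#'   `"brain"`, the gray target in 3/4-shell phantoms; use `"gray"` for
#'   6-shell meshes).
#' @return a [DipoleSet-class] with host elements cached.
#' @export
corticalDipolesFromSurface <- function(surface, mesh, grayLabel = "brain") {
  if (is.character(grayLabel)) {
    grayLabel <- match(grayLabel, labelNames(mesh))
    if (is.na(grayLabel)) stop("grayLabel not found among mesh compartments")
  }
  gray <- which(elementLabels(mesh) == grayLabel)
  if (!length(gray)) stop("mesh has no gray-matter elements (label ", grayLabel, ")")
  cent <- elementCentroids(mesh)[gray, , drop = FALSE]
  nn <- .nearestVertex(surfaceVertices(surface), cent)
  host <- gray[nn$index]
  dipoleSet(positions = cent[nn$index, , drop = FALSE],
            orientations = surfaceNormals(surface),
            group = match(host, unique(host)),
            classTag = "cortical", element = host)
}

#' Subcortical dipoles from region meshes (Cartesian triplets)
#'
#' For every node of every region mesh three dipoles are created with
#' orientations e_x, e_y, e_z, sharing a group id and carrying the region
#' name (no preferred orientation is assumed for deep structures).
#'
#' @param regions named list of [LabeledTetMesh-class] region meshes.
#' @return a [DipoleSet-class].
#' @export
subcorticalDipolesFromRegions <- function(regions) {
  if (is.null(names(regions))) names(regions) <- paste0("region_", seq_along(regions))
  pos <- do.call(rbind, lapply(regions, nodePositions))
  nNode <- vapply(regions, function(m) nrow(nodePositions(m)), 0L)
  regionOfNode <- rep(names(regions), nNode)
  n <- nrow(pos)
  eye <- diag(3)
  dipoleSet(positions = pos[rep(seq_len(n), each = 3L), , drop = FALSE],
            orientations = eye[rep(1:3, n), , drop = FALSE],
            group = rep(seq_len(n), each = 3L),
            classTag = "subcortical",
            region = regionOfNode[rep(seq_len(n), each = 3L)])
}

#' Source depths relative to the inner skull
#'
#' Per dipole, the Euclidean distance to the closest inner-skull surface
#' vertex (nearest-vertex, not point-to-triangle, so the surface vertex
#' spacing bounds the metric accuracy).
#'
#' @param dipoles a [DipoleSet-class].
#' @param innerSkull a [TriSurface-class].
#' @return numeric vector of depths in mm.
#' @export
sourceDepths <- function(dipoles, innerSkull) {
  if (nrow(surfaceVertices(innerSkull)) == 0) stop("empty inner-skull surface")
  .nearestVertex(dipolePositions(dipoles), surfaceVertices(innerSkull))$distance
}

#' Source angles relative to the inner-skull normal
#'
#' The angle in [0, 180] degrees between each dipole orientation and the
#' outward normal at the closest inner-skull vertex. Angles near 0/180 mark
#' radial sources, near 90 tangential ones.
#'
#' @param dipoles a [DipoleSet-class].
#' @param innerSkull a [TriSurface-class] with vertex normals.
#' @return numeric vector of angles in degrees.
#' @export
sourceAngles <- function(dipoles, innerSkull) {
  nn <- .nearestVertex(dipolePositions(dipoles), surfaceVertices(innerSkull))
  nrm <- surfaceNormals(innerSkull)[nn$index, , drop = FALSE]
  nl <- .rowNorms(nrm)
  if (any(nl < .Machine$double.eps)) stop("zero-length surface normal")
  nrm <- nrm / nl
  d <- rowSums(dipoleOrientations(dipoles) * nrm)
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Attach depth and angle covariates to a DipoleSet
#'
#' @param dipoles a [DipoleSet-class].
#' @param innerSkull a [TriSurface-class].
#' @return the [DipoleSet-class] with `depth` and `angle` filled.
#' @export
withSourceMetrics <- function(dipoles, innerSkull) {
  dipoles@depth <- sourceDepths(dipoles, innerSkull)
  dipoles@angle <- sourceAngles(dipoles, innerSkull)
  methods::validObject(dipoles)
  dipoles
}

# quantile-type-7 five-number summary
.fiveNum <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Cluster values into equal-width bins with five-number summaries
#'
#' Bins are right-open except the last, which is closed. Values outside
#' `range` are assigned NA and excluded from the summaries.
#'
#' @param values finite numeric vector.
#' @param nBins number of bins (default 5).
#' @param range bin range; defaults to c(0, max(values)).
#' @return list with `assignment` (integer, NA outside range), `edges`
#'   (length nBins + 1) and `summary` (data.frame: bin, lo, hi, count, min,
#'   q1, median, q3, max).
#' @export
binValues <- function(values, nBins = 5L, range = NULL) {
  if (nBins < 1) stop("nBins must be >= 1")
  if (length(values) && any(!is.finite(values))) stop("values must be finite")
  if (is.null(range)) {
    range <- c(0, if (length(values)) max(values) else 1)
    if (range[2] <= range[1]) range[2] <- range[1] + 1   # degenerate default
  }
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("range must have positive width")
  w <- (hi - lo) / nBins
  idx <- floor((values - lo) / w) + 1L
  idx[values == hi] <- nBins
  idx[values < lo | values > hi] <- NA_integer_
  edges <- lo + w * (0:nBins)
  summ <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    v <- values[!is.na(idx) & idx == b]
    if (!length(v))
      return(data.frame(bin = b, lo = edges[b], hi = edges[b + 1], count = 0L,
                        min = NA_real_, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_, max = NA_real_))
    f <- .fiveNum(v)
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1], count = length(v),
               min = f[["min"]], q1 = f[["q1"]], median = f[["median"]],
               q3 = f[["q3"]], max = f[["max"]])
  }))
  list(assignment = as.integer(idx), edges = edges, summary = summ)
}
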