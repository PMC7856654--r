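# Synthetic layered-sphere head models: labeled tetrahedral meshes,
# conductivity assignment (incl. anisotropic white matter), sensor layouts,
# a folded synthetic cortex, subcortical ball regions and baseline noise.

#' Conductivity table of the three head-model variants (S/m)
#'
#' Isotropic reference values per compartment for the three-compartment
#' isotropic (3CI), four-compartment isotropic (4CI) and six-compartment
#' anisotropic (6CA) variants. For 6CA the white-matter value is the mean
#' tensor eigenvalue of the anisotropic fit.
#'
#' @return named list of named numeric vectors.
#' @export
conductivityTable <- function() {
  list(
    `3CI` = c(brain = 0.33, skull = 0.01, scalp = 0.43),
    `4CI` = c(brain = 0.33, csf = 1.79, skull = 0.01, scalp = 0.43),
    `6CA` = c(white = 0.14, gray = 0.33, csf = 1.79,
              spongiosa = 0.025, compacta = 0.008, scalp = 0.43))
}

# How mesh compartment names collapse onto a variant's compartments.
.variantLabelMap <- function(variant) {
  switch(variant,
    `3CI` = c(brain = "brain", csf = "brain", white = "brain", gray = "brain",
              skull = "skull", spongiosa = "skull", compacta = "skull",
              scalp = "scalp"),
    `4CI` = c(brain = "brain", white = "brain", gray = "brain", csf = "csf",
              skull = "skull", spongiosa = "skull", compacta = "skull",
              scalp = "scalp"),
    `6CA` = c(white = "white", gray = "gray", csf = "csf",
              spongiosa = "spongiosa", compacta = "compacta", scalp = "scalp"),
    stop("unknown variant: ", variant))
}

.defaultShellNames <- function(k) {
  switch(as.character(k),
    `1` = "brain",
    `3` = c("brain", "skull", "scalp"),
    `4` = c("brain", "csf", "skull", "scalp"),
    `6` = c("white", "gray", "csf", "spongiosa", "compacta", "scalp"),
    paste0("shell_", seq_len(k)))
}

#' Canonical shell radii of the synthetic sphere phantom (mm)
#'
#' brain/CSF-outer/skull-outer/scalp-outer at 78/80/86/92 mm; the
#' six-compartment split divides the brain shell at 60 mm (white inside,
#' gray outside) and the skull shell at 83 mm (spongiosa inside, compacta
#' outside).
#'
#' @param nShells 3, 4 or 6.
#' @return numeric vector of increasing shell radii.
#' @export
canonicalRadii <- function(nShells = 4L) {
  switch(as.character(nShells),
    `3` = c(80, 86, 92),
    `4` = c(78, 80, 86, 92),
    `6` = c(60, 78, 80, 83, 86, 92),
    stop("nShells must be 3, 4 or 6"))
}

#' Build a labeled tetrahedral mesh of a layered sphere
#'
#' Icosphere-shell extrusion: nested icosphere surfaces are connected by
#' prisms (each split into three tetrahedra with a globally consistent
#' diagonal rule, so the mesh is conforming) plus a tetrahedral core. Radial
#' layer spacing approximately equals `targetEdgeLength` and every
#' compartment interface coincides with a layer, so each shell is resolved by
#' at least one element layer. The angular subdivision is chosen so the
#' angular edge length at mid-radius matches the target (angular edges grow
#' linearly with radius). Elements are labeled by the innermost shell
#' containing their centroid, innermost first.
#'
#' @param radii strictly increasing shell radii in mm.
#' @param targetEdgeLength target element edge length in mm.
#' @param seed integer; a seeded random rotation is applied to the node
#'   lattice so meshes for different seeds differ while remaining
#'   deterministic per seed.
#' @param labelNames optional compartment names (innermost first); defaults
#'   to brain/skull/scalp-style names for 1, 3, 4 or 6 shells.
#' @param subdivisions optional explicit icosphere subdivision level,
#'   overriding the edge-length heuristic.
#' @return a [LabeledTetMesh-class].
#' @export
buildLayeredSphereMesh <- function(radii, targetEdgeLength, seed = 1L,
                                   labelNames = NULL, subdivisions = NULL) {
  radii <- as.numeric(radii)
  if (length(radii) < 1L || any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing and positive")
  if (targetEdgeLength <= 0) stop("targetEdgeLength must be positive")
  if (targetEdgeLength > radii[1])
    stop("targetEdgeLength exceeds the innermost shell radius ",
         "(innermost compartment would be unresolved)")
  R <- radii[length(radii)]
  if (is.null(subdivisions))
    subdivisions <- max(1L, as.integer(round(log2(1.0515 * (R / 2) / targetEdgeLength))))
  ico <- icosphere(subdivisions)
  V <- nrow(ico$vertices)

  # radial levels: equal spacing within each compartment, interfaces included
  levels <- numeric(0)
  inner <- 0
  for (r in radii) {
    nl <- max(1L, round((r - inner) / targetEdgeLength))
    levels <- c(levels, inner + (r - inner) * seq_len(nl) / nl)
    inner <- r
  }
  L <- length(levels)

  rot <- .seedRotation(seed)
  dirs <- ico$vertices %*% t(rot)
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(levels, function(r) r * dirs)))

  nodeId <- function(lev, vid) 1L + (lev - 1L) * V + vid
  f <- ico$faces
  # core: center + innermost shell triangles
  core <- cbind(1L, nodeId(1L, f[, 1]), nodeId(1L, f[, 2]), nodeId(1L, f[, 3]))
  # prisms between consecutive levels; sort each triangle's vertex ids so the
  # split diagonals agree across shared quad faces
  fs <- t(apply(f, 1, sort))
  i0 <- fs[, 1]; j0 <- fs[, 2]; k0 <- fs[, 3]
  prismTets <- function(lev) {
    b <- function(v) nodeId(lev, v); t2 <- function(v) nodeId(lev + 1L, v)
    rbind(cbind(b(i0), b(j0), b(k0), t2(i0)),
          cbind(t2(i0), b(j0), b(k0), t2(j0)),
          cbind(t2(i0), t2(j0), b(k0), t2(k0)))
  }
  elems <- rbind(core, do.call(rbind, lapply(seq_len(L - 1L), prismTets)))
  storage.mode(elems) <- "integer"

  # consistent positive orientation
  v6 <- .tetVolumes(nodes, elems)
  neg <- v6 < 0
  if (any(neg)) elems[neg, c(3, 4)] <- elems[neg, c(4, 3)]
  if (any(.tetVolumes(nodes, elems) <= 0)) stop("degenerate tetrahedra generated")

  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
           nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  labels <- findInterval(.rowNorms(cent), radii) + 1L
  labels <- pmin(labels, length(radii))
  if (is.null(labelNames)) labelNames <- .defaultShellNames(length(radii))
  if (length(labelNames) != length(radii))
    stop("labelNames must have one entry per shell")

  new("LabeledTetMesh", nodes = nodes, elements = elems,
      labels = as.integer(labels), labelNames = labelNames)
}

#' Anisotropic conductivity tensor with a prescribed mean eigenvalue
#'
#' Builds sigma = lambda_t I + (lambda_l - lambda_t) d d^T with
#' lambda_l / lambda_t = `anisotropyRatio` and mean eigenvalue
#' (lambda_l + 2 lambda_t) / 3 = `referenceSigma` ("fit the mean" constraint).
#' The largest eigenvalue's eigenvector is the fiber direction.
#'
#' @param fiberDirection nonzero 3-vector (longitudinal direction).
#' @param referenceSigma isotropic reference conductivity in S/m.
#' @param anisotropyRatio longitudinal:transversal eigenvalue ratio (>= 1).
#' @return 3 x 3 symmetric positive-definite matrix.
#' @export
makeAnisotropicTensor <- function(fiberDirection, referenceSigma,
                                  anisotropyRatio = 10) {
  if (referenceSigma <= 0) stop("referenceSigma must be positive")
  if (anisotropyRatio < 1) stop("anisotropyRatio must be >= 1")
  nrm <- sqrt(sum(fiberDirection^2))
  if (nrm < .Machine$double.eps) stop("fiberDirection must be nonzero")
  d <- fiberDirection / nrm
  lt <- 3 * referenceSigma / (anisotropyRatio + 2)
  ll <- anisotropyRatio * lt
  lt * diag(3) + (ll - lt) * tcrossprod(d)
}

# vectorized compressed-form version used for whole compartments
.anisotropicTensorRows <- function(directions, referenceSigma, anisotropyRatio) {
  d <- .normalizeRows(directions)
  lt <- 3 * referenceSigma / (anisotropyRatio + 2)
  ll <- anisotropyRatio * lt
  dd <- cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
              d[, 1] * d[, 2], d[, 1] * d[, 3], d[, 2] * d[, 3])
  sweep((ll - lt) * dd, 2, c(lt, lt, lt, 0, 0, 0), "+")
}

#' Assign per-element conductivity tensors for a head-model variant
#'
#' Isotropic compartments receive sigma * Identity with the variant's table
#' value; for 6CA the white-matter compartment receives anisotropic tensors
#' with a locally radial fiber direction (synthetic convention) whose mean
#' eigenvalue equals the isotropic white-matter reference. A mesh with more
#' compartments than the variant (e.g. a 4-shell mesh under 3CI) is allowed:
#' labels collapse onto the variant's compartments (CSF into brain, skull
#' split into skull), mirroring "only the tissue labels were modified while
#' the mesh remained the same".
#'
#' @param mesh a [LabeledTetMesh-class] with canonical compartment names.
#' @param variant one of `"3CI"`, `"4CI"`, `"6CA"`.
#' @param anisotropyRatio longitudinal:transversal ratio for 6CA white matter.
#' @return a [ConductivityField-class].
#' @export
assignConductivities <- function(mesh, variant = c("4CI", "3CI", "6CA"),
                                 anisotropyRatio = 10) {
  variant <- match.arg(variant)
  tab <- conductivityTable()[[variant]]
  map <- .variantLabelMap(variant)
  meshNames <- labelNames(mesh)
  if (variant == "6CA" && !all(c("white", "gray") %in% meshNames))
    stop("variant 6CA requires compartments 'white' and 'gray' in the mesh; missing: ",
         paste(setdiff(c("white", "gray"), meshNames), collapse = ", "))
  unknown <- setdiff(meshNames, names(map))
  if (length(unknown))
    stop("mesh compartments not mappable to variant ", variant, ": ",
         paste(unknown, collapse = ", "))
  target <- unname(map[meshNames[elementLabels(mesh)]])
  tensors <- matrix(0, nrow(meshElements(mesh)), 6L)
  iso <- tab[target]
  tensors[, 1:3] <- iso
  if (variant == "6CA") {
    wm <- which(target == "white")
    cent <- elementCentroids(mesh)[wm, , drop = FALSE]
    r <- .rowNorms(cent)
    cent[r < 1e-9, ] <- rep(c(0, 0, 1), each = sum(r < 1e-9))
    tensors[wm, ] <- .anisotropicTensorRows(cent, tab[["white"]], anisotropyRatio)
  }
  new("ConductivityField", tensors = tensors, variant = variant)
}

#' Outer (scalp) surface node indices of a layered-sphere mesh
#' @noRd
.scalpNodes <- function(mesh) {
  r <- .rowNorms(nodePositions(mesh))
  R <- max(r)
  which(r > R - 1e-6 * R)
}

#' Place point electrodes and coils around a head mesh
#'
#' Electrodes are laid out quasi-uniformly (Fibonacci lattice) on the scalp
#' sphere and snapped to the closest scalp-surface mesh node (point-electrode
#' convention, making the EEG restriction matrix trivial); coils sit on a
#' sphere at scalp radius + `coilOffset` with radially oriented axes.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param nElectrodes,nCoils channel counts (defaults 71 EEG / 271 MEG).
#' @param coilOffset distance of the coil sphere from the scalp in mm.
#' @param seed integer; rotates the lattices deterministically.
#' @param coilTilt tilt of the coil axes away from the radial direction, in
#'   degrees (0 = axial/radial convention; nonzero tilts mix in a tangential
#'   component, which makes the sensors sensitive to volume currents in
#'   spherical geometry).
#' @return a [SensorSet-class].
#' @export
placeSensors <- function(mesh, nElectrodes = 71L, nCoils = 271L,
                         coilOffset = 20, seed = 1L, coilTilt = 0) {
  if (nElectrodes <= 0 || nCoils <= 0) stop("sensor counts must be positive")
  if (coilOffset <= 0) stop("coilOffset must be positive")
  nodes <- nodePositions(mesh)
  scalp <- .scalpNodes(mesh)
  if (nElectrodes > length(scalp))
    stop("nElectrodes (", nElectrodes, ") exceeds the number of scalp surface nodes (",
         length(scalp), ")")
  R <- max(.rowNorms(nodes))
  rot <- .seedRotation(seed + 1L)
  targets <- (.fibonacciSphere(nElectrodes) %*% t(rot)) * R
  nn <- .nearestVertex(targets, nodes[scalp, , drop = FALSE])
  idx <- scalp[nn$index]
  # resolve collisions: each electrode needs its own node
  if (anyDuplicated(idx)) {
    used <- logical(nrow(nodes))
    for (i in seq_along(idx)) {
      if (!used[idx[i]]) { used[idx[i]] <- TRUE; next }
      free <- scalp[!used[scalp]]
      j <- .nearestVertex(targets[i, , drop = FALSE], nodes[free, , drop = FALSE])$index
      idx[i] <- free[j]
      used[idx[i]] <- TRUE
    }
  }
  coils <- (.fibonacciSphere(nCoils) %*% t(rot)) * (R + coilOffset)
  axes <- .normalizeRows(coils)
  if (coilTilt != 0) {
    up <- matrix(c(0, 0, 1), nrow(axes), 3, byrow = TRUE)
    pole <- abs(axes[, 3]) > 0.99
    up[pole, ] <- rep(c(1, 0, 0), each = sum(pole))
    t1 <- .normalizeRows(.rowCross(axes, up))
    axes <- cos(coilTilt * pi / 180) * axes + sin(coilTilt * pi / 180) * t1
  }
  new("SensorSet",
      electrodes = nodes[idx, , drop = FALSE],
      electrodeNodes = as.integer(idx),
      coils = coils,
      coilOrientations = axes,
      eegLabels = sprintf("EEG%03d", seq_len(nElectrodes)),
      megLabels = sprintf("MEG%03d", seq_len(nCoils)))
}

#' Synthetic folded cortex surface
#'
#' A radially perturbed icosphere r(n) = baseRadius + foldAmplitude * f(n),
#' where f is a smooth band-limited fold field in [-1, 1] built from a seeded
#' superposition of plane-wave sinusoids of angular frequency
#' 2*pi*foldFrequency (foldFrequency full folds across the diameter, i.e.
#' sulcal wavelength about 2*baseRadius/foldFrequency). The folding produces
#' vertex normals spanning radial to tangential orientations, emulating gyral
#' crowns and sulcal walls.
#'
#' @param baseRadius mean cortex radius in mm.
#' @param foldAmplitude fold depth in mm (0 = perfect sphere).
#' @param foldFrequency integer number of folds across the diameter.
#' @param meshResolution icosphere subdivision level (default 4, 2562 vertices).
#' @param seed integer seed for the fold field.
#' @param maxRadius the surface must stay strictly inside this radius
#'   (innermost head-model shell; default 78 mm).
#' @return a [TriSurface-class].
#' @export
synthCortexSurface <- function(baseRadius = 60, foldAmplitude = 8,
                               foldFrequency = 6L, meshResolution = 4L,
                               seed = 1L, maxRadius = 78) {
  if (baseRadius + foldAmplitude >= maxRadius)
    stop("cortex surface would escape the brain compartment: baseRadius + foldAmplitude must be < maxRadius")
  ico <- icosphere(meshResolution)
  n <- ico$vertices
  if (foldAmplitude == 0) {
    vert <- baseRadius * n
    return(new("TriSurface", vertices = vert, faces = ico$faces, normals = n))
  }
  # fold field: phase-modulated sinusoid pushed towards a square wave so the
  # sulcal walls are steep; smooth, exactly in [-1, 1]
  mMod <- 0.8; steep <- 2
  waves <- .withSeed(seed, {
    list(dirs = .normalizeRows(matrix(stats::rnorm(6), 2, 3)),
         phase = stats::runif(2, 0, 2 * pi))
  })
  k <- pi * foldFrequency
  w1 <- as.numeric(k * (n %*% waves$dirs[1, ]) + waves$phase[1])
  w2 <- as.numeric(k * (n %*% waves$dirs[2, ]) + waves$phase[2])
  g <- sin(w1 + mMod * sin(w2))
  f <- tanh(steep * g) / tanh(steep)
  rho <- baseRadius + foldAmplitude * f
  vert <- rho * n
  # exact normals of the radial graph rho(n) * n: proportional to
  # n - grad_s(rho) / rho, with the fold field differentiated analytically
  dg <- cos(w1 + mMod * sin(w2)) * k *
    (matrix(waves$dirs[1, ], nrow(n), 3, byrow = TRUE) +
     outer(mMod * cos(w2), waves$dirs[2, ]))
  gradRho <- foldAmplitude * (steep / tanh(steep)) / cosh(steep * g)^2 * dg
  tang <- gradRho - n * rowSums(gradRho * n)
  nrm <- .normalizeRows(n - tang / rho)
  if (max(rho) >= maxRadius) stop("cortex surface escapes the brain compartment")
  new("TriSurface", vertices = vert, faces = ico$faces, normals = nrm)
}

#' Triangulated sphere surface (e.g. the inner skull)
#'
#' @param radius sphere radius in mm.
#' @param maxVertexSpacing upper bound on the edge length in mm (controls the
#'   accuracy of nearest-vertex depth/angle metrics).
#' @return a [TriSurface-class] with radial outward normals.
#' @export
sphereSurface <- function(radius, maxVertexSpacing = 2) {
  subdiv <- max(1L, ceiling(log2(1.0515 * radius / maxVertexSpacing)))
  ico <- icosphere(subdiv)
  new("TriSurface", vertices = radius * ico$vertices, faces = ico$faces,
      normals = ico$vertices)
}

#' Default subcortical region layout for the sphere phantom
#'
#' Nine regions named after the subcortical structures of the human brain,
#' placed as balls at anatomically inspired (head-centered, mm) positions
#' well inside the brain compartment.
#'
#' @return data.frame with name, x, y, z, radius.
#' @export
subcorticalLayout <- function() {
  data.frame(
    name = c("cerebellum", "thalamus", "caudate", "putamen", "pallidum",
             "hippocampus", "amygdala", "accumbens area",
             "ventral diencephalon"),
    x = c(0,  0, 12, -24, 20, -28, 24,  8,  0),
    y = c(-45, -10, 12, 0, 0, -20, -5, 12, -5),
    z = c(-20, 5, 5, 0, 0, -10, -15, -8, -10),
    radius = c(14, 8, 5, 6, 4, 6, 4, 3, 5))
}

#' Synthetic subcortical ball regions
#'
#' One small tetrahedral ball mesh per region (icosphere core), strictly
#' inside the brain compartment.
#'
#' @param centers n x 3 matrix of ball centers (mm), or NULL for the default
#'   nine-region layout.
#' @param radii ball radii (mm).
#' @param names region names.
#' @param meshResolution icosphere subdivision of each ball (default 1,
#'   42 surface nodes).
#' @param seed integer seed (rotates each ball's lattice).
#' @param brainRadius radius of the brain compartment the balls must stay
#'   inside (default 78 mm).
#' @return named list of [LabeledTetMesh-class] ball meshes.
#' @export
synthSubcorticalRegions <- function(centers = NULL, radii = NULL, names = NULL,
                                    meshResolution = 1L, seed = 1L,
                                    brainRadius = 78) {
  if (is.null(centers)) {
    lay <- subcorticalLayout()
    centers <- as.matrix(lay[, c("x", "y", "z")])
    radii <- lay$radius
    names <- lay$name
  }
  centers <- .asMatrix3(centers, "centers")
  if (length(radii) != nrow(centers)) stop("one radius per center required")
  if (is.null(names)) names <- paste0("region_", seq_len(nrow(centers)))
  cdist <- .rowNorms(centers)
  out <- any(cdist + radii >= brainRadius)
  if (out)
    stop("subcortical region(s) not strictly inside the brain compartment: ",
         paste(names[cdist + radii >= brainRadius], collapse = ", "))
  res <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ball <- buildLayeredSphereMesh(radii = radii[i],
                                   targetEdgeLength = radii[i],
                                   seed = seed + i,
                                   labelNames = names[i],
                                   subdivisions = meshResolution)
    nodes <- sweep(nodePositions(ball), 2, centers[i, ], "+")
    res[[i]] <- new("LabeledTetMesh", nodes = nodes,
                    elements = meshElements(ball),
                    labels = elementLabels(ball), labelNames = names[i])
  }
  stats::setNames(res, names)
}

#' Synthetic baseline noise recording
#'
#' Zero-mean white Gaussian samples per channel, EEG channels first (uV) then
#' MEG channels (fT), with the requested per-channel variances (optionally
#' log-normal per-channel jitter of the variance).
#'
#' @param sensors a [SensorSet-class].
#' @param eegVariance EEG noise variance in uV^2 (default 10, the order of
#'   magnitude seen in pretrigger baselines of averaged evoked recordings).
#' @param megVariance MEG noise variance in fT^2 (default 1e4).
#' @param nSamples samples per channel (>= 2).
#' @param seed integer seed.
#' @param variancesJitterSd standard deviation of the per-channel
#'   log10-variance jitter (0 = identical variances).
#' @return a [BaselineRecording-class].
#' @export
synthNoiseBaseline <- function(sensors, eegVariance = 10, megVariance = 1e4,
                               nSamples = 10000L, seed = 1L,
                               variancesJitterSd = 0) {
  if (eegVariance <= 0 || megVariance <= 0) stop("variances must be positive")
  if (nSamples < 2) stop("nSamples must be >= 2")
  ne <- nEeg(sensors); nm <- nMeg(sensors)
  .withSeed(seed, {
    v <- c(rep(eegVariance, ne), rep(megVariance, nm))
    if (variancesJitterSd > 0)
      v <- v * 10^stats::rnorm(ne + nm, 0, variancesJitterSd)
    samples <- matrix(stats::rnorm((ne + nm) * nSamples, sd = rep(sqrt(v), nSamples)),
                      nrow = ne + nm)
    rownames(samples) <- c(sensors@eegLabels, sensors@megLabels)
    new("BaselineRecording", samples = samples,
        channelModality = c(rep("eeg", ne), rep("meg", nm)),
        meta = list(seed = seed, eegVariance = eegVariance,
                    megVariance = megVariance))
  })
}
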