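# First-order Lagrangian FEM for the EEG/MEG forward problem: stiffness
# assembly, partial-integration dipole right-hand sides, point-electrode
# restriction, MEG secondary-field integration rows, transfer matrices and
# leadfield computation. Internals are SI (m, S/m, A*m, V, T); meshes arrive
# in mm.

# Per-element P1 shape-function gradients (1/m), volumes (m^3) and centroids
# (m) for a mesh given in mm.
.elementGeometry <- function(mesh) {
  nodes <- nodePositions(mesh) / MM_PER_M
  el <- meshElements(mesh)
  p1 <- nodes[el[, 1], , drop = FALSE]; p2 <- nodes[el[, 2], , drop = FALSE]
  p3 <- nodes[el[, 3], , drop = FALSE]; p4 <- nodes[el[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c3 <- p4 - p1
  v6 <- rowSums(a * .rowCross(b, c3))      # 6 * volume
  if (any(v6 == 0)) stop("degenerate (zero-volume) element(s): ",
                         paste(utils::head(which(v6 == 0), 5), collapse = ", "))
  g2 <- .rowCross(b, c3) / v6
  g3 <- .rowCross(c3, a) / v6
  g4 <- .rowCross(a, b) / v6
  g1 <- -(g2 + g3 + g4)
  list(grads = list(g1, g2, g3, g4), vol = v6 / 6,
       centroids = (p1 + p2 + p3 + p4) / 4, nodes = nodes, elements = el)
}

# sigma * grad(phi_a) per element for each local vertex a (list of m x 3)
.sigmaGrads <- function(geom, conductivity) {
  tn <- conductivityTensors(conductivity)
  lapply(geom$grads, function(g) cbind(
    tn[, 1] * g[, 1] + tn[, 4] * g[, 2] + tn[, 5] * g[, 3],
    tn[, 4] * g[, 1] + tn[, 2] * g[, 2] + tn[, 6] * g[, 3],
    tn[, 5] * g[, 1] + tn[, 6] * g[, 2] + tn[, 3] * g[, 3]))
}

#' Assemble the FEM stiffness matrix
#'
#' Entries K_ij = sum over elements of vol(E) * grad(phi_i) . sigma_E
#' grad(phi_j) with piecewise-linear basis functions (element-wise constant
#' gradients). The result is symmetric positive semi-definite with the
#' constant vector spanning its nullspace (pure Neumann problem).
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param conductivity a [ConductivityField-class] with one tensor per element.
#' @param solver solver settings used downstream: list with `method`
#'   ("cholesky" or "cg"), `tol` (relative residual, default 1e-8) and
#'   `maxit`.
#' @return a [StiffnessSystem-class].
#' @export
assembleStiffness <- function(mesh, conductivity,
                              solver = list(method = "cholesky", tol = 1e-8,
                                            maxit = 10000L)) {
  stopifnot(nrow(conductivityTensors(conductivity)) == nrow(meshElements(mesh)))
  geom <- .elementGeometry(mesh)
  sg <- .sigmaGrads(geom, conductivity)
  el <- geom$elements
  n <- nrow(geom$nodes)
  m <- nrow(el)
  ii <- jj <- integer(16L * m); xx <- numeric(16L * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- k * m + seq_len(m)
    ii[idx] <- el[, a]; jj[idx] <- el[, b]
    xx[idx] <- geom$vol * rowSums(geom$grads[[a]] * sg[[b]])
    k <- k + 1L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  K <- (K + Matrix::t(K)) / 2
  defaults <- list(method = "cholesky", tol = 1e-8, maxit = 10000L)
  solver <- utils::modifyList(defaults, solver)
  new("StiffnessSystem", K = K, solver = solver)
}

#' Locate the host element of each point
#'
#' Brute-force barycentric membership test restricted to elements whose
#' centroid lies within the largest element circumradius of the point; ties
#' (points on shared faces/edges) resolve to the lowest element index.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param points n x 3 positions in mm.
#' @return integer vector of element indices.
#' @export
locateElements <- function(mesh, points) {
  points <- .asMatrix3(points) / MM_PER_M
  geom <- .elementGeometry(mesh)
  cent <- geom$centroids
  el <- geom$elements
  reach <- max(.rowNorms(geom$nodes[el[, 1], , drop = FALSE] - cent),
               .rowNorms(geom$nodes[el[, 2], , drop = FALSE] - cent),
               .rowNorms(geom$nodes[el[, 3], , drop = FALSE] - cent),
               .rowNorms(geom$nodes[el[, 4], , drop = FALSE] - cent))
  out <- integer(nrow(points))
  c2 <- rowSums(cent^2)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    d2 <- c2 - 2 * as.numeric(cent %*% p) + sum(p^2)
    cand <- which(d2 <= (reach * 1.0001)^2)
    cand <- cand[order(cand)]
    hit <- NA_integer_
    for (e in cand) {
      dp <- p - cent[e, ]
      lam <- vapply(1:4, function(a) 0.25 + sum(geom$grads[[a]][e, ] * dp), 0)
      if (all(lam >= -1e-9)) { hit <- e; break }
    }
    if (is.na(hit)) stop("point ", i, " lies outside the mesh")
    out[i] <- hit
  }
  out
}

#' Partial-integration right-hand side for one dipole
#'
#' For the dipole's host element with vertices i the load vector is
#' f_i = q . grad(phi_i), q the dipole moment; all other entries vanish, and
#' the four nonzeros sum to zero since the shape-function gradients do.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param position dipole position in mm (strictly inside some element; ties
#'   break to the lowest element index).
#' @param orientation unit 3-vector.
#' @param momentNAm dipole moment magnitude in nAm (default 1).
#' @param element optional pre-located host element index.
#' @return sparse vector (length = number of nodes) of class
#'   [Matrix::sparseVector-class].
#' @export
partialIntegrationRhs <- function(mesh, position, orientation, momentNAm = 1,
                                  element = NULL) {
  if (is.null(element)) element <- locateElements(mesh, matrix(position, 1))
  geom <- .elementGeometry(mesh)
  q <- as.numeric(orientation) * momentNAm * 1e-9   # A*m
  vals <- vapply(1:4, function(a) sum(geom$grads[[a]][element, ] * q), 0)
  Matrix::sparseVector(x = vals, i = as.integer(meshElements(mesh)[element, ]),
                       length = nrow(nodePositions(mesh)))
}

# nodes x ndipoles sparse RHS matrix, one partial-integration column per
# dipole (momentNAm per unit orientation)
.dipoleRhsMatrix <- function(mesh, dipoles, momentNAm = 1) {
  elements <- dipoles@element
  if (anyNA(elements))
    elements[is.na(elements)] <- locateElements(
      mesh, dipolePositions(dipoles)[is.na(elements), , drop = FALSE])
  geom <- .elementGeometry(mesh)
  q <- dipoleOrientations(dipoles) * momentNAm * 1e-9
  nd <- nDipoles(dipoles)
  el <- meshElements(mesh)[elements, , drop = FALSE]
  ii <- as.integer(el)
  jj <- rep(seq_len(nd), 4L)
  xx <- unlist(lapply(1:4, function(a)
    rowSums(geom$grads[[a]][elements, , drop = FALSE] * q)), use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(nodePositions(mesh)), nd))
}

#' EEG point-electrode restriction matrix
#'
#' One unit entry per electrode at its snapped scalp node (electrodes x
#' nodes). Errors if an electrode position does not coincide with its mesh
#' node within tolerance.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param sensors a [SensorSet-class] with electrodes snapped to scalp nodes.
#' @param tolerance mm.
#' @return sparse matrix (electrodes x nodes).
#' @export
eegRestriction <- function(mesh, sensors, tolerance = 1e-6) {
  nodes <- nodePositions(mesh)
  idx <- sensors@electrodeNodes
  d <- .rowNorms(electrodePositions(sensors) - nodes[idx, , drop = FALSE])
  if (any(d > tolerance))
    stop("electrode(s) not coincident with a mesh node: ",
         paste(which(d > tolerance), collapse = ", "))
  Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                       dims = c(length(idx), nrow(nodes)))
}

#' MEG secondary-field integration rows
#'
#' Row for a coil at r with axis o maps nodal potentials u to the oriented
#' secondary magnetic reading o . B_sec(r), with
#' B_sec(r) = -(mu0/4pi) sum_E sigma_E grad(u)_E x int_E (r-x)/|r-x|^3 dx,
#' the element integrals evaluated with a fixed 4-point quadrature rule.
#'
#' @param mesh a [LabeledTetMesh-class].
#' @param conductivity a [ConductivityField-class].
#' @param sensors a [SensorSet-class]; every coil must be farther from the
#'   mesh than one element diameter (kernel near-singularity guard).
#' @return dense matrix (coils x nodes), in T per V.
#' @export
megIntegrationRows <- function(mesh, conductivity, sensors) {
  geom <- .elementGeometry(mesh)
  sg <- .sigmaGrads(geom, conductivity)
  el <- geom$elements
  nNodes <- nrow(geom$nodes)
  coils <- coilPositions(sensors) / MM_PER_M
  axes <- coilOrientations(sensors)
  # guard: coil strictly outside, farther than one element diameter
  edgeMax <- max(.rowNorms(geom$nodes[el[, 2], , drop = FALSE] -
                           geom$nodes[el[, 1], , drop = FALSE]))
  nn <- .nearestVertex(coils * MM_PER_M, nodePositions(mesh))
  if (any(nn$distance / MM_PER_M <= edgeMax))
    stop("coil(s) closer to the mesh than one element diameter: ",
         paste(which(nn$distance / MM_PER_M <= edgeMax), collapse = ", "))
  # 4-point tetrahedral quadrature, degree 2
  aQ <- 0.5854101966249685; bQ <- 0.1381966011250105
  P <- lapply(1:4, function(a) geom$nodes[el[, a], , drop = FALSE])
  S <- P[[1]] + P[[2]] + P[[3]] + P[[4]]
  Xq <- lapply(1:4, function(j) bQ * S + (aQ - bQ) * P[[j]])
  rows <- matrix(0, nrow(coils), nNodes)
  nodeIdx <- as.integer(el)   # element nodes, local vertex-major
  for (ci in seq_len(nrow(coils))) {
    rc <- coils[ci, ]
    w <- matrix(0, nrow(el), 3)
    for (j in 1:4) {
      d <- sweep(-Xq[[j]], 2, rc, "+")       # rc - x_q
      w <- w + 0.25 * d / .rowNorms(d)^3
    }
    w <- w * geom$vol
    v <- .rowCross(w, matrix(axes[ci, ], nrow(el), 3, byrow = TRUE))
    vals <- unlist(lapply(sg, function(s) rowSums(s * v)), use.names = FALSE)
    acc <- rowsum(vals, nodeIdx)
    rows[ci, as.integer(rownames(acc))] <- -MU0_OVER_4PI * acc[, 1]
  }
  rows
}

#' Primary (infinite-medium) magnetic field of a current dipole
#'
#' o . (mu0/4pi) q x (r - r0) / |r - r0|^3 per coil; with `orientations`
#' NULL the full field vectors are returned.
#'
#' @param position dipole position in mm.
#' @param moment dipole moment 3-vector in nAm.
#' @param points n x 3 field points in mm (distinct from the dipole).
#' @param orientations optional n x 3 unit coil axes.
#' @return numeric vector of oriented readings in fT (or n x 3 field matrix).
#' @export
primaryBField <- function(position, moment, points, orientations = NULL) {
  points <- .asMatrix3(points, "points")
  d <- sweep(points, 2, as.numeric(position)) / MM_PER_M
  dn <- .rowNorms(d)
  if (any(dn < .Machine$double.eps)) stop("field point coincides with the dipole")
  q <- as.numeric(moment) * 1e-9
  B <- MU0_OVER_4PI * .rowCross(matrix(q, nrow(d), 3, byrow = TRUE), d) / dn^3 * 1e15
  if (is.null(orientations)) B else rowSums(B * .asMatrix3(orientations))
}

# ---- linear solvers ---------------------------------------------------------

# Solve K x = b for zero-mean x, b compatible (projected to zero mean).
# Grounding node 1 fixes the constant; the returned solutions are re-centered.
.makeSolver <- function(system) {
  K <- system@K
  n <- nrow(K)
  settings <- system@solver
  if (identical(settings$method, "cg")) {
    d <- Matrix::diag(K)
    d[d <= 0] <- 1
    function(B) {
      B <- as.matrix(B)
      B <- sweep(B, 2, colMeans(B))
      X <- matrix(0, n, ncol(B))
      for (j in seq_len(ncol(B))) {
        b <- B[, j]
        nb <- sqrt(sum(b^2))
        if (nb == 0) next
        x <- numeric(n)
        r <- b
        z <- r / d
        z <- z - mean(z)                   # stay in the compatible subspace
        p <- z
        rz <- sum(r * z)
        for (it in seq_len(settings$maxit)) {
          Kp <- as.numeric(K %*% p)
          alpha <- rz / sum(p * Kp)
          x <- x + alpha * p
          r <- r - alpha * Kp
          r <- r - mean(r)
          if (sqrt(sum(r^2)) <= settings$tol * nb) break
          z <- r / d
          z <- z - mean(z)
          rz2 <- sum(r * z)
          p <- z + (rz2 / rz) * p
          rz <- rz2
        }
        if (sqrt(sum(r^2)) > settings$tol * nb)
          stop(sprintf("CG did not converge: relative residual %.3e after %d iterations",
                       sqrt(sum(r^2)) / nb, settings$maxit))
        x <- x - mean(x)
        X[, j] <- x
      }
      X
    }
  } else {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K[-1, -1, drop = FALSE]),
                           LDL = FALSE)
    function(B) {
      B <- as.matrix(B)
      B <- sweep(B, 2, colMeans(B))
      X2 <- as.matrix(Matrix::solve(ch, B[-1, , drop = FALSE]))
      X <- rbind(0, X2)
      sweep(X, 2, colMeans(X))
    }
  }
}

#' Solve the forward system directly for one or more right-hand sides
#'
#' Direct counterpart of the transfer-matrix path: returns zero-mean nodal
#' potential vectors (V) for the given compatible right-hand sides.
#'
#' @param system a [StiffnessSystem-class].
#' @param rhs numeric vector/matrix or sparse equivalent (nodes x k).
#' @return dense matrix nodes x k.
#' @export
solvePotential <- function(system, rhs) {
  if (inherits(rhs, "sparseVector")) rhs <- as.numeric(rhs)
  if (is.null(dim(rhs))) rhs <- matrix(rhs, ncol = 1)
  .makeSolver(system)(as.matrix(rhs))
}

#' Compute a transfer matrix
#'
#' Each transfer row t_k solves the adjoint system K t_k = r_k^T (r_k the
#' sensor row), with the pure-Neumann nullspace handled by zero-mean
#' projection of right-hand side and solution. Afterwards a single sparse dot
#' product per dipole replaces a full linear solve.
#'
#' @param system a [StiffnessSystem-class].
#' @param sensorRows sensors x nodes mapping ([eegRestriction()] or
#'   [megIntegrationRows()]).
#' @param modality `"eeg"` or `"meg"`.
#' @return a [TransferMatrix-class] (sensors x nodes).
#' @export
computeTransferMatrix <- function(system, sensorRows, modality = c("eeg", "meg")) {
  modality <- match.arg(modality)
  if (ncol(sensorRows) != nrow(system@K))
    stop("sensorRows column count must equal the node count")
  X <- .makeSolver(system)(Matrix::t(sensorRows))
  # contract check: K t = centered rhs to solver tolerance
  Bc <- as.matrix(Matrix::t(sensorRows))
  Bc <- sweep(Bc, 2, colMeans(Bc))
  res <- as.matrix(system@K %*% X) - Bc
  nb <- sqrt(colSums(Bc^2))
  rel <- ifelse(nb > 0, sqrt(colSums(res^2)) / nb, 0)
  if (any(rel > system@solver$tol))
    stop(sprintf("transfer solve exceeded tolerance: max relative residual %.3e",
                 max(rel)))
  new("TransferMatrix", mat = t(X), modality = modality)
}

# ---- leadfields -------------------------------------------------------------

#' Construct a Leadfield container
#'
#' @param mat sensors x dipoles matrix (EEG uV/nAm, MEG fT/nAm).
#' @param modality `"eeg"` or `"meg"`.
#' @param dipoles the [DipoleSet-class] the columns correspond to.
#' @param sensorLabels channel labels (rows).
#' @param units character, e.g. `"uV/nAm"`.
#' @return a [Leadfield-class].
#' @export
Leadfield <- function(mat, modality, dipoles, sensorLabels = NULL,
                      units = if (modality == "eeg") "uV/nAm" else "fT/nAm") {
  cd <- S4Vectors::DataFrame(
    x_mm = dipolePositions(dipoles)[, 1], y_mm = dipolePositions(dipoles)[, 2],
    z_mm = dipolePositions(dipoles)[, 3],
    ox = dipoleOrientations(dipoles)[, 1], oy = dipoleOrientations(dipoles)[, 2],
    oz = dipoleOrientations(dipoles)[, 3],
    group = dipoleGroups(dipoles), class = dipoleClass(dipoles),
    region = dipoleRegions(dipoles), depth_mm = dipoleDepths(dipoles),
    angle_deg = dipoleAngles(dipoles))
  if (!is.null(sensorLabels)) rownames(mat) <- sensorLabels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(leadfield = mat), colData = cd,
    metadata = list(modality = modality, units = units))
  new("Leadfield", se)
}

#' Compute EEG and MEG leadfields for a dipole set
#'
#' EEG columns are average-referenced transfer solutions in uV per nAm; MEG
#' columns are the secondary (volume-current) transfer solutions plus the
#' primary infinite-medium field at each coil, oriented along the coil axes,
#' in fT per nAm. Columns follow the dipole-set order.
#'
#' @param transferEeg [TransferMatrix-class] for the electrodes (or NULL).
#' @param transferMeg [TransferMatrix-class] for the coils (or NULL).
#' @param mesh,dipoles,sensors the model the transfer matrices were built on.
#' @return named list with elements `eeg` and `meg` ([Leadfield-class] or
#'   NULL).
#' @export
computeLeadfield <- function(transferEeg, transferMeg, mesh, dipoles, sensors) {
  rhs <- .dipoleRhsMatrix(mesh, dipoles, momentNAm = 1)
  out <- list(eeg = NULL, meg = NULL)
  if (!is.null(transferEeg)) {
    B <- as.matrix(transferEeg@mat %*% rhs)                 # volts
    B <- sweep(B, 2, colMeans(B))                           # average reference
    out$eeg <- Leadfield(B * 1e6, "eeg", dipoles, sensors@eegLabels)
  }
  if (!is.null(transferMeg)) {
    Bs <- as.matrix(transferMeg@mat %*% rhs)                # tesla (secondary)
    coils <- coilPositions(sensors)
    axes <- coilOrientations(sensors)
    pos <- dipolePositions(dipoles)
    ori <- dipoleOrientations(dipoles)
    Bp <- matrix(0, nrow(coils), nDipoles(dipoles))
    for (i in seq_len(nDipoles(dipoles)))
      Bp[, i] <- primaryBField(pos[i, ], ori[i, ], coils, axes)   # fT
    out$meg <- Leadfield(Bs * 1e15 + Bp, "meg", dipoles, sensors@megLabels)
  }
  out
}
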