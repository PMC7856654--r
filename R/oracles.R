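# Quasi-analytic concentric-sphere solutions used as ground truth for the
# FEM: the multilayer Legendre-series electric potential and the Sarvas
# closed-form magnetic field.

#' Construct a concentric-sphere volume conductor model
#'
#' @param radii strictly increasing shell radii in mm (outer radius last).
#' @param conductivities isotropic conductivity per shell in S/m, innermost
#'   first.
#' @param center sphere center in mm.
#' @return a [SphereModel-class].
#' @export
sphereModel <- function(radii, conductivities, center = c(0, 0, 0)) {
  new("SphereModel", center = as.numeric(center), radii = as.numeric(radii),
      conductivities = as.numeric(conductivities))
}

# Radial two-point solve for one harmonic degree: returns the total exterior
# surface coefficient C_n per unit "primary" amplitude. Radii scaled to the
# outer radius; per-layer basis functions are scaled to their own interfaces
# so matrix entries stay O(1) up to high degree.
.sphereDegreeResponse <- function(n, cs, sigma, rho0) {
  L <- length(cs)                      # cs: scaled interface radii, cs[L] = 1
  lp0 <- if (n == 1) 0 else (n - 1) * log(rho0)   # rho0^(n-1), rho0 = 0 safe
  p <- function(rho) exp(lp0 - (n + 1) * log(rho))
  if (L == 1) {
    A1 <- (n + 1) / n * p(1)
    return(A1 + p(1))
  }
  m <- 2 * L - 1
  M <- matrix(0, m, m)
  rhs <- numeric(m)
  colA <- function(j) if (j == 1) 1L else 2L * (j - 1L)   # A_j column
  colB <- function(j) 2L * j - 1L                          # B_j column (j >= 2)
  # value/derivative of layer j basis at radius rho
  valA <- function(j, rho) (rho / cs[j])^n
  derA <- function(j, rho) n / rho * (rho / cs[j])^n
  valB <- function(j, rho) (rho / cs[j - 1])^(-(n + 1))
  derB <- function(j, rho) -(n + 1) / rho * (rho / cs[j - 1])^(-(n + 1))
  row <- 0L
  for (j in seq_len(L - 1)) {
    r0 <- cs[j]
    row <- row + 1L   # continuity of potential
    M[row, colA(j)] <- valA(j, r0)
    if (j > 1) M[row, colB(j)] <- valB(j, r0)
    M[row, colA(j + 1)] <- -valA(j + 1, r0)
    M[row, colB(j + 1)] <- -valB(j + 1, r0)
    row <- row + 1L   # continuity of normal current
    M[row, colA(j)] <- sigma[j] * derA(j, r0)
    if (j > 1) M[row, colB(j)] <- sigma[j] * derB(j, r0)
    M[row, colA(j + 1)] <- -sigma[j + 1] * derA(j + 1, r0)
    M[row, colB(j + 1)] <- -sigma[j + 1] * derB(j + 1, r0)
    if (j == 1) {
      rhs[row - 1L] <- -p(r0)
      rhs[row] <- sigma[1] * (n + 1) / r0 * p(r0)
    }
  }
  row <- row + 1L       # insulating outer boundary
  M[row, colA(L)] <- derA(L, 1)
  M[row, colB(L)] <- derB(L, 1)
  x <- solve(M, rhs)
  x[colA(L)] * valA(L, 1) + x[colB(L)] * valB(L, 1)
}

#' Electric potential of a dipole in a multilayer concentric sphere
#'
#' Truncated Legendre-series solution of the EEG forward problem in a layered
#' isotropic sphere with insulating exterior. The series is truncated
#' adaptively: summation stops once adding 10 further terms changes every
#' electrode value by less than `tol` relative.
#'
#' @param model a [SphereModel-class].
#' @param position dipole position in mm (strictly inside the innermost
#'   shell; eccentricities above 0.95 are rejected as numerically degenerate).
#' @param moment dipole moment 3-vector in nAm.
#' @param electrodes n x 3 electrode positions in mm, on (or radially
#'   projected onto) the outer surface.
#' @param maxDegree series cap (default 200).
#' @param tol relative stopping tolerance (default 1e-8).
#' @return numeric vector of potentials in uV.
#' @export
eegSpherePotential <- function(model, position, moment, electrodes,
                               maxDegree = 200L, tol = 1e-8) {
  stopifnot(is(model, "SphereModel"))
  electrodes <- .asMatrix3(electrodes, "electrodes")
  b <- as.numeric(position) - model@center
  R <- model@radii[length(model@radii)]
  r0 <- sqrt(sum(b^2))
  if (r0 >= model@radii[1]) stop("dipole must lie strictly inside the innermost shell")
  if (r0 > 0.95 * model@radii[1])
    stop("dipole eccentricity above 0.95: series evaluation rejected as degenerate")
  e <- sweep(electrodes, 2, model@center)
  re <- .rowNorms(e)
  if (any(re < R * (1 - 1e-6)))
    stop("electrodes must lie on or outside the outer surface")
  ehat <- e / re
  cs <- model@radii / R
  sigma <- model@conductivities
  rho0 <- r0 / R

  bhat <- if (r0 > 0) b / r0 else c(0, 0, 1)
  q <- as.numeric(moment) * 1e-9          # nAm -> A*m
  cosg <- pmin(1, pmax(-1, as.numeric(ehat %*% bhat)))
  sing <- sqrt(pmax(0, 1 - cosg^2))
  # in-plane tangential unit vector from dipole axis towards each electrode
  tvec <- ehat - cosg %*% t(bhat)
  tn <- .rowNorms(tvec)
  tvec <- tvec / pmax(tn, .Machine$double.eps)
  tvec[tn < 1e-12, ] <- 0
  mr <- sum(q * bhat)
  mt <- as.numeric(tvec %*% q)

  nE <- nrow(electrodes)
  V <- numeric(nE)
  Pnm2 <- rep(1, nE)        # P_0
  Pnm1 <- cosg              # P_1
  P1nm2 <- rep(0, nE)       # P_0^1
  P1nm1 <- sing             # P_1^1  (convention P_n^1 = sin(g) * P_n'(cos g))
  lastCheck <- V
  for (n in seq_len(maxDegree)) {
    Pn <- if (n == 1) Pnm1 else ((2 * n - 1) * cosg * Pnm1 - (n - 1) * Pnm2) / n
    P1n <- if (n == 1) P1nm1 else ((2 * n - 1) * cosg * P1nm1 - n * P1nm2) / (n - 1)
    Cn <- .sphereDegreeResponse(n, cs, sigma, rho0)
    V <- V + Cn * (n * mr * Pn + mt * P1n)
    if (n > 1) { Pnm2 <- Pnm1; Pnm1 <- Pn; P1nm2 <- P1nm1; P1nm1 <- P1n }
    if (n %% 10 == 0) {
      if (max(abs(V - lastCheck)) <= tol * max(abs(V), .Machine$double.xmin)) break
      lastCheck <- V
    }
  }
  V <- V / (4 * pi * sigma[1] * (R / MM_PER_M)^2)   # volts
  V * 1e6                                           # uV
}

#' Magnetic field of a dipole in a spherically symmetric conductor (Sarvas)
#'
#' Closed-form total magnetic field outside a spherically symmetric volume
#' conductor. Depends only on the sphere center, not on radii or
#' conductivities; radial dipoles produce an exactly vanishing field.
#'
#' @param center sphere center in mm.
#' @param position dipole position in mm.
#' @param moment dipole moment 3-vector in nAm.
#' @param points n x 3 field points in mm, strictly farther from the center
#'   than the dipole.
#' @return n x 3 matrix of magnetic field vectors in fT.
#' @export
megSphereField <- function(center, position, moment, points) {
  points <- .asMatrix3(points, "points")
  r0 <- (as.numeric(position) - as.numeric(center)) / MM_PER_M
  r <- sweep(points, 2, as.numeric(center)) / MM_PER_M
  q <- as.numeric(moment) * 1e-9
  if (any(.rowNorms(r) <= sqrt(sum(r0^2)) + .Machine$double.eps))
    stop("field points must lie strictly outside the sphere containing the dipole")
  a <- sweep(r, 2, r0)
  A <- .rowNorms(a)
  Rn <- .rowNorms(r)
  ar <- rowSums(a * r)
  r0r <- as.numeric(r %*% r0)
  F <- A * (Rn * A + Rn^2 - r0r)
  if (any(abs(F) < 1e-30)) stop("field point on the Sarvas singular line")
  gF <- (A^2 / Rn + ar / A + 2 * A + 2 * Rn) * r -
        outer(A + 2 * Rn + ar / A, r0)
  qxr0 <- .cross3(q, r0)
  Bt <- (F * matrix(qxr0, nrow(r), 3, byrow = TRUE) -
         as.numeric(r %*% qxr0) * gF) / F^2 * MU0_OVER_4PI
  Bt * 1e15   # tesla -> fT
}
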