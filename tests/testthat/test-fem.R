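test_that("single-element stiffness equals the hand-integrated matrix", {
  mesh <- refTetMesh()
  K <- as.matrix(assembleStiffness(mesh, isotropicField(mesh, 1))@K)
  # reference tet (mm): grads (1/m): g2 = (1,0,0)*1e3 etc., g1 = -(1,1,1)*1e3,
  # volume 1/6 mm^3 = 1/6 * 1e-9 m^3 -> K = vol * G^T G
  G <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 1e3
  expect_equal(K, (1e-9 / 6) * G %*% t(G), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("stiffness has the constant nullspace and scales linearly in sigma", {
  sys <- tinySystem()
  ones <- rep(1, nrow(sys@K))
  expect_lt(max(abs(as.numeric(sys@K %*% ones))) / max(abs(sys@K)), 1e-10)
  expect_equal(max(abs(sys@K - Matrix::t(sys@K))), 0)
  K2 <- assembleStiffness(tinyMesh(), isotropicField(tinyMesh(), 2 * 0.33))@K
  expect_equal(as.matrix(K2), 2 * as.matrix(sys@K), tolerance = 1e-12)
})

test_that("degenerate elements are rejected by name", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  mesh <- refTetMesh()
  mesh@nodes <- nodes   # flatten the tet (bypasses validity on purpose)
  expect_error(assembleStiffness(mesh, isotropicField(mesh, 1)),
               "degenerate.*element.*1")
})

test_that("partial-integration RHS matches hand-computed shape gradients", {
  mesh <- refTetMesh()
  f <- as.numeric(partialIntegrationRhs(mesh, c(0.25, 0.25, 0.25), c(1, 0, 0)))
  # x-components of the four gradients, times 1 nAm
  expect_equal(f, c(-1, 1, 0, 0) * 1e3 * 1e-9, tolerance = 1e-15)
  expect_equal(sum(f), 0, tolerance = 1e-24)
  f2 <- as.numeric(partialIntegrationRhs(mesh, c(0.25, 0.25, 0.25), c(1, 0, 0),
                                         momentNAm = 2))
  expect_equal(f2, 2 * f)
  expect_error(partialIntegrationRhs(mesh, c(5, 5, 5), c(1, 0, 0)), "outside")
})

test_that("host-element lookup ties break to the lowest element index", {
  mesh <- tinyMesh()
  el <- meshElements(mesh)
  # a point on the shared face of two elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)], el[, c(1, 3, 4)],
                 el[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  shared <- names(which(table(key) == 2))[1]
  tri <- as.integer(strsplit(shared, "-")[[1]])
  p <- colMeans(nodePositions(mesh)[tri, ])
  eid <- rep(seq_len(nrow(el)), 4)
  owners <- sort(eid[key == shared])
  expect_equal(locateElements(mesh, matrix(p, 1)), owners[1])
  # centroids locate to their own element
  cent <- elementCentroids(mesh)[c(3, 100, 400), ]
  expect_equal(locateElements(mesh, cent), c(3L, 100L, 400L))
})

test_that("EEG restriction is a 0/1 selector with average-reference behavior", {
  mesh <- tinyMesh(); sens <- tinySensors()
  R <- eegRestriction(mesh, sens)
  expect_equal(dim(R), c(10, nrow(nodePositions(mesh))))
  expect_equal(Matrix::rowSums(R), rep(1, 10), ignore_attr = TRUE)
  expect_equal(range(R@x), c(1, 1))
  u <- rep(3.5, nrow(nodePositions(mesh)))
  reading <- as.numeric(R %*% u)
  expect_equal(reading, rep(3.5, 10))
  expect_equal(reading - mean(reading), rep(0, 10))
  bad <- sens
  bad@electrodes[1, ] <- bad@electrodes[1, ] + 5
  expect_error(eegRestriction(mesh, bad), "not coincident")
})

test_that("MEG rows annihilate constants and match a direct Biot-Savart loop", {
  mesh <- tinyMesh(); cond <- tinyCond(); sens <- tinySensors()
  S <- megIntegrationRows(mesh, cond, sens)
  n <- nrow(nodePositions(mesh))
  expect_equal(as.numeric(S %*% rep(2.7, n)), rep(0, nMeg(sens)),
               tolerance = 1e-18)
  set.seed(3)
  u1 <- rnorm(n); u2 <- rnorm(n)
  expect_equal(as.numeric(S %*% (u1 + u2)),
               as.numeric(S %*% u1) + as.numeric(S %*% u2), tolerance = 1e-12)
  # independent direct element-loop quadrature of sigma grad(u) x kernel
  geom <- sensmap:::.elementGeometry(mesh)
  el <- geom$elements
  aQ <- 0.5854101966249685; bQ <- 0.1381966011250105
  direct <- numeric(nMeg(sens))
  for (ci in seq_len(nMeg(sens))) {
    rc <- coilPositions(sens)[ci, ] / 1e3
    o <- coilOrientations(sens)[ci, ]
    acc <- 0
    for (e in seq_len(nrow(el))) {
      gu <- c(0, 0, 0)
      for (a in 1:4) gu <- gu + geom$grads[[a]][e, ] * u1[el[e, a]]
      j <- 0.33 * gu
      w <- c(0, 0, 0)
      verts <- geom$nodes[el[e, ], ]
      for (qp in 1:4) {
        lam <- rep(bQ, 4); lam[qp] <- aQ
        x <- colSums(lam * verts)
        d <- rc - x
        w <- w + 0.25 * d / sqrt(sum(d^2))^3
      }
      w <- w * geom$vol[e]
      acc <- acc + -1e-7 * sum(o * c(j[2] * w[3] - j[3] * w[2],
                                     j[3] * w[1] - j[1] * w[3],
                                     j[1] * w[2] - j[2] * w[1]))
    }
    direct[ci] <- acc
  }
  expect_equal(as.numeric(S %*% u1), direct, tolerance = 1e-10)
  # coil too close to the mesh triggers the near-singularity guard
  close <- tinySensors()
  close@coils[1, ] <- close@coils[1, ] * 92.5 / sqrt(sum(close@coils[1, ]^2))
  expect_error(megIntegrationRows(mesh, cond, close), "element diameter")
})

test_that("primary field obeys the cross-product kernel", {
  expect_equal(primaryBField(c(0, 0, 0), c(0, 0, 10),
                             matrix(c(0, 0, 100), 1), matrix(c(0, 1, 0), 1)),
               0)   # moment parallel to the separation
  # independent closed-form evaluation: q = 10 nAm x, r = 100 mm z, o = y
  got <- primaryBField(c(0, 0, 0), c(10, 0, 0),
                       matrix(c(0, 0, 100), 1), matrix(c(0, 1, 0), 1))
  qv <- c(10e-9, 0, 0); rv <- c(0, 0, 0.1)
  bref <- 1e-7 * c(qv[2] * rv[3] - qv[3] * rv[2],
                   qv[3] * rv[1] - qv[1] * rv[3],
                   qv[1] * rv[2] - qv[2] * rv[1]) / sqrt(sum(rv^2))^3 * 1e15
  expect_equal(got, bref[2])
  # doubling the distance along the ray scales the reading by 1/4
  r1 <- primaryBField(c(0, 0, 0), c(10, 0, 0), matrix(c(0, 0, 100), 1),
                      matrix(c(0, 1, 0), 1))
  r2 <- primaryBField(c(0, 0, 0), c(10, 0, 0), matrix(c(0, 0, 200), 1),
                      matrix(c(0, 1, 0), 1))
  expect_equal(r2, r1 / 4, tolerance = 1e-12)
  expect_error(primaryBField(c(0, 0, 100), c(1, 0, 0), matrix(c(0, 0, 100), 1)),
               "coincides")
})

test_that("transfer rows reproduce direct solves for every sensor/dipole pair", {
  mesh <- tinyMesh(); sys <- tinySystem(); sens <- tinySensors()
  R <- eegRestriction(mesh, sens)
  Tr <- computeTransferMatrix(sys, R, "eeg")
  expect_equal(dim(Tr@mat), c(10, nrow(nodePositions(mesh))))
  set.seed(11)
  for (k in 1:6) {
    pos <- runif(3, -40, 40)
    ori <- rnorm(3); ori <- ori / sqrt(sum(ori^2))
    f <- partialIntegrationRhs(mesh, pos, ori)
    u <- solvePotential(sys, f)
    direct <- as.numeric(R %*% u)
    viaT <- as.numeric(Tr@mat %*% as.numeric(f))
    expect_equal(viaT - mean(viaT), direct - mean(direct), tolerance = 1e-9)
  }
  # zero sensor row -> zero transfer row
  R0 <- rbind(R, 0)
  T0 <- computeTransferMatrix(sys, R0, "eeg")
  expect_equal(max(abs(T0@mat[11, ])), 0)
  expect_error(computeTransferMatrix(sys, R[, -1], "eeg"), "node count")
})

test_that("CG and Cholesky solvers agree", {
  mesh <- tinyMesh()
  sysCG <- assembleStiffness(mesh, tinyCond(),
                             solver = list(method = "cg", tol = 1e-10))
  R <- eegRestriction(mesh, tinySensors())
  a <- computeTransferMatrix(sysCG, R, "eeg")@mat
  b <- computeTransferMatrix(tinySystem(), R, "eeg")@mat
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-6)
})

test_that("leadfields are average-referenced, orientation-linear and 1/sigma", {
  mesh <- tinyMesh(); sys <- tinySystem(); sens <- tinySensors()
  Teeg <- computeTransferMatrix(sys, eegRestriction(mesh, sens), "eeg")
  Tmeg <- computeTransferMatrix(sys, megIntegrationRows(mesh, tinyCond(), sens),
                                "meg")
  dip <- dipoleSet(rbind(c(0, 0, 30), c(0, 0, 30), c(20, 10, -15)),
                   rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1)))
  lf <- computeLeadfield(Teeg, Tmeg, mesh, dip, sens)
  Be <- leadfieldMatrix(lf$eeg); Bm <- leadfieldMatrix(lf$meg)
  expect_equal(colMeans(Be), rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(Be[, 2], -Be[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(Bm[, 2], -Bm[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  expect_s4_class(lf$eeg, "Leadfield")
  expect_equal(modality(lf$meg), "meg")
  # conductivity scaling: sigma -> c sigma scales potentials by 1/c
  sys2 <- assembleStiffness(mesh, isotropicField(mesh, 3 * 0.33))
  Teeg2 <- computeTransferMatrix(sys2, eegRestriction(mesh, sens), "eeg")
  lf2 <- computeLeadfield(Teeg2, NULL, mesh, dip, sens)
  expect_equal(leadfieldMatrix(lf2$eeg), Be / 3, tolerance = 1e-9,
               ignore_attr = TRUE)
})
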