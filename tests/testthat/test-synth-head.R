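test_that("layered sphere mesh fills the outer sphere with decreasing volume error", {
  exact <- 4 / 3 * pi * 92^3
  coarse <- buildLayeredSphereMesh(c(78, 80, 86, 92), 16, seed = 1)
  fine <- buildLayeredSphereMesh(c(78, 80, 86, 92), 6, seed = 1)
  errCoarse <- abs(sum(elementVolumes(coarse)) - exact) / exact
  errFine <- abs(sum(elementVolumes(fine)) - exact) / exact
  expect_lt(errCoarse, 0.06)
  expect_lt(errFine, 0.03)    # the 6 mm study resolution is within 3%
  expect_lt(errFine, errCoarse)
})

test_that("mesh labels follow centroid radii, innermost first", {
  mesh <- smallFourShell()
  r <- sqrt(rowSums(elementCentroids(mesh)^2))
  lab <- elementLabels(mesh)
  radii <- c(78, 80, 86, 92)
  expect_identical(labelNames(mesh), c("brain", "csf", "skull", "scalp"))
  # brute-force check over every element
  expect_identical(lab, as.integer(pmin(findInterval(r, radii) + 1L, 4L)))
  expect_true(all(lab[r < 78] == 1L))
  one <- buildLayeredSphereMesh(92, 25, seed = 1)
  expect_identical(unique(elementLabels(one)), 1L)
})

test_that("mesh generation is deterministic per seed and validates inputs", {
  a <- buildLayeredSphereMesh(92, 30, seed = 7)
  b <- buildLayeredSphereMesh(92, 30, seed = 7)
  c3 <- buildLayeredSphereMesh(92, 30, seed = 8)
  expect_identical(nodePositions(a), nodePositions(b))
  expect_false(isTRUE(all.equal(nodePositions(a), nodePositions(c3))))
  expect_error(buildLayeredSphereMesh(c(80, 78), 6), "strictly increasing")
  expect_error(buildLayeredSphereMesh(c(78, 92), 80), "innermost shell radius")
  expect_error(buildLayeredSphereMesh(92, -1), "positive")
})

test_that("mesh is conforming: interior faces shared by exactly two tets", {
  mesh <- tinyMesh()
  el <- meshElements(mesh)
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)], el[, c(1, 3, 4)],
                 el[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  counts <- table(table(key))
  expect_true(all(names(counts) %in% c("1", "2")))
  # boundary faces (count 1) must equal the outer surface triangle count
  nb <- sum(table(key) == 1)
  expect_gt(nb, 0)
})

test_that("each compartment is face-connected", {
  skip_if_not_installed("igraph")
  # angular resolution fine enough that the chord sag stays below the 2 mm
  # CSF shell thickness, so centroid-radius labels form clean bands
  mesh <- buildLayeredSphereMesh(c(78, 80, 86, 92), 16, seed = 1,
                                 subdivisions = 3)
  el <- meshElements(mesh)
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)], el[, c(1, 3, 4)],
                 el[, c(2, 3, 4)])
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- faces[, 1] + faces[, 2] + faces[, 3] - s1 - s3
  N <- nrow(nodePositions(mesh)) + 1
  key <- (s1 * N + s2) * N + s3
  eid <- rep(seq_len(nrow(el)), 4)
  shared <- split(eid, key)
  shared <- shared[lengths(shared) == 2]
  pairs <- do.call(rbind, shared)
  for (lab in unique(elementLabels(mesh))) {
    inlab <- elementLabels(mesh) == lab
    keep <- inlab[pairs[, 1]] & inlab[pairs[, 2]]
    g <- igraph::graph_from_edgelist(
      matrix(match(pairs[keep, ], which(inlab)), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, sum(inlab) - igraph::vcount(g))
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("conductivity assignment reproduces the variant tables", {
  mesh <- smallFourShell()
  lab <- elementLabels(mesh)
  f4 <- assignConductivities(mesh, "4CI")
  tn4 <- conductivityTensors(f4)
  expect_true(all(tn4[lab == 2, 1:3] == 1.79))     # CSF
  expect_true(all(tn4[lab == 1, 1:3] == 0.33))     # brain
  expect_true(all(tn4[lab == 3, 1:3] == 0.01))
  expect_true(all(tn4[lab == 4, 1:3] == 0.43))
  expect_true(all(tn4[, 4:6] == 0))                # isotropic
  f3 <- assignConductivities(mesh, "3CI")
  tn3 <- conductivityTensors(f3)
  expect_true(all(tn3[lab == 2, 1:3] == 0.33))     # CSF relabeled as brain
  expect_true(all(tn3[lab == 3, 1:3] == 0.01))
  expect_true(all(tn3[, 4:6] == 0))
  expect_error(assignConductivities(mesh, "6CA"), "white")
})

test_that("6CA white matter tensors are anisotropic with the reference mean", {
  mesh <- buildLayeredSphereMesh(canonicalRadii(6), 20, seed = 2)
  f6 <- assignConductivities(mesh, "6CA")
  tn <- conductivityTensors(f6)
  wm <- elementLabels(mesh) == 1L
  expect_gt(sum(wm), 0)
  # mean eigenvalue = trace / 3 = 0.14 for every white-matter element
  expect_equal(rowSums(tn[wm, 1:3, drop = FALSE]) / 3, rep(0.14, sum(wm)),
               tolerance = 1e-12)
  expect_true(any(tn[wm, 4:6] != 0))
  expect_true(all(tn[elementLabels(mesh) == 2L, 1:3] == 0.33))   # gray
  expect_true(all(tn[elementLabels(mesh) == 4L, 1:3] == 0.025))  # spongiosa
  expect_true(all(tn[elementLabels(mesh) == 5L, 1:3] == 0.008))  # compacta
})

test_that("anisotropic tensor construction satisfies ratio and mean constraints", {
  expect_equal(makeAnisotropicTensor(c(0, 0, 1), 0.2, 1), 0.2 * diag(3))
  Tn <- makeAnisotropicTensor(c(1, 1, 0), 0.14, 10)
  ev <- eigen(Tn, symmetric = TRUE)
  # hand-solved 2x2 system: lambda_t = 3*0.14/12, lambda_l = 10*lambda_t
  expect_equal(sort(ev$values), sort(c(0.35, 0.035, 0.035)), tolerance = 1e-12)
  expect_equal(mean(ev$values), 0.14, tolerance = 1e-12)
  d <- ev$vectors[, which.max(ev$values)]
  expect_equal(abs(sum(d * c(1, 1, 0) / sqrt(2))), 1, tolerance = 1e-12)
  expect_equal(Tn, t(Tn))
  expect_error(makeAnisotropicTensor(c(0, 0, 0), 0.14, 10), "nonzero")
  expect_error(makeAnisotropicTensor(c(0, 0, 1), -1, 10), "positive")
})

test_that("sensor placement snaps electrodes to scalp nodes and offsets coils", {
  mesh <- smallFourShell()
  s <- placeSensors(mesh, 20, 30, 20, seed = 3)
  expect_equal(nEeg(s), 20)
  expect_equal(nMeg(s), 30)
  expect_equal(electrodePositions(s),
               nodePositions(mesh)[s@electrodeNodes, ], ignore_attr = TRUE)
  expect_true(all(abs(sqrt(rowSums(coilPositions(s)^2)) - 112) < 0.1))
  expect_true(all(abs(sqrt(rowSums(coilOrientations(s)^2)) - 1) < 1e-9))
  d <- as.matrix(dist(electrodePositions(s)))
  expect_gt(min(d[upper.tri(d)]), 0)
  expect_error(placeSensors(mesh, 1e6, 10, 20), "scalp surface nodes")
})

test_that("folded cortex spans radial to tangential normals; sphere limit is radial", {
  flat <- synthCortexSurface(60, 0, 6, 3, seed = 1)
  rad <- flat@vertices / sqrt(rowSums(flat@vertices^2))
  expect_lt(max(rowAngles(surfaceNormals(flat), rad)), 1e-3)
  ctx <- synthCortexSurface(60, 8, 6, 4, seed = 1)
  rad <- ctx@vertices / sqrt(rowSums(ctx@vertices^2))
  ang <- rowAngles(surfaceNormals(ctx), rad)
  expect_gt(mean(ang > 60), 0.10)
  expect_true(all(sqrt(rowSums(surfaceVertices(ctx)^2)) < 78))
  expect_error(synthCortexSurface(72, 8, 6, 3), "escape")
})

test_that("subcortical regions are balls strictly inside the brain", {
  regs <- synthSubcorticalRegions(seed = 4)
  expect_length(regs, 9)
  expect_setequal(names(regs),
                  c("cerebellum", "thalamus", "caudate", "putamen", "pallidum",
                    "hippocampus", "amygdala", "accumbens area",
                    "ventral diencephalon"))
  lay <- subcorticalLayout()
  for (i in seq_len(nrow(lay))) {
    nd <- nodePositions(regs[[lay$name[i]]])
    ctr <- as.numeric(lay[i, c("x", "y", "z")])
    expect_lte(max(sqrt(rowSums(sweep(nd, 2, ctr)^2))), lay$radius[i] + 1e-9)
    expect_true(all(sqrt(rowSums(nd^2)) < 78))
  }
  # two disjoint balls keep disjoint node sets
  two <- synthSubcorticalRegions(centers = rbind(c(-20, 0, 0), c(20, 0, 0)),
                                 radii = c(5, 5), names = c("a", "b"), seed = 1)
  da <- nodePositions(two$a); db <- nodePositions(two$b)
  expect_gt(min(sqrt(outer(rowSums(da^2), rowSums(db^2), "+") -
                     2 * da %*% t(db))), 0)
  expect_error(
    synthSubcorticalRegions(centers = matrix(c(70, 0, 0), 1), radii = 20,
                            names = "bad", seed = 1),
    "strictly inside")
})

test_that("baseline noise matches requested variances and is reproducible", {
  mesh <- tinyMesh()
  s <- placeSensors(mesh, 8, 8, 25, seed = 1)
  b1 <- synthNoiseBaseline(s, 10, 1e4, 10000L, seed = 11)
  b2 <- synthNoiseBaseline(s, 10, 1e4, 10000L, seed = 11)
  expect_identical(b1@samples, b2@samples)
  v <- apply(b1@samples, 1, var)
  expect_true(all(abs(v[1:8] - 10) / 10 < 0.1))
  expect_true(all(abs(v[9:16] - 1e4) / 1e4 < 0.1))
  expect_identical(dim(synthNoiseBaseline(s, 1, 1, 2L, seed = 1)@samples),
                   c(16L, 2L))
  # Monte-Carlo convergence: median absolute deviation shrinks with n
  small <- synthNoiseBaseline(s, 10, 1e4, 200L, seed = 5)
  big <- synthNoiseBaseline(s, 10, 1e4, 20000L, seed = 5)
  devSmall <- median(abs(apply(small@samples[1:8, ], 1, var) - 10))
  devBig <- median(abs(apply(big@samples[1:8, ], 1, var) - 10))
  expect_lt(devBig, devSmall)
  expect_error(synthNoiseBaseline(s, -1, 1, 100L), "positive")
  expect_error(synthNoiseBaseline(s, 1, 1, 1L), "nSamples")
})
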