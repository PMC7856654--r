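test_that("noise variance estimation is the unbiased sample variance", {
  b <- new("BaselineRecording", samples = rbind(c(-1, 1), c(0, 0.5)),
           channelModality = c("eeg", "eeg"), meta = list())
  nm <- estimateNoiseVariance(b)
  expect_equal(unname(nm$variances[1]), 2)          # hand arithmetic, n - 1
  expect_equal(unname(nm$variances[2]), 0.125)
  one <- new("BaselineRecording", samples = matrix(1, 1, 1),
             channelModality = "eeg", meta = list())
  expect_error(estimateNoiseVariance(one), "2 baseline samples")
})

test_that("SNR map implements the dB formula exactly", {
  # N = 1, a * b = s: signal std equals noise std -> 0 dB
  expect_equal(snrMap(matrix(0.5, 1, 1), noiseVariances = 25, amplitude = 10), 0)
  # N = 1, a = 10 nAm, b = 1 uV/nAm, s^2 = 10 uV^2 -> 10 dB
  expect_equal(snrMap(matrix(1, 1, 1), 10, amplitude = 10), 10)
  set.seed(2)
  b <- matrix(rnorm(50), 10)
  s2 <- runif(10, 1, 4)
  snr1 <- snrMap(b, s2, amplitude = 10)
  expect_equal(snrMap(b, s2, amplitude = 20) - snr1,
               rep(20 * log10(2), 5), tolerance = 1e-12)
  # homogeneity: scaling leadfield and noise std jointly leaves SNR unchanged
  expect_equal(snrMap(3.7 * b, 3.7^2 * s2, amplitude = 10), snr1,
               tolerance = 1e-12)
  # monotonicity: inflating one channel's variance decreases every SNR
  s2b <- s2; s2b[4] <- s2b[4] * 5
  expect_true(all(snrMap(b, s2b, amplitude = 10) < snr1))
  # zero column -> -Inf sentinel, not an error
  b0 <- b; b0[, 2] <- 0
  expect_equal(snrMap(b0, s2)[2], -Inf)
  expect_error(snrMap(b, c(s2[-10], 0)), "positive")
  expect_error(snrMap(b, s2[-1]), "per leadfield row")
})

test_that("differential SNR is an antisymmetric elementwise difference", {
  expect_equal(differentialSnr(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(differentialSnr(12, 5), 7)
  a <- c(3, -4, 0.5); b <- c(1, 1, 1)
  expect_equal(differentialSnr(a, b), -differentialSnr(b, a))
  expect_error(differentialSnr(1:3, 1:2), "same dipole set")
})

test_that("SVD projection recovers structure of synthetic leadfields", {
  # orthogonal columns with norms 3, 2, 1: already an SVD
  L <- cbind(c(3, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 1, 0))
  pr <- svdProject(L)
  expect_equal(pr$d, c(3, 2, 1))
  expect_equal(abs(pr$v), diag(3), tolerance = 1e-12)
  # sign convention: largest-magnitude entry of each V column positive
  expect_true(all(apply(pr$v, 2, function(col) col[which.max(abs(col))] > 0)))
  # rank-2 matrix: third singular value 0
  L2 <- cbind(c(1, 2, 0), c(0, 1, 1), c(1, 3, 1))
  expect_equal(svdProject(L2)$d[3], 0, tolerance = 1e-12)
  # projection reconstructs L when recombined
  set.seed(4)
  L3 <- matrix(rnorm(30), 10)
  pr3 <- svdProject(L3)
  expect_equal(pr3$meg %*% t(pr3$v), L3, tolerance = 1e-10)
  expect_error(svdProject(matrix(0, 4, 3)), "rank-0")
})

test_that("SVD radial direction matches the Sarvas nullspace", {
  coils <- 100 * sensmap:::.fibonacciSphere(271)
  axes <- coils / 100
  for (ecc in c(0.3, 0.6, 0.85)) {
    pos <- c(20, -10, 1) / sqrt(sum(c(20, -10, 1)^2)) * 80 * ecc
    L <- vapply(1:3, function(d) {
      m <- c(0, 0, 0); m[d] <- 1
      rowSums(megSphereField(c(0, 0, 0), pos, m, coils) * axes)
    }, numeric(271))
    v3 <- svdProject(L)$v[, 3]
    expect_gt(abs(sum(v3 * pos / sqrt(sum(pos^2)))), 0.95)
  }
})

test_that("projected component energy is conserved", {
  set.seed(9)
  L <- matrix(rnorm(36), 12)
  # homogeneous noise: orthogonal projection preserves sum_k b^2 / s^2
  pr <- svdProject(L)
  expect_equal(sum(pr$meg^2) / 4, sum(L^2) / 4, tolerance = 1e-10)
  # heterogeneous noise via the whitened variant
  s <- runif(12, 0.5, 2)
  prw <- svdProject(L, whiten = s)
  expect_equal(sum((prw$meg / s)^2), sum((L / s)^2), tolerance = 1e-10)
})

test_that("subcortical projection yields per-component SNR rows", {
  set.seed(21)
  nE <- 8L; nM <- 12L
  pos <- rbind(c(10, 0, 0), c(0, -15, 5))
  regs <- synthSubcorticalRegions(centers = pos, radii = c(4, 4),
                                  names = c("a", "b"), seed = 2)
  dip <- subcorticalDipolesFromRegions(regs)
  Be <- matrix(rnorm(nE * nDipoles(dip)), nE)
  Bm <- matrix(rnorm(nM * nDipoles(dip)), nM)
  lfE <- Leadfield(Be, "eeg", dip)
  lfM <- Leadfield(Bm, "meg", dip)
  out <- projectSubcortical(lfE, lfM, rep(10, nE), rep(1e4, nM))
  expect_equal(nrow(out), 3 * length(unique(dipoleGroups(dip))))
  expect_setequal(unique(out$component),
                  c("tangential1", "tangential2", "radial"))
  expect_equal(out$diff_snr, out$snr_meg - out$snr_eeg)
  # singular values descending within each group
  for (g in unique(out$group))
    expect_false(is.unsorted(rev(out$singular_value[out$group == g])))
})

test_that("binned SNR summaries match direct order-statistics computation", {
  snr <- c(5, 7, 9, 11, 2, 4, 6, 8, 10, 12)
  cov <- c(1, 1, 1, 1, 1, 9, 9, 9, 9, 9)
  s <- summarizeByBins(snr, cov, nBins = 2, range = c(0, 10))
  lowBin <- sort(snr[cov < 5]); hiBin <- sort(snr[cov >= 5])
  expect_equal(unlist(s[1, c("min", "q1", "median", "q3", "max")]),
               unname(quantile(lowBin, c(0, .25, .5, .75, 1))),
               ignore_attr = TRUE)
  expect_equal(unlist(s[2, c("min", "q1", "median", "q3", "max")]),
               unname(quantile(hiBin, c(0, .25, .5, .75, 1))),
               ignore_attr = TRUE)
  # single bin summarizes the whole vector; constant data collapse
  one <- summarizeByBins(snr, cov, nBins = 1, range = c(0, 10))
  expect_equal(one$median, median(snr))
  const <- summarizeByBins(rep(3, 6), 1:6, nBins = 2, range = c(0, 6))
  expect_equal(unlist(const[1, c("min", "q1", "median", "q3", "max")]),
               rep(3, 5), ignore_attr = TRUE)
  # -Inf sentinels excluded
  s2 <- summarizeByBins(c(snr, -Inf), c(cov, 1), nBins = 2, range = c(0, 10))
  expect_equal(s2$count, s$count)
})

test_that("heat maps are column-normalized joint histograms", {
  # 6 hand-placed points on a 2 x 3 grid
  snr <- c(0.5, 0.5, 1.5, 0.5, 1.5, 1.5)
  cov <- c(0.5, 0.5, 0.5, 1.5, 2.5, 2.5)
  hm <- heatmapByColumn(snr, cov, snrBins = 2, covariateBins = 3,
                        snrRange = c(0, 2), covariateRange = c(0, 3))
  expect_equal(hm$matrix, rbind(c(2 / 3, 1, 0), c(1 / 3, 0, 1)))
  expect_equal(colSums(hm$matrix), rep(1, 3))
  # all mass in one cell
  hm2 <- heatmapByColumn(rep(1, 5), rep(1, 5), 2, 2, c(0, 2), c(0, 2))
  expect_equal(sum(hm2$matrix == 1), 1)
  expect_equal(sum(hm2$matrix), 1)
  # empty columns stay zero; nonempty sum to one
  hm3 <- heatmapByColumn(runif(20), runif(20, 0, 0.3), 4, 5,
                         c(0, 1), c(0, 1))
  cs <- colSums(hm3$matrix)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
})
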