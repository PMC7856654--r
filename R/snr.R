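# SNR maps: per-channel noise variances from baseline recordings, the
# per-dipole SNR in dB, differential (MEG minus EEG) maps, the SVD-based
# radial/tangential projection of subcortical leadfields, and the binned
# summary representations.

#' Estimate per-channel noise variances from a baseline recording
#'
#' Unbiased (n - 1) sample variance per channel.
#'
#' @param baseline a [BaselineRecording-class] with at least 2 samples.
#' @return list with `variances` (named numeric, uV^2 for EEG channels, fT^2
#'   for MEG channels) and `modality` (character per channel).
#' @export
estimateNoiseVariance <- function(baseline) {
  x <- baseline@samples
  if (ncol(x) < 2) stop("at least 2 baseline samples per channel required")
  v <- apply(x, 1, stats::var)
  list(variances = v, modality = baseline@channelModality)
}

#' Per-dipole SNR map in dB
#'
#' SNR_i = 10 log10( a^2 / N * sum_k b_ki^2 / s_k^2 ), with a the source
#' amplitude in nAm, b the leadfield in sensor units per nAm and s_k^2 the
#' per-channel noise variance in squared sensor units. Dipoles with an
#' exactly zero leadfield column yield -Inf (sentinel, not an error).
#'
#' @param leadfield a [Leadfield-class] (or plain sensors x dipoles matrix).
#' @param noiseVariances numeric vector, one positive variance per channel.
#' @param amplitude source amplitude in nAm (default 10).
#' @return numeric vector of SNR values in dB.
#' @export
snrMap <- function(leadfield, noiseVariances, amplitude = 10) {
  b <- if (is(leadfield, "Leadfield")) leadfieldMatrix(leadfield) else leadfield
  if (length(noiseVariances) != nrow(b))
    stop("one noise variance per leadfield row (channel) required")
  if (any(noiseVariances <= 0)) stop("noise variances must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  N <- nrow(b)
  power <- amplitude^2 / N * colSums(b^2 / noiseVariances)
  10 * log10(power)
}

#' Differential SNR map (MEG minus EEG)
#'
#' D_i = SNR_MEG_i - SNR_EEG_i per dipole; positive values mark dipoles the
#' MEG is more sensitive to.
#'
#' @param snrMeg,snrEeg numeric vectors over the same dipole set.
#' @return numeric vector in dB.
#' @export
differentialSnr <- function(snrMeg, snrEeg) {
  if (length(snrMeg) != length(snrEeg))
    stop("SNR maps must cover the same dipole set")
  snrMeg - snrEeg
}

#' SVD-based radial/tangential projection of one subcortical group
#'
#' The MEG leadfield L (n x 3, Cartesian orientation columns of one source
#' node) is decomposed L = U S V^T; the third column of V (smallest singular
#' value) is the quasi-radial source direction, to which the MEG is nearly
#' blind. Both modalities' leadfields are projected onto V's columns, giving
#' two tangential and one radial component column each. V columns are
#' sign-fixed so their largest-magnitude entry is positive.
#'
#' @param megGroup n_meg x 3 matrix (Cartesian columns of one group).
#' @param eegGroup n_eeg x 3 matrix for the same group (or NULL).
#' @param whiten optional length-n_meg noise standard deviations; if given
#'   the SVD is taken on the row-whitened MEG leadfield (the default follows
#'   the unwhitened convention).
#' @return list with `u`, `d` (descending singular values), `v` (3 x 3),
#'   `meg` and `eeg` (n x 3 projected leadfields, columns tangential1,
#'   tangential2, radial).
#' @export
svdProject <- function(megGroup, eegGroup = NULL, whiten = NULL) {
  megGroup <- as.matrix(megGroup)
  if (ncol(megGroup) != 3L) stop("megGroup must have 3 Cartesian columns")
  M <- if (is.null(whiten)) megGroup else megGroup / whiten
  if (all(M == 0)) stop("rank-0 MEG leadfield group")
  s <- svd(M)
  flip <- vapply(1:3, function(j) {
    col <- s$v[, j]
    if (col[which.max(abs(col))] < 0) -1 else 1
  }, 0)
  v <- sweep(s$v, 2, flip, "*")
  u <- sweep(s$u, 2, flip, "*")
  list(u = u, d = s$d, v = v,
       meg = megGroup %*% v,
       eeg = if (is.null(eegGroup)) NULL else as.matrix(eegGroup) %*% v)
}

#' Project all subcortical groups of a leadfield pair
#'
#' Applies [svdProject()] to every subcortical group (Cartesian triplet) and
#' returns per-group radial/tangential component columns plus component SNR
#' values (amplitude applied to the unit-norm projected orientation, matching
#' the cortical convention).
#'
#' @param lfEeg,lfMeg [Leadfield-class] objects over the same dipole set.
#' @param noiseEeg,noiseMeg per-channel noise variances.
#' @param amplitude source amplitude in nAm.
#' @return data.frame with one row per (group, component): region, group,
#'   component ("tangential1", "tangential2", "radial"), singular value,
#'   snr_eeg, snr_meg, diff_snr.
#' @export
projectSubcortical <- function(lfEeg, lfMeg, noiseEeg, noiseMeg,
                               amplitude = 10) {
  cd <- SummarizedExperiment::colData(lfMeg)
  sub <- which(cd$class == "subcortical")
  if (!length(sub)) stop("leadfield contains no subcortical dipoles")
  Be <- leadfieldMatrix(lfEeg); Bm <- leadfieldMatrix(lfMeg)
  groups <- split(sub, cd$group[sub])
  comp <- c("tangential1", "tangential2", "radial")
  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    cols <- groups[[gi]]
    stopifnot(length(cols) == 3L)
    pr <- svdProject(Bm[, cols, drop = FALSE], Be[, cols, drop = FALSE])
    se <- snrMap(pr$eeg, noiseEeg, amplitude)
    sm <- snrMap(pr$meg, noiseMeg, amplitude)
    res[[gi]] <- data.frame(
      region = cd$region[cols[1]], group = cd$group[cols[1]],
      component = comp, singular_value = pr$d,
      snr_eeg = se, snr_meg = sm, diff_snr = sm - se)
  }
  do.call(rbind, res)
}

#' Five-number SNR summaries per covariate bin
#'
#' @param snr numeric SNR values (dB); -Inf sentinels are excluded.
#' @param covariate numeric covariate (depth in mm or angle in degrees).
#' @param nBins number of bins (default 5).
#' @param range covariate bin range (e.g. c(0, 50) mm or c(0, 180) degrees).
#' @return data.frame as in [binValues()] summaries.
#' @export
summarizeByBins <- function(snr, covariate, nBins = 5L, range = NULL) {
  if (length(snr) != length(covariate)) stop("snr and covariate lengths differ")
  keep <- is.finite(snr)
  bins <- binValues(covariate[keep], nBins = nBins, range = range)
  idx <- bins$assignment
  v <- snr[keep]
  summ <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    x <- v[!is.na(idx) & idx == b]
    if (!length(x))
      return(data.frame(bin = b, lo = bins$edges[b], hi = bins$edges[b + 1],
                        count = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_))
    f <- .fiveNum(x)
    data.frame(bin = b, lo = bins$edges[b], hi = bins$edges[b + 1],
               count = length(x), min = f[["min"]], q1 = f[["q1"]],
               median = f[["median"]], q3 = f[["q3"]], max = f[["max"]])
  }))
  summ
}

#' Column-normalized bidimensional histogram (heat map)
#'
#' Joint histogram of (SNR, covariate) with every nonempty covariate column
#' scaled to sum to 1; empty columns stay zero.
#'
#' @param snr,covariate equal-length numeric vectors (-Inf SNR excluded).
#' @param snrBins,covariateBins bin counts.
#' @param snrRange,covariateRange bin ranges (defaults: data range; c(0, max)
#'   for the covariate).
#' @return list with `matrix` (snrBins x covariateBins), `snrEdges`,
#'   `covariateEdges`.
#' @export
heatmapByColumn <- function(snr, covariate, snrBins = 30L, covariateBins = 30L,
                            snrRange = NULL, covariateRange = NULL) {
  if (length(snr) != length(covariate)) stop("snr and covariate lengths differ")
  keep <- is.finite(snr)
  snr <- snr[keep]; covariate <- covariate[keep]
  if (is.null(snrRange)) snrRange <- if (length(snr)) range(snr) else c(0, 1)
  if (snrRange[2] <= snrRange[1]) snrRange <- snrRange[1] + c(-0.5, 0.5)
  bs <- binValues(snr, nBins = snrBins, range = snrRange)
  bc <- binValues(covariate, nBins = covariateBins, range = covariateRange)
  H <- matrix(0, snrBins, covariateBins)
  ok <- !is.na(bs$assignment) & !is.na(bc$assignment)
  for (i in which(ok)) H[bs$assignment[i], bc$assignment[i]] <-
      H[bs$assignment[i], bc$assignment[i]] + 1
  cs <- colSums(H)
  nz <- cs > 0
  H[, nz] <- sweep(H[, nz, drop = FALSE], 2, cs[nz], "/")
  list(matrix = H, snrEdges = bs$edges, covariateEdges = bc$edges)
}
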