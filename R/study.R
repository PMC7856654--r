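# Study configuration and the end-to-end sensitivity pipeline: one shared
# mesh per study, per-variant conductivity/leadfields/SNR maps, differential
# maps, subcortical SVD projections and binned summaries.

#' Default study configuration
#'
#' All tunable parameters of the synthetic sphere sensitivity study with the
#' study defaults: canonical 78/80/86/92 mm shells, the standard conductivity
#' table, 71 electrodes / 271 coils, 10 nAm source amplitude and noise
#' variances of 10 uV^2 (EEG) and 1e4 fT^2 (MEG). One global seed expands
#' deterministically into per-stage seeds, so adding a stage never perturbs
#' earlier stages' randomness.
#'
#' @param ... overrides for individual entries (unknown names are an error).
#' @return a named list with class `sensmapConfig`.
#' @export
studyConfig <- function(...) {
  cfg <- list(
    radii = c(78, 80, 86, 92),
    mesh_edge_mm = 6,
    mesh_subdivisions = NULL,
    variants = c("3CI", "4CI"),
    anisotropy_ratio = 10,
    n_electrodes = 71L,
    n_coils = 271L,
    coil_offset_mm = 20,
    coil_tilt_deg = 0,
    cortex_base_radius_mm = 60,
    cortex_fold_amplitude_mm = 8,
    cortex_fold_frequency = 6L,
    cortex_resolution = 4L,
    subcortical_resolution = 1L,
    inner_skull_spacing_mm = 2,
    noise_eeg_variance_uV2 = 10,
    noise_meg_variance_fT2 = 1e4,
    noise_samples = 10000L,
    amplitude_nAm = 10,
    solver = list(method = "cholesky", tol = 1e-8, maxit = 10000L),
    depth_bins = 5L,
    depth_range_mm = c(0, 50),
    angle_bins = 5L,
    angle_range_deg = c(0, 180),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over, keep.null = TRUE)
  .validateConfig(cfg)
  class(cfg) <- "sensmapConfig"
  cfg
}

.validateConfig <- function(cfg) {
  if (any(cfg$radii <= 0) || is.unsorted(cfg$radii, strictly = TRUE))
    stop("config: radii must be strictly increasing and positive")
  if (cfg$mesh_edge_mm <= 0) stop("config: mesh_edge_mm must be positive")
  if (!all(cfg$variants %in% c("3CI", "4CI", "6CA")))
    stop("config: variants must be among 3CI, 4CI, 6CA")
  for (nm in c("n_electrodes", "n_coils", "noise_eeg_variance_uV2",
               "noise_meg_variance_fT2", "amplitude_nAm", "noise_samples"))
    if (cfg[[nm]] <= 0) stop("config: ", nm, " must be positive")
  if (any(unlist(conductivityTable()) <= 0)) stop("conductivity table corrupt")
  invisible(cfg)
}

#' Load a study configuration from YAML
#'
#' Absent keys take their defaults; unknown keys are rejected by name; the
#' merged configuration is validated.
#'
#' @param path YAML file (empty file = full default configuration).
#' @return a `sensmapConfig`.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(studyConfig, raw)
}

#' Save a study configuration as YAML
#' @param config a `sensmapConfig`.
#' @param path output file.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# canonicalize (sort names recursively) so the hash is stable under key order
.canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, .canonicalize)
  } else x
}

#' Stable hash of a study configuration
#' @param config a `sensmapConfig`.
#' @return character hash, independent of key ordering.
#' @export
configHash <- function(config) {
  rlang::hash(.canonicalize(unclass(config)))
}

#' Run the full synthetic sensitivity study
#'
#' Builds one layered-sphere mesh, sensors, folded cortex, subcortical
#' regions and baseline noise, then for every head-model variant (same mesh,
#' only the tissue labels/tensors differ) computes EEG and MEG leadfields via
#' transfer matrices, per-dipole SNR and differential SNR maps with
#' depth/angle covariates, subcortical SVD radial/tangential projections, and
#' binned summaries plus column-normalized heat maps.
#'
#' @param config a `sensmapConfig` (see [studyConfig()]).
#' @param verbose print stage timings.
#' @return a list of class `sensmapStudy`: `config`, `hash`, `mesh`,
#'   `sensors`, `cortex`, `innerSkull`, `dipoles`, `noise`, and `variants`
#'   (per variant: `snr` data.frame, `subcortical` projection data.frame,
#'   `summaries`, `heatmaps`, `leadfields`).
#' @export
runSensitivityStudy <- function(config = studyConfig(), verbose = FALSE) {
  .validateConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stageSeed <- function(stage) deriveSeed(config$seed, stage)

  say("stage: mesh")
  mesh <- buildLayeredSphereMesh(config$radii, config$mesh_edge_mm,
                                 seed = stageSeed("mesh"),
                                 subdivisions = config$mesh_subdivisions)
  sensors <- placeSensors(mesh, config$n_electrodes, config$n_coils,
                          config$coil_offset_mm, seed = stageSeed("sensors"),
                          coilTilt = config$coil_tilt_deg)
  say("stage: source spaces")
  cortex <- synthCortexSurface(config$cortex_base_radius_mm,
                               config$cortex_fold_amplitude_mm,
                               config$cortex_fold_frequency,
                               config$cortex_resolution,
                               seed = stageSeed("cortex"),
                               maxRadius = config$radii[1])
  regions <- synthSubcorticalRegions(meshResolution = config$subcortical_resolution,
                                     seed = stageSeed("subcortical"),
                                     brainRadius = config$radii[1])
  grayName <- if ("gray" %in% labelNames(mesh)) "gray" else "brain"
  cortical <- corticalDipolesFromSurface(cortex, mesh, grayName)
  subcort <- subcorticalDipolesFromRegions(regions)
  subcort@element <- locateElements(mesh, dipolePositions(subcort))
  dipoles <- c(cortical, subcort)
  innerSkullRadius <- .innerSkullRadius(config$radii)
  innerSkull <- sphereSurface(innerSkullRadius, config$inner_skull_spacing_mm)
  dipoles <- withSourceMetrics(dipoles, innerSkull)

  say("stage: noise")
  baseline <- synthNoiseBaseline(sensors, config$noise_eeg_variance_uV2,
                                 config$noise_meg_variance_fT2,
                                 config$noise_samples,
                                 seed = stageSeed("noise"))
  noise <- estimateNoiseVariance(baseline)
  sEeg <- noise$variances[noise$modality == "eeg"]
  sMeg <- noise$variances[noise$modality == "meg"]

  cov <- data.frame(depth = dipoleDepths(dipoles), angle = dipoleAngles(dipoles),
                    class = dipoleClass(dipoles), region = dipoleRegions(dipoles),
                    group = dipoleGroups(dipoles))
  variants <- list()
  for (variant in config$variants) {
    say("stage: variant %s", variant)
    cond <- assignConductivities(mesh, variant, config$anisotropy_ratio)
    sys <- assembleStiffness(mesh, cond, config$solver)
    Teeg <- computeTransferMatrix(sys, eegRestriction(mesh, sensors), "eeg")
    Tmeg <- computeTransferMatrix(sys, megIntegrationRows(mesh, cond, sensors),
                                  "meg")
    lf <- computeLeadfield(Teeg, Tmeg, mesh, dipoles, sensors)
    snrEeg <- snrMap(lf$eeg, sEeg, config$amplitude_nAm)
    snrMeg <- snrMap(lf$meg, sMeg, config$amplitude_nAm)
    snr <- cbind(cov, snr_eeg = snrEeg, snr_meg = snrMeg,
                 diff_snr = differentialSnr(snrMeg, snrEeg))
    ctx <- cov$class == "cortical"
    summaries <- list(
      eeg_by_depth = summarizeByBins(snrEeg[ctx], cov$depth[ctx],
                                     config$depth_bins, config$depth_range_mm),
      meg_by_depth = summarizeByBins(snrMeg[ctx], cov$depth[ctx],
                                     config$depth_bins, config$depth_range_mm),
      diff_by_depth = summarizeByBins(snr$diff_snr[ctx], cov$depth[ctx],
                                      config$depth_bins, config$depth_range_mm),
      eeg_by_angle = summarizeByBins(snrEeg[ctx], cov$angle[ctx],
                                     config$angle_bins, config$angle_range_deg),
      meg_by_angle = summarizeByBins(snrMeg[ctx], cov$angle[ctx],
                                     config$angle_bins, config$angle_range_deg),
      diff_by_angle = summarizeByBins(snr$diff_snr[ctx], cov$angle[ctx],
                                      config$angle_bins, config$angle_range_deg))
    heatmaps <- list(
      eeg_by_depth = heatmapByColumn(snrEeg[ctx], cov$depth[ctx],
                                     covariateBins = config$depth_bins * 6L,
                                     covariateRange = config$depth_range_mm),
      meg_by_depth = heatmapByColumn(snrMeg[ctx], cov$depth[ctx],
                                     covariateBins = config$depth_bins * 6L,
                                     covariateRange = config$depth_range_mm),
      eeg_by_angle = heatmapByColumn(snrEeg[ctx], cov$angle[ctx],
                                     covariateBins = config$angle_bins * 6L,
                                     covariateRange = config$angle_range_deg),
      meg_by_angle = heatmapByColumn(snrMeg[ctx], cov$angle[ctx],
                                     covariateBins = config$angle_bins * 6L,
                                     covariateRange = config$angle_range_deg))
    variants[[variant]] <- list(
      snr = snr,
      subcortical = projectSubcortical(lf$eeg, lf$meg, sEeg, sMeg,
                                       config$amplitude_nAm),
      summaries = summaries, heatmaps = heatmaps, leadfields = lf)
  }
  structure(list(config = config, hash = configHash(config), mesh = mesh,
                 sensors = sensors, cortex = cortex, innerSkull = innerSkull,
                 dipoles = dipoles, baseline = baseline, noise = noise,
                 variants = variants),
            class = "sensmapStudy")
}

# inner-skull radius = outer radius of the CSF shell (or of the brain for a
# 1/3-shell model without explicit CSF)
.innerSkullRadius <- function(radii) {
  k <- length(radii)
  if (k >= 4) radii[k - 2] else radii[1]
}

#' Write the study artifacts of a run to a directory
#'
#' CSV summaries and heat maps, TSV dipoles/sensors, a VTK PolyData cortical
#' map with per-vertex `snr_eeg`, `snr_meg` and `diff_snr` scalars (dipole
#' values of the first dipole of each surface vertex group), and the YAML
#' config with its hash. Rerunning with the same config reproduces the CSV
#' summaries byte-identically.
#'
#' @param study a `sensmapStudy`.
#' @param dir output directory (created if needed).
#' @export
writeStudyResults <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveConfig(study$config, file.path(dir, "config.yaml"))
  writeLines(study$hash, file.path(dir, "config.hash"))
  writeSensorsTsv(study$sensors, file.path(dir, "sensors.tsv"))
  writeDipolesTsv(study$dipoles, file.path(dir, "dipoles.tsv"))
  ctx <- which(dipoleClass(study$dipoles) == "cortical")
  for (variant in names(study$variants)) {
    v <- study$variants[[variant]]
    snr <- cbind(v$snr, config_hash = study$hash)
    utils::write.csv(snr, file.path(dir, sprintf("snr_%s.csv", variant)),
                     row.names = FALSE)
    utils::write.csv(cbind(v$subcortical, config_hash = study$hash),
                     file.path(dir, sprintf("subcortical_%s.csv", variant)),
                     row.names = FALSE)
    for (nm in names(v$summaries))
      utils::write.csv(cbind(v$summaries[[nm]], config_hash = study$hash),
                       file.path(dir, sprintf("summary_%s_%s.csv", variant, nm)),
                       row.names = FALSE)
    for (nm in names(v$heatmaps))
      utils::write.csv(v$heatmaps[[nm]]$matrix,
                       file.path(dir, sprintf("heatmap_%s_%s.csv", variant, nm)),
                       row.names = FALSE)
    # per-vertex cortical map: vertex i of the cortex surface corresponds to
    # cortical dipole i (one dipole per vertex, in vertex order)
    writeSurfaceMap(study$cortex,
                    list(snr_eeg = v$snr$snr_eeg[ctx],
                         snr_meg = v$snr$snr_meg[ctx],
                         diff_snr = v$snr$diff_snr[ctx]),
                    file.path(dir, sprintf("cortical_map_%s.vtk", variant)))
  }
  invisible(dir)
}

#' @export
print.sensmapStudy <- function(x, ...) {
  cat("sensmap sensitivity study\n")
  cat("  config hash:", x$hash, "\n")
  cat(sprintf("  mesh: %d nodes / %d tets; sensors: %d EEG, %d MEG\n",
              nrow(nodePositions(x$mesh)), nrow(meshElements(x$mesh)),
              nEeg(x$sensors), nMeg(x$sensors)))
  cat(sprintf("  dipoles: %d cortical, %d subcortical\n",
              sum(dipoleClass(x$dipoles) == "cortical"),
              sum(dipoleClass(x$dipoles) == "subcortical")))
  cat("  variants:", paste(names(x$variants), collapse = ", "), "\n")
  invisible(x)
}
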