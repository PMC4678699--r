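## End-to-end orchestration: preprocess -> cluster -> prune -> normalize ->
## bin -> profiles -> classify -> crosstab -> dice, with every intermediate
## written to a run directory in standard formats (NIfTI volumes, CSV
## tables, JSON summary).

write_volume <- function(vol, path, voxel_size = c(1, 1, 1)) {
  storage <- if (is.logical(vol)) array(as.integer(vol), dim(vol)) else vol
  img <- RNifti::asNifti(storage, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run the full tissue-signature pipeline on one study
#'
#' Executes the whole analysis in order: CSF/vessel exclusion, relative
#' maps, spatial contiguity weighting, feature assembly, dispersion-
#' parameter derivation from the reference ROIs, ISODATA clustering, CoV
#' pruning, CSF/WM-anchored normalization and binning, per-signature
#' temporal profiles, lesion-ROI dilation and tissue classification,
#' signature-by-class cross-tabulation, and Dice overlap of the abnormal
#' region with the maximal-lesion ROI. All artifacts are reproducible from
#' the configuration and seed alone.
#'
#' @param study A [serial_study] with reference ROIs and lesion ROIs.
#' @param out_dir Output directory (created if missing); set to `NULL` to
#'   skip writing files and just return the results.
#' @param parameters Parameter combination to cluster on.
#' @param phi_N,k,K,I,eps_r,L ISODATA controls (see [isodata_params()]);
#'   `phi_C` and `phi_S` are derived from the study's WM/GM ROIs.
#' @param cov_threshold CoV pruning threshold.
#' @param dilate_steps,connectivity Lesion-ROI dilation before tissue
#'   classification (0 steps opts out).
#' @param radius,decay Contiguity-weighting settings.
#' @param seed Integer seed (initialization of the clustering).
#' @return Invisibly, a list of class `pipeline_run`: the processed study,
#'   `features`, `model`, `pruned`, `signatures`, `profiles`, `classes`,
#'   `crosstab`, `overlap`, and `summary` (the JSON-serializable run
#'   summary).
#' @export
run_pipeline <- function(study, out_dir = NULL,
                         parameters = c("ADC", "FA", "T2"),
                         phi_N = 100, k = 6, K = 8, I = 100, eps_r = 1e-4,
                         L = 1, cov_threshold = 0.05, dilate_steps = 3,
                         connectivity = 6, radius = 1, decay = 1,
                         seed = 1L) {
  stopifnot(inherits(study, "serial_study"))
  prep <- prepare_study(study, parameters, radius = radius, decay = decay)
  study <- prep$study
  features <- prep$features
  disp <- derive_dispersion_params(features, study$ref_rois$wm,
                                   study$ref_rois$gm)
  params <- isodata_params(phi_N = phi_N, phi_C = disp$phi_C,
                           phi_S = disp$phi_S, k = k, K = K, I = I,
                           eps_r = eps_r, L = L)
  model <- run_isodata(features, params, seed = seed)
  pruned <- prune_by_cov(model, cov_threshold)
  csf_ref <- reference_feature_vector(study, features, study$ref_rois$csf)
  wm_ref <- reference_feature_vector(study, features, study$ref_rois$wm)
  sigmap <- compute_signature_map(pruned, csf_ref, wm_ref)
  ipsi_region <- study$hemisphere == 1L & study$analysis_mask
  profiles <- signature_time_profiles(sigmap$bins, study, ipsi_region)

  rois <- study$lesion_rois
  if (dilate_steps > 0) {
    for (r in c("acute", "maximal", "chronic")) {
      rois[[r]] <- dilate_roi(rois[[r]], steps = dilate_steps,
                              connectivity = connectivity,
                              brain_mask = study$brain_mask)
    }
  }
  classes <- classify_tissue(rois, study$brain_mask)
  xtab <- crosstab_signatures_classes(sigmap$bins, classes, ipsi_region)
  abn <- abnormal_region(pruned)
  overlap <- dice_overlap(abn, study$lesion_rois$maximal, ipsi_region)

  class_counts <- table(factor(TISSUE_CLASSES[unclass(classes)[study$brain_mask] + 1L],
                               levels = TISSUE_CLASSES))
  sig_counts <- table(factor(signature_bins()[sigmap$bins[ipsi_region & sigmap$bins >= 0] + 1L],
                             levels = signature_bins()))
  summary <- list(
    parameters = paste(parameters, collapse = "+"),
    seed = as.integer(seed),
    cov_threshold = cov_threshold,
    phi_N = phi_N, phi_C = disp$phi_C, phi_S = disp$phi_S,
    k = k, K = K, I = I, eps_r = eps_r, L = L,
    radius = radius, decay = decay,
    dilate_steps = dilate_steps, connectivity = connectivity,
    n_voxels = nrow(features$data),
    n_iterations = model$n_iter,
    converged = model$converged,
    n_clusters = pruned$n_before,
    n_clusters_pruned = pruned$n_after,
    n_abnormal_clusters = sum(!pruned$is_normal),
    cluster_cov = as.numeric(pruned$cov_values),
    cluster_values = as.numeric(sigmap$cluster_values),
    cluster_bins = as.character(sigmap$cluster_bins),
    signature_voxels = as.list(sig_counts),
    class_voxels = as.list(class_counts),
    DSI = overlap$DSI, TP = overlap$TP, FP = overlap$FP, FN = overlap$FN,
    TN = overlap$TN
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vs <- study$voxel_size_mm
    write_volume(assignments_volume(model), file.path(out_dir, "clusters.nii.gz"), vs)
    write_volume(sigmap$normalized, file.path(out_dir, "signatures.nii.gz"), vs)
    write_volume(sigmap$bins, file.path(out_dir, "signature_bins.nii.gz"), vs)
    write_volume(abn, file.path(out_dir, "abnormal.nii.gz"), vs)
    write_volume(array(unclass(classes), dim(classes)),
                 file.path(out_dir, "tissue_classes.nii.gz"), vs)
    jsonlite::write_json(
      list(signature_bins = signature_bins(),
           tissue_classes = TISSUE_CLASSES),
      file.path(out_dir, "code_tables.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(profiles, file.path(out_dir, "signature_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(xtab, file.path(out_dir, "signature_class_crosstab.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(structure(list(study = study, features = features, model = model,
                           pruned = pruned, signatures = sigmap,
                           profiles = profiles, classes = classes,
                           crosstab = xtab, overlap = overlap,
                           summary = summary, out_dir = out_dir),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("pipeline_run (", s$parameters, "): ", s$n_clusters, " clusters -> ",
      s$n_clusters_pruned, " after CoV pruning (threshold ", s$cov_threshold,
      "); DSI vs maximal lesion = ", sprintf("%.3f", s$DSI), "\n", sep = "")
  invisible(x)
}

#' Write a phantom dataset to a directory
#'
#' Volumes go out as NIfTI (`{param}_{hours}h.nii.gz`, `mask.nii.gz`,
#' `hemisphere.nii.gz`, `truth_labels.nii.gz`, ROI masks) and the
#' configuration as JSON.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- phantom$study
  vs <- st$voxel_size_mm
  for (p in names(st$maps)) {
    for (tk in names(st$maps[[p]])) {
      write_volume(st$maps[[p]][[tk]],
                   file.path(dir, sprintf("%s_%sh.nii.gz", p, tk)), vs)
    }
  }
  write_volume(st$brain_mask, file.path(dir, "mask.nii.gz"), vs)
  write_volume(st$hemisphere, file.path(dir, "hemisphere.nii.gz"), vs)
  write_volume(phantom$truth_labels, file.path(dir, "truth_labels.nii.gz"), vs)
  write_volume(phantom$truth_clusters, file.path(dir, "truth_clusters.nii.gz"), vs)
  write_volume(array(unclass(phantom$truth_classes), dim(phantom$truth_classes)),
               file.path(dir, "truth_classes.nii.gz"), vs)
  for (r in c("wm", "gm", "csf")) {
    write_volume(st$ref_rois[[r]], file.path(dir, sprintf("roi_%s.nii.gz", r)), vs)
  }
  for (r in c("acute", "maximal", "chronic")) {
    write_volume(st$lesion_rois[[r]],
                 file.path(dir, sprintf("lesion_%s.nii.gz", r)), vs)
  }
  cfg <- phantom$config
  cfg$signature_profiles <- lapply(cfg$signature_profiles, function(m) {
    as.data.frame(cbind(timepoint_h = attr(phantom$config$signature_profiles,
                                           "timepoints_h"), m))
  })
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
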