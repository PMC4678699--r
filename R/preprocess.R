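## Preprocessing: analysis mask, relative maps, spatial contiguity
## weighting, and assembly of the per-voxel spatiotemporal feature matrix.

#' Exclude CSF and large vessels from the analysis mask
#'
#' Voxels whose ADC at the earliest timepoint strictly exceeds the threshold
#' (default 1.2e-3 mm^2/s) are removed from the brain mask; such values arise
#' mostly from CSF and large vessels.
#'
#' @param adc_first_timepoint 3D ADC map (mm^2/s) at the earliest timepoint.
#' @param brain_mask Logical 3D array.
#' @param threshold Exclusion threshold in mm^2/s; strictly-greater values
#'   are excluded, a voxel exactly at the threshold is retained.
#' @return Logical analysis mask.
#' @export
exclude_csf_vessels <- function(adc_first_timepoint, brain_mask,
                                threshold = 1.2e-3) {
  stopifnot(threshold > 0)
  stop_shape(adc_first_timepoint, brain_mask, "ADC map and brain mask")
  brain_mask & !(adc_first_timepoint > threshold)
}

#' Apply the CSF/vessel exclusion to a study
#'
#' Convenience wrapper that stores the [exclude_csf_vessels()] result as the
#' study's analysis mask, using the earliest ADC map.
#'
#' @param study A [serial_study].
#' @param threshold Passed to [exclude_csf_vessels()].
#' @return The study with `$analysis_mask` set.
#' @export
apply_analysis_mask <- function(study, threshold = 1.2e-3) {
  adc1 <- get_map(study, "ADC", study$timepoints_h[1])
  study$analysis_mask <- exclude_csf_vessels(adc1, study$brain_mask, threshold)
  study
}

#' Compute relative (contralateral-normalized) maps
#'
#' Each quantitative map is divided by its mean over the contralateral
#' hemisphere restricted to the analysis mask, yielding rADC/rFA/rT2 maps in
#' which normal contralateral tissue averages exactly 1. Refuses to run twice
#' on the same study (relative maps are tracked, not silently re-divided).
#'
#' @param study A [serial_study] with the analysis mask set (if absent, the
#'   brain mask is used with a message).
#' @return The study with `$relative_maps` (named `rADC`, `rFA`, `rT2`) and
#'   `$relative_means` (the divisors used) populated.
#' @export
compute_relative_maps <- function(study) {
  if (!is.null(study$relative_maps)) {
    stop("relative maps already computed for this study; refusing to ",
         "renormalize relative values")
  }
  if (is.null(study$analysis_mask)) {
    message("no analysis mask set; using the brain mask for contralateral means")
    study$analysis_mask <- study$brain_mask
  }
  contra <- study$hemisphere == 2L & study$analysis_mask
  if (!any(contra)) stop("empty contralateral analysis region")
  rel <- list()
  means <- list()
  for (p in names(study$maps)) {
    rel[[paste0("r", p)]] <- list()
    means[[p]] <- numeric(0)
    for (tk in as.character(study$timepoints_h)) {
      v <- study$maps[[p]][[tk]]
      m <- mean(v[contra])
      if (!is.finite(m) || m == 0) {
        stop("zero or non-finite contralateral mean for (", p, ", ", tk, " h)")
      }
      rel[[paste0("r", p)]][[tk]] <- v / m
      means[[p]][tk] <- m
    }
  }
  study$relative_maps <- rel
  study$relative_means <- means
  study
}

#' Spatial contiguity weighting of the relative maps
#'
#' Replaces every in-mask voxel of every relative map by the Gaussian
#' distance-weighted mean of its in-mask cubic neighborhood: weights
#' `w(d) = exp(-d^2 / (2 decay^2))` with `d` the Euclidean center distance
#' in voxel units, out-of-mask neighbors carrying zero weight, and weights
#' renormalized to sum to one. This is the spatial component of the
#' clustering: it pulls each voxel's temporal profile toward its local
#' neighborhood, damping voxel noise before the feature matrix is built.
#'
#' @param study A [serial_study] with relative maps computed.
#' @param radius Neighborhood (Chebyshev) radius in voxels; 1 means 3x3x3.
#' @param decay Gaussian length scale in voxels.
#' @return The study with smoothed relative maps; the settings are recorded
#'   in `$contiguity`.
#' @export
spatial_contiguity_weight <- function(study, radius = 1, decay = 1) {
  stopifnot(radius >= 1, decay > 0)
  if (is.null(study$relative_maps)) {
    stop("relative maps must be computed before contiguity weighting")
  }
  for (p in names(study$relative_maps)) {
    for (tk in names(study$relative_maps[[p]])) {
      study$relative_maps[[p]][[tk]] <- gaussian_neighborhood_mean(
        study$relative_maps[[p]][[tk]], study$analysis_mask, radius, decay)
    }
  }
  study$contiguity <- list(radius = radius, decay = decay)
  study
}

#' Build the spatiotemporal feature matrix
#'
#' One row per analysis-mask voxel; columns are the relative values of the
#' requested parameters at every timepoint, ordered timepoint-major
#' (t1 x p1, t1 x p2, ..., t2 x p1, ...). With `standardize = TRUE` every
#' column is z-scored and the (mean, sd) recorded, so Mahalanobis distances
#' with the global diagonal covariance are well scaled across parameters.
#'
#' @param study A [serial_study] with relative maps computed.
#' @param parameters Subset of `c("ADC", "FA", "T2")` (relative forms are
#'   used).
#' @param standardize Z-score columns (default `TRUE`).
#' @return Object of class `feature_matrix`: `data` (V x t*f), `voxel_index`
#'   (V x 3, 0-based coordinates), `voxel_linear` (1-based linear indices),
#'   `feature_index` (data frame: column, timepoint_h, parameter),
#'   `standardization` (list of per-column mean and sd, or `NULL`), plus the
#'   grid dimension and the parameter/timepoint sets.
#' @export
build_feature_matrix <- function(study, parameters = c("ADC", "FA", "T2"),
                                 standardize = TRUE) {
  if (is.null(study$relative_maps)) {
    stop("relative maps must be computed before building features")
  }
  parameters <- match.arg(parameters, c("ADC", "FA", "T2"), several.ok = TRUE)
  mask <- study$analysis_mask
  vox <- which(mask)
  tps <- study$timepoints_h
  ncol_out <- length(tps) * length(parameters)
  X <- matrix(0, nrow = length(vox), ncol = ncol_out)
  fi <- data.frame(column = seq_len(ncol_out),
                   timepoint_h = rep(tps, each = length(parameters)),
                   parameter = paste0("r", rep(parameters, length(tps))))
  j <- 0L
  for (tk in as.character(tps)) {
    for (p in parameters) {
      j <- j + 1L
      X[, j] <- get_map(study, p, tk, relative = TRUE)[vox]
    }
  }
  colnames(X) <- paste0(fi$parameter, "_", fi$timepoint_h, "h")
  std <- NULL
  if (standardize) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
    std <- list(mean = mu, sd = sd_)
  }
  structure(list(
    data = X,
    voxel_index = arrayInd(vox, dim(mask)) - 1L,
    voxel_linear = vox,
    feature_index = fi,
    standardization = std,
    grid_dim = dim(mask),
    parameters = parameters,
    timepoints_h = tps
  ), class = "feature_matrix")
}

#' Feature-matrix rows covered by an ROI
#'
#' @param features A [build_feature_matrix()] result.
#' @param roi Logical 3D array on the same grid.
#' @return Integer row indices.
#' @export
roi_rows <- function(features, roi) {
  stopifnot(all(dim(roi) == features$grid_dim))
  which(roi[features$voxel_linear])
}

#' Reference feature vector for a reference ROI
#'
#' Mean relative value over the ROI voxels for every feature column, mapped
#' into the feature space of `features` (i.e. standardized with its recorded
#' column statistics). Works for ROIs outside the analysis mask, such as the
#' CSF region excluded from clustering, so normalization anchors keep their
#' meaning without re-including CSF voxels.
#'
#' @param study The study the features were built from (relative maps
#'   computed).
#' @param features A [build_feature_matrix()] result.
#' @param roi Logical 3D array.
#' @return Numeric vector of length `ncol(features$data)`.
#' @export
reference_feature_vector <- function(study, features, roi) {
  stopifnot(all(dim(roi) == features$grid_dim))
  if (!any(roi)) stop("empty reference ROI")
  vox <- which(roi)
  fi <- features$feature_index
  v <- vapply(seq_len(nrow(fi)), function(j) {
    p <- sub("^r", "", fi$parameter[j])
    mean(get_map(study, p, fi$timepoint_h[j], relative = TRUE)[vox])
  }, numeric(1))
  if (!is.null(features$standardization)) {
    v <- (v - features$standardization$mean) / features$standardization$sd
  }
  v
}
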