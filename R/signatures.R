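## Post-cluster processing: temporal coefficient-of-variation pruning,
## CSF/WM-anchored normalization of cluster values to 1-100, binning into
## named tissue signatures, and per-signature temporal profiles.

#' Signature bin labels
#'
#' The eleven tens-bins of the normalized 1-100 scale: `N` (values up to 5),
#' the named abnormal signatures `I` (6-15), `II` (26-35), `III` (36-45),
#' `IV` (46-55), `V` (56-65), and generic labels `B2` (16-25) and `B7`-`B10`
#' (66-100) for bins that carry no named signature.
#'
#' @return Character vector of the 11 labels, in bin order; integer codes
#'   0..10 follow this order.
#' @export
signature_bins <- function() {
  c("N", "I", "B2", "II", "III", "IV", "V", "B7", "B8", "B9", "B10")
}

#' Temporal coefficient of variation of a cluster centroid
#'
#' Per parameter, the ratio of the (population) standard deviation to the
#' mean of the centroid's trajectory over timepoints; the pooled value is
#' the maximum over parameters, so a cluster temporally dispersed in any
#' parameter counts as dispersed. The centroid must be in interpretable
#' (relative-value) units, not z-scored.
#'
#' @param centroid Numeric vector of length `nrow(feature_index)`.
#' @param feature_index Data frame with columns `column`, `timepoint_h`,
#'   `parameter` as produced by [build_feature_matrix()].
#' @return List with `per_parameter` (named numeric) and `pooled` (scalar).
#' @export
temporal_cov <- function(centroid, feature_index) {
  stopifnot(length(centroid) == nrow(feature_index))
  pars <- unique(feature_index$parameter)
  per <- vapply(pars, function(p) {
    traj <- centroid[feature_index$parameter == p]
    if (length(traj) < 2) {
      stop("parameter ", p, " has fewer than 2 timepoints; CoV undefined")
    }
    m <- mean(traj)
    if (abs(m) < 1e-12) stop("zero-mean trajectory for ", p, "; CoV undefined")
    sqrt(mean((traj - m)^2)) / m
  }, numeric(1))
  list(per_parameter = per, pooled = max(per))
}

## Centroids mapped back from z-scored to relative-value units.
destandardize_centroids <- function(model) {
  cent <- model$centroids
  std <- model$standardization
  if (is.null(std)) return(cent)
  sweep(sweep(cent, 2, std$sd, "*"), 2, std$mean, "+")
}

#' Prune temporally flat clusters
#'
#' Clusters whose pooled temporal CoV (computed on the de-standardized,
#' relative-value centroid) is at or below `threshold` are merged into a
#' single normal-tissue cluster (union of voxels, size-weighted centroid);
#' clusters above the threshold are retained as abnormal.
#'
#' @param model An `isodata_model` fitted on a `feature_matrix`.
#' @param threshold CoV threshold (default 0.05).
#' @return Object of class `pruned_model`: `centroids` and `assignments`
#'   over the retained clusters (the normal cluster, when present, is
#'   cluster 1), `is_normal` flag per retained cluster, `cov_values` per
#'   original cluster, `n_before`/`n_after` cluster counts, and the
#'   geometry/standardization metadata carried over from the model.
#' @export
prune_by_cov <- function(model, threshold = 0.05) {
  stopifnot(nrow(model$centroids) >= 1, threshold >= 0)
  if (is.null(model$feature_index)) {
    stop("model carries no feature_index; fit on a feature_matrix")
  }
  raw <- destandardize_centroids(model)
  covs <- vapply(seq_len(nrow(raw)), function(j) {
    temporal_cov(raw[j, ], model$feature_index)$pooled
  }, numeric(1))
  normal <- which(covs <= threshold)
  abnormal <- which(covs > threshold)
  sizes <- tabulate(model$assignments, nbins = nrow(model$centroids))
  has_normal <- length(normal) > 0
  new_cent <- NULL
  map <- integer(nrow(model$centroids))
  if (has_normal) {
    wts <- sizes[normal]
    new_cent <- rbind(colSums(model$centroids[normal, , drop = FALSE] * wts) /
                        sum(wts))
    map[normal] <- 1L
  }
  for (i in seq_along(abnormal)) {
    map[abnormal[i]] <- i + as.integer(has_normal)
    new_cent <- rbind(new_cent, model$centroids[abnormal[i], ])
  }
  out <- model
  out$centroids <- unname(new_cent)
  out$assignments <- map[model$assignments]
  out$sizes <- tabulate(out$assignments, nbins = nrow(new_cent))
  out$is_normal <- c(if (has_normal) TRUE, rep(FALSE, length(abnormal)))
  out$cov_values <- covs
  out$threshold <- threshold
  out$n_before <- nrow(model$centroids)
  out$n_after <- nrow(new_cent)
  class(out) <- c("pruned_model", "isodata_model")
  out
}

#' Abnormal-tissue region of a pruned model
#'
#' @param pruned A [prune_by_cov()] result.
#' @return Logical 3D array: voxels assigned to any abnormal (retained)
#'   cluster.
#' @export
abnormal_region <- function(pruned) {
  stopifnot(inherits(pruned, "pruned_model"))
  vol <- array(FALSE, pruned$grid_dim)
  abn <- which(!pruned$is_normal)
  vol[pruned$voxel_linear[pruned$assignments %in% abn]] <- TRUE
  vol
}

#' Normalize cluster values to the 1-100 scale
#'
#' Each cluster centroid is scored by its relative proximity to the
#' contralateral-WM and CSF reference vectors,
#' `s = |mu - wm| / (|mu - wm| + |mu - csf|)`, and the scores are rescaled
#' so the WM-nearest cluster maps to 1 and the CSF-nearest to 100
#' (`value = 1 + 99 s'`). The scale is monotone in relative proximity to
#' CSF and invariant to affine rescalings applied jointly to centroids and
#' references.
#'
#' @param model An `isodata_model` or `pruned_model`.
#' @param csf_ref,wm_ref Reference feature vectors in the same feature
#'   space as the centroids (see [reference_feature_vector()]).
#' @return Numeric vector of per-cluster values in `[1, 100]`.
#' @export
normalize_clusters <- function(model, csf_ref, wm_ref) {
  cent <- model$centroids
  stopifnot(length(csf_ref) == ncol(cent), length(wm_ref) == ncol(cent))
  if (isTRUE(all.equal(csf_ref, wm_ref, tolerance = 1e-12))) {
    stop("coincident CSF and WM reference vectors")
  }
  d_wm <- sqrt(rowSums(sweep(cent, 2, wm_ref, "-")^2))
  d_csf <- sqrt(rowSums(sweep(cent, 2, csf_ref, "-")^2))
  s <- d_wm / (d_wm + d_csf)
  if (nrow(cent) == 1) return(1)
  rng <- range(s)
  if (diff(rng) < 1e-15) {
    stop("all clusters equidistant between the reference anchors; ",
         "normalization undefined")
  }
  s <- (s - rng[1]) / (rng[2] - rng[1])
  1 + 99 * s
}

#' Bin normalized values into signatures
#'
#' Values at or below 5 are `N` (normal); the remaining scale is cut into
#' tens-bins with closed upper bounds: 6-15 `I`, 16-25 `B2`, 26-35 `II`,
#' 36-45 `III`, 46-55 `IV`, 56-65 `V`, then `B7`-`B10` up to 100.
#' Non-integer values use the same half-open intervals (5 < v <= 15 is `I`).
#'
#' @param values Numeric vector in `[1, 100]`.
#' @return Factor with levels [signature_bins()].
#' @export
bin_signatures <- function(values) {
  if (any(!is.finite(values)) || any(values < 1) || any(values > 100)) {
    stop("normalized values must lie in [1, 100]")
  }
  cut(values, breaks = c(1, 5, 15, 25, 35, 45, 55, 65, 75, 85, 95, 100),
      labels = signature_bins(), include.lowest = TRUE, right = TRUE)
}

#' Normalized signature map of a pruned model
#'
#' Combines [normalize_clusters()] and [bin_signatures()] into per-voxel
#' volumes.
#'
#' @param pruned A [prune_by_cov()] result.
#' @param csf_ref,wm_ref Reference feature vectors.
#' @return List: `cluster_values` (per retained cluster), `cluster_bins`
#'   (factor), `normalized` (3D array, 0 outside the analysis mask), `bins`
#'   (integer-coded 3D array, codes 0..10 in [signature_bins()] order, -1
#'   outside), `bin_labels`.
#' @export
compute_signature_map <- function(pruned, csf_ref, wm_ref) {
  vals <- normalize_clusters(pruned, csf_ref, wm_ref)
  bins <- bin_signatures(vals)
  normalized <- array(0, pruned$grid_dim)
  normalized[pruned$voxel_linear] <- vals[pruned$assignments]
  bin_vol <- array(-1L, pruned$grid_dim)
  bin_vol[pruned$voxel_linear] <- as.integer(bins)[pruned$assignments] - 1L
  list(cluster_values = vals, cluster_bins = bins, normalized = normalized,
       bins = bin_vol, bin_labels = signature_bins())
}

#' Temporal profiles per signature
#'
#' Mean, standard deviation, and voxel count of every relative parameter at
#' every timepoint, per signature label, over a region (by default the
#' ipsilateral analysis mask). Empty signatures are omitted with a message.
#'
#' @param label_volume 3D array of signature labels: either a character
#'   array, or an integer-coded array as produced by
#'   [compute_signature_map()] (codes 0..10, -1 = outside).
#' @param study A [serial_study] with relative maps computed.
#' @param region Optional logical 3D array restricting the tally.
#' @return Data frame with columns `signature`, `timepoint_h`, `parameter`,
#'   `mean`, `sd`, `n`.
#' @export
signature_time_profiles <- function(label_volume, study, region = NULL) {
  stop_shape(label_volume, study$brain_mask, "label volume and study")
  if (is.null(study$relative_maps)) {
    stop("relative maps must be computed before profiling")
  }
  if (is.null(region)) {
    region <- study$hemisphere == 1L &
      (study$analysis_mask %||% study$brain_mask)
  }
  if (is.numeric(label_volume)) {
    lv <- array(NA_character_, dim(label_volume))
    ok <- label_volume >= 0
    lv[ok] <- signature_bins()[label_volume[ok] + 1L]
    label_volume <- lv
  }
  labels <- label_volume
  labels[!region] <- NA_character_
  present <- sort(unique(labels[!is.na(labels)]))
  known <- signature_bins()
  present <- present[order(match(present, known, nomatch = length(known) + 1))]
  if (length(present) == 0) {
    message("no labeled voxels in the profiling region; empty profile")
  }
  rows <- list()
  for (sig in present) {
    vox <- which(!is.na(labels) & labels == sig)
    for (tk in as.character(study$timepoints_h)) {
      for (p in names(study$relative_maps)) {
        v <- study$relative_maps[[p]][[tk]][vox]
        rows[[length(rows) + 1]] <- data.frame(
          signature = sig, timepoint_h = as.numeric(tk), parameter = p,
          mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
          n = length(v))
      }
    }
  }
  do.call(rbind, rows)
}
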