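## Overlap scoring against reference lesions and the input-combination by
## CoV-threshold optimization sweep.

#' Dice overlap between a predicted and a reference mask
#'
#' Voxel counts and Dice similarity index `DSI = 2 TP / (2 TP + FP + FN)`
#' computed inside an evaluation region. When both masks are empty inside
#' the region the DSI is defined as 1 (and the event is logged); an empty
#' reference with a non-empty prediction scores 0.
#'
#' @param predicted,reference Logical 3D arrays on the same grid.
#' @param region Optional logical array; counts are restricted to it
#'   (default: the whole grid).
#' @return List of class `overlap_result` with `TP`, `FP`, `FN`, `TN`,
#'   `DSI`.
#' @export
dice_overlap <- function(predicted, reference, region = NULL) {
  stop_shape(predicted, reference, "predicted and reference masks")
  if (is.null(region)) {
    region <- array(TRUE, dim(predicted))
  } else {
    stop_shape(predicted, region, "masks and evaluation region")
  }
  if (!any(region)) stop("empty evaluation region")
  p <- predicted[region]
  r <- reference[region]
  TP <- sum(p & r)
  FP <- sum(p & !r)
  FN <- sum(!p & r)
  TN <- sum(!p & !r)
  denom <- 2 * TP + FP + FN
  if (denom == 0) {
    message("both masks empty in the evaluation region; DSI defined as 1")
    dsi <- 1
  } else {
    dsi <- 2 * TP / denom
  }
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, DSI = dsi),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: DSI = %.4f (TP %d, FP %d, FN %d, TN %d)\n",
              x$DSI, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Default parameter-combination grid
#'
#' The six input combinations evaluated by the sweep: each single parameter,
#' ADC with FA, ADC with T2, and all three.
#'
#' @return List of character vectors.
#' @export
parameter_combinations <- function() {
  list(c("ADC"), c("FA"), c("T2"), c("ADC", "FA"), c("ADC", "T2"),
       c("ADC", "FA", "T2"))
}

combo_label <- function(combo) paste(combo, collapse = "+")

## Preprocess one study for one parameter combination; returns the study
## (masked, relative, contiguity-weighted) plus its feature matrix.
prepare_study <- function(study, parameters, radius = 1, decay = 1,
                          adc_threshold = 1.2e-3, standardize = TRUE) {
  study <- apply_analysis_mask(study, adc_threshold)
  study <- compute_relative_maps(study)
  study <- spatial_contiguity_weight(study, radius = radius, decay = decay)
  features <- build_feature_matrix(study, parameters,
                                   standardize = standardize)
  list(study = study, features = features)
}

#' Sweep input combinations and CoV thresholds
#'
#' For every (parameter combination, CoV threshold) configuration and every
#' study: preprocess, cluster with ISODATA (`phi_C`/`phi_S` derived per
#' study and combination from the reference ROIs), prune at the threshold,
#' extract the abnormal region, and score its Dice overlap with the study's
#' maximal-lesion ROI inside the ipsilateral analysis mask. Clustering is
#' performed once per (study, combination) and re-pruned per threshold,
#' which is identical to independent runs because pruning is a pure
#' post-processing step. Each clustering seed is derived from the master
#' seed and the combination label, so results do not depend on grid order.
#'
#' @param studies List of [serial_study] objects with lesion ROIs (a single
#'   study may be passed bare).
#' @param combinations List of parameter combinations (default
#'   [parameter_combinations()]).
#' @param cov_thresholds Numeric vector of pruning thresholds (default 0.10
#'   down to 0.01 in steps of 0.01).
#' @param params An [isodata_params()] object; its `phi_C`/`phi_S` are
#'   overridden by the per-study derivation.
#' @param seed Master seed.
#' @param radius,decay Contiguity-weighting settings.
#' @return Object of class `sweep_result`: `results` (one row per study x
#'   configuration with the DSI and cluster counts), `summary` (mean and sd
#'   DSI per configuration), and `best` (the configuration with the highest
#'   mean DSI; ties go to the first in grid order).
#' @export
sweep_configurations <- function(studies,
                                 combinations = parameter_combinations(),
                                 cov_thresholds = seq(0.10, 0.01, by = -0.01),
                                 params = isodata_params(phi_C = 1, phi_S = 1),
                                 seed = 1L, radius = 1, decay = 1) {
  if (inherits(studies, "serial_study")) studies <- list(studies)
  stopifnot(length(studies) >= 1, length(cov_thresholds) >= 1)
  rows <- list()
  for (si in seq_along(studies)) {
    for (combo in combinations) {
      lab <- combo_label(combo)
      res <- tryCatch({
        prep <- prepare_study(studies[[si]], combo, radius = radius,
                              decay = decay)
        study <- prep$study
        disp <- derive_dispersion_params(prep$features, study$ref_rois$wm,
                                         study$ref_rois$gm)
        p <- params
        p$phi_C <- disp$phi_C
        p$phi_S <- disp$phi_S
        model <- run_isodata(prep$features, p,
                             seed = derive_seed(seed, lab, si))
        region <- study$hemisphere == 1L & study$analysis_mask
        lapply(cov_thresholds, function(th) {
          pruned <- prune_by_cov(model, th)
          ov <- dice_overlap(abnormal_region(pruned),
                             study$lesion_rois$maximal, region)
          data.frame(study = si, combination = lab, cov_threshold = th,
                     DSI = ov$DSI, TP = ov$TP, FP = ov$FP, FN = ov$FN,
                     n_clusters = pruned$n_before,
                     n_abnormal = sum(!pruned$is_normal),
                     error = NA_character_)
        })
      }, error = function(e) {
        lapply(cov_thresholds, function(th) {
          data.frame(study = si, combination = lab, cov_threshold = th,
                     DSI = NA_real_, TP = NA_integer_, FP = NA_integer_,
                     FN = NA_integer_, n_clusters = NA_integer_,
                     n_abnormal = NA_integer_, error = conditionMessage(e))
        })
      })
      rows <- c(rows, res)
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(DSI ~ combination + cov_threshold, data = results,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v)),
                   na.action = stats::na.pass)
  summary_df <- data.frame(combination = agg$combination,
                           cov_threshold = agg$cov_threshold,
                           mean_DSI = agg$DSI[, "mean"],
                           sd_DSI = agg$DSI[, "sd"])
  ## preserve grid order for deterministic tie-breaks
  labs <- vapply(combinations, combo_label, character(1))
  summary_df <- summary_df[order(match(summary_df$combination, labs),
                                 match(summary_df$cov_threshold,
                                       cov_thresholds)), ]
  rownames(summary_df) <- NULL
  ok <- which(is.finite(summary_df$mean_DSI))
  best <- if (length(ok)) summary_df[ok[which.max(summary_df$mean_DSI[ok])], ]
          else summary_df[0, ]
  structure(list(results = results, summary = summary_df, best = best,
                 seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", nrow(x$results), "configuration evaluations\n")
  if (nrow(x$best)) {
    cat(sprintf("  best: %s at CoV threshold %.2f (mean DSI %.3f)\n",
                x$best$combination, x$best$cov_threshold, x$best$mean_DSI))
  }
  invisible(x)
}
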