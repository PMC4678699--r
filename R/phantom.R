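## Synthetic serial stroke phantom -------------------------------------------
##
## The phantom emulates a unilateral MCA-occlusion study: an ellipsoidal
## brain with a white-matter interior, an optional grey-matter shell, a
## central CSF (ventricle) compartment, and ellipsoidal lesion regions in the
## ipsilateral hemisphere whose ADC/FA/T2 values follow signature-specific
## relative time-courses. Ground-truth labels, lesion ROIs, and tissue
## classes come with the data, so every downstream stage is testable.

SIGNATURE_IDS <- c("I", "II", "III", "IV", "V")

#' Default per-signature relative time-course anchors
#'
#' Anchor multipliers (relative to the local compartment baseline) for the
#' five abnormal tissue signatures at the seven default timepoints; values at
#' other timepoints are piecewise-linear in log-time. The anchors encode the
#' qualitative temporal behavior each signature stands for:
#'
#' * rADC: acutely decreased for II, IV, and V, most strongly for V then II;
#'   II keeps falling through 24 h before slowly renormalizing; IV rebounds
#'   sharply within the first 24 h then drifts down chronically; V rises
#'   progressively from 24 h onward; I and III start normal, III dips by
#'   24 h then recovers, I drifts slowly down in the chronic phase.
#' * rFA: acutely decreased only for V; every signature trends down until
#'   144 h, after which I and IV renormalize while the rest keep falling.
#' * rT2: II and V increase monotonically across all timepoints; I and IV
#'   peak at 144 h then fall back (IV with the steepest subacute rise after
#'   3 h apart from V); III rises then plateaus from 72 h.
#'
#' @param timepoints_h Timepoints (hours) at which anchors are tabulated.
#' @return Named list (signatures I..V) of `length(timepoints_h)` x 3
#'   matrices with columns `rADC`, `rFA`, `rT2`; timepoints stored in
#'   `attr(, "timepoints_h")`.
#' @export
default_signature_profiles <- function(timepoints_h = c(1, 2, 3, 24, 72, 144, 240)) {
  base_t <- c(1, 2, 3, 24, 72, 144, 240)
  tab <- list(
    I = cbind(rADC = c(1.00, 1.00, 1.00, 1.02, 0.98, 0.95, 0.92),
              rFA  = c(1.00, 0.98, 0.96, 0.90, 0.85, 0.80, 0.88),
              rT2  = c(1.02, 1.04, 1.06, 1.35, 1.50, 1.55, 1.10)),
    II = cbind(rADC = c(0.75, 0.72, 0.70, 0.60, 0.68, 0.78, 0.88),
               rFA  = c(1.00, 0.97, 0.94, 0.85, 0.75, 0.65, 0.62),
               rT2  = c(1.02, 1.05, 1.08, 1.25, 1.40, 1.55, 1.70)),
    III = cbind(rADC = c(1.00, 0.97, 0.94, 0.80, 0.85, 0.92, 0.96),
                rFA  = c(1.00, 0.98, 0.95, 0.88, 0.80, 0.72, 0.70),
                rT2  = c(1.02, 1.05, 1.10, 1.30, 1.45, 1.45, 1.45)),
    IV = cbind(rADC = c(0.80, 0.82, 0.85, 1.15, 1.10, 1.05, 0.95),
               rFA  = c(1.00, 0.97, 0.94, 0.86, 0.78, 0.70, 0.80),
               rT2  = c(1.02, 1.06, 1.12, 1.50, 1.65, 1.70, 1.08)),
    V = cbind(rADC = c(0.55, 0.55, 0.57, 0.70, 0.85, 1.00, 1.15),
              rFA  = c(0.80, 0.78, 0.75, 0.68, 0.60, 0.55, 0.52),
              rT2  = c(1.05, 1.10, 1.15, 1.45, 1.70, 1.90, 2.10))
  )
  out <- lapply(tab, function(m) {
    im <- vapply(colnames(m), function(p) {
      stats::approx(log(base_t), m[, p], xout = log(timepoints_h),
                    rule = 2)$y
    }, numeric(length(timepoints_h)))
    im <- matrix(im, nrow = length(timepoints_h),
                 dimnames = list(NULL, colnames(m)))
    im
  })
  attr(out, "timepoints_h") <- timepoints_h
  out
}

#' Relative multipliers of one signature at one timepoint
#'
#' @param signature_id One of `"N"`, `"I"` .. `"V"`. `"N"` is normal tissue
#'   and always returns the unit profile.
#' @param timepoint_h Timepoint in hours; values between anchors are
#'   interpolated linearly in log-time.
#' @param profiles Profile table as from [default_signature_profiles()].
#' @return Named numeric `(rADC, rFA, rT2)`.
#' @export
signature_profile <- function(signature_id, timepoint_h,
                              profiles = default_signature_profiles()) {
  if (identical(signature_id, "N")) {
    return(c(rADC = 1, rFA = 1, rT2 = 1))
  }
  if (!signature_id %in% names(profiles)) {
    stop("unknown signature_id '", signature_id, "'; valid ids: N, ",
         paste(names(profiles), collapse = ", "))
  }
  tp <- attr(profiles, "timepoints_h")
  m <- profiles[[signature_id]]
  out <- vapply(colnames(m), function(p) {
    stats::approx(log(tp), m[, p], xout = log(timepoint_h), rule = 2)$y
  }, numeric(1))
  names(out) <- colnames(m)
  out
}

#' Default compartment baselines
#'
#' Physiologically typical quantitative values per compartment. CSF ADC sits
#' above the 1.2e-3 mm^2/s exclusion threshold by design so ventricles are
#' removed from the analysis mask.
#'
#' @return Named list (`WM`, `GM`, `CSF`) of named numeric vectors
#'   `(ADC, FA, T2)` in mm^2/s, unitless, and ms.
#' @export
default_compartment_baselines <- function() {
  list(WM = c(ADC = 0.70e-3, FA = 0.45, T2 = 80),
       GM = c(ADC = 0.80e-3, FA = 0.15, T2 = 95),
       CSF = c(ADC = 3.0e-3, FA = 0.05, T2 = 2000))
}

#' Default planted lesion geometry
#'
#' Three ellipsoidal signature regions (II, IV, V) in the ipsilateral
#' (left, x below midline) white matter, scaled with the grid so reduced-size
#' phantoms keep the same anatomy. Coordinates are 0-based voxel indices.
#'
#' @param grid_shape Integer length 3.
#' @return List of `list(signature, center, radii)` entries.
#' @export
default_signature_regions <- function(grid_shape = c(64, 64, 24)) {
  s <- grid_shape / c(64, 64, 24)
  mk <- function(sig, center, radii) {
    list(signature = sig, center = center * s, radii = pmax(radii * s, 1.6))
  }
  list(mk("II", c(16, 24, 11), c(5, 5, 3)),
       mk("IV", c(16, 40, 11), c(5, 5, 3)),
       mk("V", c(23, 32, 12), c(4, 4, 3)))
}

#' Phantom configuration
#'
#' @param grid_shape Integer length 3, voxels.
#' @param voxel_size_mm Numeric length 3, mm.
#' @param timepoints_h Strictly increasing imaging timepoints (hours).
#' @param compartment_baselines As [default_compartment_baselines()].
#' @param signature_regions As [default_signature_regions()]; every region
#'   must fit inside the ipsilateral (low-x) half of the grid.
#' @param signature_profiles As [default_signature_profiles()].
#' @param noise_sd Named additive Gaussian noise sd per parameter, in the
#'   parameter's own units. The defaults are 5 percent of the WM baseline.
#' @param gm_shell If `TRUE` (default) the outer 20 percent of the brain
#'   ellipsoid radius is grey matter; if `FALSE` the parenchyma is
#'   homogeneous white matter (useful when exact relative-value recovery is
#'   needed, since the contralateral mean then equals the WM baseline).
#' @param abnormal_rADC,abnormal_rT2 Relative-value thresholds defining
#'   abnormality for the ground-truth lesion ROIs: a voxel is acutely
#'   abnormal when its noiseless 1-h rADC falls below `abnormal_rADC`, and
#'   chronically abnormal when its noiseless final-timepoint rT2 exceeds
#'   `abnormal_rT2`. The rT2 default (1.3) sits above the grey-matter
#'   relative level (about 1.09) so normal GM is not flagged.
#' @param seed Integer RNG seed for the noise.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 24),
                           voxel_size_mm = c(2, 2, 2),
                           timepoints_h = c(1, 2, 3, 24, 72, 144, 240),
                           compartment_baselines = default_compartment_baselines(),
                           signature_regions = default_signature_regions(grid_shape),
                           signature_profiles = default_signature_profiles(timepoints_h),
                           noise_sd = c(ADC = 3.5e-5, FA = 0.0225, T2 = 4),
                           gm_shell = TRUE,
                           abnormal_rADC = 0.9,
                           abnormal_rT2 = 1.3,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            all(voxel_size_mm > 0))
  if (any(diff(timepoints_h) <= 0)) {
    stop("timepoints_h must be strictly increasing")
  }
  for (cp in names(compartment_baselines)) {
    b <- compartment_baselines[[cp]]
    if (any(b <= 0)) stop("compartment baselines must be positive")
    if (b[["FA"]] < 0 || b[["FA"]] > 1) stop("FA baselines must be in [0, 1]")
  }
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  for (m in signature_profiles) {
    if (any(m <= 0)) stop("profile multipliers must be positive")
  }
  for (reg in signature_regions) {
    if (!reg$signature %in% SIGNATURE_IDS) {
      stop("unknown signature '", reg$signature, "' in signature_regions; ",
           "valid ids: ", paste(SIGNATURE_IDS, collapse = ", "))
    }
    if (reg$center[1] + reg$radii[1] >= grid_shape[1] / 2) {
      stop("signature region '", reg$signature,
           "' extends beyond the ipsilateral (low-x) hemisphere")
    }
  }
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    timepoints_h = timepoints_h,
    compartment_baselines = compartment_baselines,
    signature_regions = signature_regions,
    signature_profiles = signature_profiles,
    noise_sd = noise_sd, gm_shell = gm_shell,
    abnormal_rADC = abnormal_rADC, abnormal_rT2 = abnormal_rT2,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

## Compartment geometry: 1 = WM, 2 = GM, 3 = CSF, 0 = outside brain.
phantom_compartments <- function(config) {
  dm <- config$grid_shape
  center <- (dm - 1) / 2
  radii <- pmax(dm / 2 - 2, 2)
  gx <- ((seq_len(dm[1]) - 1 - center[1]) / radii[1])^2
  gy <- ((seq_len(dm[2]) - 1 - center[2]) / radii[2])^2
  gz <- ((seq_len(dm[3]) - 1 - center[3]) / radii[3])^2
  rr <- sqrt(outer(outer(gx, gy, `+`), gz, `+`))
  brain <- rr <= 1
  csf <- ellipsoid_mask(dm, center, pmax(dm * c(0.06, 0.12, 0.12), 1.5)) & brain
  comp <- array(0L, dm)
  comp[brain] <- 1L
  if (config$gm_shell) comp[brain & rr >= 0.8] <- 2L
  comp[csf] <- 3L
  comp
}

#' Generate a synthetic serial stroke dataset
#'
#' Builds the compartment geometry, plants the configured signature regions
#' (parenchymal voxels only -- a region overlapping the ventricles does not
#' relabel CSF), sets every voxel to `baseline * profile multiplier`, adds
#' seed-deterministic Gaussian noise (FA clipped to \[0, 1\], ADC/T2 at 0),
#' and derives ground truth from the noiseless data: the acute ROI is the
#' set of voxels whose noiseless 1-h rADC falls below the abnormality
#' threshold, the chronic ROI those whose noiseless final rT2 exceeds its
#' threshold, and the maximal ROI the abnormal extent at the (earliest)
#' timepoint where that extent is largest. Truth tissue classes follow from
#' those ROIs via [classify_tissue()].
#'
#' @param config A [phantom_config()].
#' @return List of class `phantom_dataset` with elements `study`
#'   ([serial_study]), `truth_labels` (integer array, 0 = normal,
#'   1..5 = signatures I..V), `truth_clusters` (integer array of generative
#'   mixture components: 1..5 signatures, 101 WM, 102 GM, 103 CSF),
#'   `truth_classes` (tissue class map), `compartments`, and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  dm <- config$grid_shape
  comp <- phantom_compartments(config)
  brain <- comp > 0L
  nx <- dm[1]
  hemisphere <- array(0L, dm)
  ipsi_x <- slice.index(comp, 1) <= nx / 2
  hemisphere[brain & ipsi_x] <- 1L
  hemisphere[brain & !ipsi_x] <- 2L

  ## planted labels (parenchyma only)
  truth <- array(0L, dm)
  for (reg in config$signature_regions) {
    vox <- ellipsoid_mask(dm, reg$center, reg$radii) & brain & comp != 3L
    code <- match(reg$signature, SIGNATURE_IDS)
    clash <- vox & truth != 0L & truth != code
    if (any(clash)) {
      stop("signature regions overlap with conflicting ids ('",
           SIGNATURE_IDS[truth[which(clash)[1]]], "' vs '", reg$signature, "')")
    }
    if (any(hemisphere[vox] != 1L)) {
      stop("signature region '", reg$signature,
           "' has voxels outside the ipsilateral hemisphere")
    }
    truth[vox] <- code
  }

  ## noiseless maps, then noise
  params <- c("ADC", "FA", "T2")
  comp_codes <- c(WM = 1L, GM = 2L, CSF = 3L)
  base_vol <- lapply(params, function(p) {
    v <- array(0, dm)
    for (cp in names(comp_codes)) {
      v[comp == comp_codes[[cp]]] <- config$compartment_baselines[[cp]][[p]]
    }
    v
  })
  names(base_vol) <- params
  tks <- as.character(config$timepoints_h)
  mult <- list()
  for (sig in SIGNATURE_IDS) {
    mult[[sig]] <- vapply(config$timepoints_h, function(t) {
      signature_profile(sig, t, config$signature_profiles)
    }, numeric(3))  # 3 x t matrix, rows rADC/rFA/rT2
  }
  noiseless <- lapply(params, function(p) {
    pr <- paste0("r", p)
    out <- list()
    for (i in seq_along(tks)) {
      v <- base_vol[[p]]
      for (code in seq_along(SIGNATURE_IDS)) {
        sel <- truth == code
        if (any(sel)) v[sel] <- v[sel] * mult[[SIGNATURE_IDS[code]]][pr, i]
      }
      out[[tks[i]]] <- v
    }
    out
  })
  names(noiseless) <- params

  nb <- sum(brain)
  maps <- with_seed(config$seed, {
    lapply(params, function(p) {
      out <- list()
      for (tk in tks) {
        v <- noiseless[[p]][[tk]]
        if (config$noise_sd[[p]] > 0) {
          v[brain] <- v[brain] + stats::rnorm(nb, sd = config$noise_sd[[p]])
        }
        if (p == "FA") v <- pmin(pmax(v, 0), 1) else v <- pmax(v, 0)
        out[[tk]] <- v
      }
      out
    })
  })
  names(maps) <- params

  ## reference ROIs
  contra <- hemisphere == 2L
  wm_box <- ellipsoid_mask(dm, c(0.72, 0.5, 0.48) * dm,
                           pmax(c(6, 6, 4) * dm / c(64, 64, 24), 1.6))
  wm_roi <- comp == 1L & contra & wm_box
  gm_band <- slice.index(comp, 2) >= 0.375 * dm[2] &
    slice.index(comp, 2) <= 0.625 * dm[2]
  gm_roi <- comp == 2L & contra & gm_band
  csf_roi <- comp == 3L
  if (!any(wm_roi)) stop("phantom grid too small: empty contralateral WM ROI")
  if (config$gm_shell && !any(gm_roi)) {
    stop("phantom grid too small: empty contralateral GM ROI")
  }

  ## ground-truth lesion ROIs from the noiseless data
  excl <- brain & !(noiseless$ADC[[tks[1]]] > 1.2e-3)
  contra_excl <- excl & contra
  rel <- function(p, tk) {
    noiseless[[p]][[tk]] / mean(noiseless[[p]][[tk]][contra_excl])
  }
  acute <- excl & rel("ADC", tks[1]) < config$abnormal_rADC
  chronic <- excl & rel("T2", tks[length(tks)]) > config$abnormal_rT2
  abn <- lapply(tks, function(tk) {
    excl & (rel("ADC", tk) < config$abnormal_rADC |
              rel("T2", tk) > config$abnormal_rT2)
  })
  counts <- vapply(abn, sum, integer(1))
  i_max <- which.max(counts)  # earliest timepoint on ties
  rois <- list(acute = acute, maximal = abn[[i_max]], chronic = chronic,
               maximal_timepoint_h = config$timepoints_h[i_max],
               chronic_timepoint_h = config$timepoints_h[length(tks)])

  truth_clusters <- array(0L, dm)
  truth_clusters[brain] <- 100L + comp[brain]
  truth_clusters[truth > 0L] <- truth[truth > 0L]

  study <- serial_study(maps = maps, timepoints_h = config$timepoints_h,
                        brain_mask = brain, hemisphere = hemisphere,
                        ref_rois = list(wm = wm_roi, gm = gm_roi,
                                        csf = csf_roi),
                        lesion_rois = rois,
                        voxel_size_mm = config$voxel_size_mm)
  structure(list(study = study, truth_labels = truth,
                 truth_clusters = truth_clusters,
                 truth_classes = classify_tissue(rois, brain),
                 compartments = comp, config = config),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("phantom_dataset:", paste(dim(x$compartments), collapse = "x"),
      "grid;", sum(x$truth_labels > 0), "lesion voxels in",
      length(x$config$signature_regions), "region(s)\n")
  print(x$study)
  invisible(x)
}
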