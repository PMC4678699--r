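## Operational tissue classification from acute, maximal, and chronic lesion
## ROIs, plus the signature-by-class cross-tabulation.

TISSUE_CLASSES <- c("Normal", "Core", "Growth", "Recovery", "Edema")

#' Morphological binary dilation of an ROI
#'
#' Applies `steps` dilation passes with a face-adjacent (6-connected)
#' structuring element -- or the full 26-connected cube -- then intersects
#' with the brain mask. With 6-connectivity, `n` passes equal a single
#' dilation with the radius-`n` octahedral element.
#'
#' @param mask Logical 3D array.
#' @param steps Number of dilation passes (0 leaves the mask unchanged).
#' @param connectivity 6 (face neighbors, default) or 26 (full cube).
#' @param brain_mask Optional logical array to clip the result to.
#' @return Logical 3D array containing the input mask.
#' @export
dilate_roi <- function(mask, steps = 3, connectivity = 6, brain_mask = NULL) {
  stopifnot(steps >= 0, connectivity %in% c(6, 26))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  }
  out <- mask
  for (s in seq_len(steps)) {
    acc <- out
    for (i in seq_len(nrow(offs))) {
      acc <- acc | shift3(out, offs[i, ], fill = FALSE)
    }
    out <- acc
  }
  if (!is.null(brain_mask)) {
    stop_shape(mask, brain_mask, "mask and brain mask")
    out <- out & brain_mask
  }
  out
}

#' Classify tissue from lesion ROIs
#'
#' Operational classes from the set relations between the acute (1-h ADC)
#' lesion, the chronic (follow-up T2) lesion, and the maximal lesion (the
#' timepoint of largest T2 lesion extent): Core is acute-and-chronic, Growth
#' chronic-but-not-acute, Recovery acute-but-not-chronic, Edema abnormal
#' only at the maximal timepoint, and everything else in the brain mask is
#' Normal. Acute membership takes precedence over Edema, so a voxel in both
#' the maximal and acute ROIs that misses the chronic ROI is Recovery.
#'
#' @param rois Named list of logical arrays `acute`, `maximal`, `chronic`
#'   (normally already dilated with [dilate_roi()]; pass raw masks to opt
#'   out).
#' @param brain_mask Logical 3D array.
#' @return Integer 3D array of class `tissue_class_map` with codes 0 Normal,
#'   1 Core, 2 Growth, 3 Recovery, 4 Edema (labels in `attr(, "labels")`);
#'   the five classes partition the brain mask.
#' @export
classify_tissue <- function(rois, brain_mask) {
  for (r in c("acute", "maximal", "chronic")) {
    if (is.null(rois[[r]])) stop("missing ROI '", r, "'")
    stop_shape(rois[[r]], brain_mask, paste0(r, " ROI and brain mask"))
  }
  a <- rois$acute & brain_mask
  m <- rois$maximal & brain_mask
  c_ <- rois$chronic & brain_mask
  out <- array(0L, dim(brain_mask))
  out[c_ & !a] <- 2L             # Growth
  out[a & !c_] <- 3L             # Recovery
  out[a & c_] <- 1L              # Core
  out[m & !a & !c_] <- 4L        # Edema
  out[!brain_mask] <- 0L
  structure(out, labels = TISSUE_CLASSES, class = "tissue_class_map")
}

#' Cross-tabulate signatures against tissue classes
#'
#' Voxel counts and row percentages per (signature, tissue class) cell,
#' restricted to a region (by default where the signature labels are
#' defined). Row percentages sum to 100 within each signature.
#'
#' @param bins Signature label volume: integer-coded array from
#'   [compute_signature_map()] or a character array.
#' @param classes A [classify_tissue()] map (or integer array with the same
#'   codes).
#' @param region Optional logical array restricting the tally.
#' @return Data frame with columns `signature`, `class`, `n`,
#'   `pct_of_signature`.
#' @export
crosstab_signatures_classes <- function(bins, classes, region = NULL) {
  stop_shape(bins, classes, "signature and class volumes")
  if (is.numeric(bins)) {
    lv <- array(NA_character_, dim(bins))
    ok <- bins >= 0
    lv[ok] <- signature_bins()[bins[ok] + 1L]
    bins <- lv
  }
  keep <- !is.na(bins)
  if (!is.null(region)) keep <- keep & region
  sig <- bins[keep]
  cls <- attr(classes, "labels", exact = TRUE) %||% TISSUE_CLASSES
  cl <- cls[unclass(classes)[keep] + 1L]
  tab <- table(signature = sig, class = cl)
  df <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  totals <- tapply(df$n, df$signature, sum)
  df$pct_of_signature <- ifelse(totals[df$signature] > 0,
                                100 * df$n / totals[df$signature], 0)
  ord <- order(match(df$signature, signature_bins()),
               match(df$class, TISSUE_CLASSES))
  rownames(df) <- NULL
  df[ord, , drop = FALSE]
}
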