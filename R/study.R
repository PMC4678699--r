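#' Serial multiparametric MRI study container
#'
#' Bundles co-registered, skull-stripped serial quantitative maps with the
#' masks the pipeline needs: a brain mask, a hemisphere labeling, reference
#' ROIs (contralateral white matter, contralateral grey matter, CSF) used to
#' derive clustering dispersion parameters and normalization anchors, and
#' optional lesion ROIs (acute, maximal, chronic).
#'
#' Hemisphere labels use the integer codes 0 = outside brain, 1 =
#' ipsilateral (lesioned) and 2 = contralateral. All volumes must share the
#' same grid.
#'
#' @param maps Named list, one entry per parameter (`"ADC"` in mm^2/s,
#'   `"FA"` unitless, `"T2"` in ms); each entry a named list of 3D arrays
#'   keyed by timepoint (hours, `as.character`).
#' @param timepoints_h Strictly increasing numeric vector of imaging
#'   timepoints in hours after stroke onset.
#' @param brain_mask Logical 3D array.
#' @param hemisphere Integer 3D array with codes 0/1/2 as above.
#' @param ref_rois Named list of logical arrays `wm`, `gm`, `csf`. `wm` and
#'   `gm` must lie in the contralateral hemisphere.
#' @param lesion_rois Optional named list of logical arrays `acute`,
#'   `maximal`, `chronic` plus scalars `maximal_timepoint_h` and
#'   `chronic_timepoint_h`.
#' @param voxel_size_mm Numeric length 3.
#' @return An object of class `serial_study`.
#' @export
serial_study <- function(maps, timepoints_h, brain_mask, hemisphere,
                         ref_rois, lesion_rois = NULL,
                         voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.list(maps), length(maps) >= 1)
  if (any(diff(timepoints_h) <= 0)) {
    stop("timepoints_h must be strictly increasing")
  }
  dm <- dim(brain_mask)
  stopifnot(length(dm) == 3)
  stop_shape(brain_mask, hemisphere, "brain_mask/hemisphere")
  for (p in names(maps)) {
    tks <- as.character(timepoints_h)
    if (!all(tks %in% names(maps[[p]]))) {
      missing_tp <- setdiff(tks, names(maps[[p]]))
      stop("missing map for (", p, ", ", paste(missing_tp, collapse = ", "),
           " h)")
    }
    for (tk in tks) stop_shape(brain_mask, maps[[p]][[tk]], paste0(p, " map"))
  }
  for (r in names(ref_rois)) {
    stop_shape(brain_mask, ref_rois[[r]], paste0(r, " ROI"))
    if (any(ref_rois[[r]] & !brain_mask)) {
      stop("reference ROI '", r, "' extends outside the brain mask")
    }
  }
  for (r in c("wm", "gm")) {
    if (!is.null(ref_rois[[r]]) && any(hemisphere[ref_rois[[r]]] != 2L)) {
      stop("reference ROI '", r, "' must lie in the contralateral hemisphere")
    }
  }
  structure(list(
    maps = maps,
    timepoints_h = timepoints_h,
    brain_mask = brain_mask,
    hemisphere = hemisphere,
    ref_rois = ref_rois,
    lesion_rois = lesion_rois,
    voxel_size_mm = voxel_size_mm,
    analysis_mask = NULL,
    relative_maps = NULL,
    relative_means = NULL,
    contiguity = NULL
  ), class = "serial_study")
}

#' @export
print.serial_study <- function(x, ...) {
  cat("serial_study:", paste(dim(x$brain_mask), collapse = "x"), "grid,",
      length(x$timepoints_h), "timepoints (",
      paste(x$timepoints_h, collapse = ", "), "h ),",
      "parameters:", paste(names(x$maps), collapse = ", "), "\n")
  cat("  brain voxels:", sum(x$brain_mask),
      if (!is.null(x$analysis_mask)) paste("; analysis voxels:",
                                           sum(x$analysis_mask)) else "",
      "\n")
  invisible(x)
}

## Fetch one map array; errors name the missing (parameter, timepoint).
get_map <- function(study, parameter, timepoint_h, relative = FALSE) {
  src <- if (relative) study$relative_maps else study$maps
  key <- if (relative) paste0("r", sub("^r", "", parameter)) else parameter
  if (is.null(src[[key]])) stop("no ", key, " maps in study")
  m <- src[[key]][[as.character(timepoint_h)]]
  if (is.null(m)) stop("missing map (", key, ", ", timepoint_h, " h)")
  m
}
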