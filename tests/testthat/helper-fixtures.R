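## Shared fixtures: phantoms are generated in code (no binary data) and the
## expensive default-size runs are memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

## Reduced-grid phantom for fast unit tests.
small_phantom <- function(seed = 1, noiseless = FALSE, gm_shell = TRUE,
                          grid = c(32, 32, 16)) {
  noise <- if (noiseless) c(ADC = 0, FA = 0, T2 = 0) else
    c(ADC = 3.5e-5, FA = 0.0225, T2 = 4)
  generate_phantom(phantom_config(grid_shape = grid, seed = seed,
                                  noise_sd = noise, gm_shell = gm_shell))
}

## Default (full-size) phantom and its end-to-end pipeline run, at the
## package default seeds; computed once.
default_phantom <- function() {
  if (is.null(.fixture_cache$ph)) {
    .fixture_cache$ph <- generate_phantom(phantom_config())
  }
  .fixture_cache$ph
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_pipeline(default_phantom()$study,
                                       out_dir = NULL, seed = 1)
  }
  .fixture_cache$run
}

## Homogeneous-parenchyma phantom (no GM shell): the contralateral mean then
## equals the WM baseline, so relative values inside signature regions equal
## the configured multipliers exactly when noise is off.
homogeneous_phantom <- function(seed = 1, noiseless = TRUE) {
  key <- paste0("hom_", seed, "_", noiseless)
  if (is.null(.fixture_cache[[key]])) {
    noise <- if (noiseless) c(ADC = 0, FA = 0, T2 = 0) else
      c(ADC = 3.5e-5, FA = 0.0225, T2 = 4)
    .fixture_cache[[key]] <- generate_phantom(
      phantom_config(gm_shell = FALSE, noise_sd = noise, seed = seed))
  }
  .fixture_cache[[key]]
}

## Character label volume of the planted truth (N + signature ids).
truth_label_volume <- function(phantom) {
  lab <- array(NA_character_, dim(phantom$truth_labels))
  lab[phantom$study$brain_mask] <- "N"
  sel <- phantom$truth_labels > 0
  lab[sel] <- c("I", "II", "III", "IV", "V")[phantom$truth_labels[sel]]
  lab
}

## Minimal hand-built study for preprocessing unit tests: uniform maps whose
## values can be overwritten per test.
tiny_study <- function(vals = list(ADC = 1.0e-3, FA = 0.30, T2 = 80),
                       timepoints = c(1, 24), dims = c(6, 4, 4)) {
  mask <- array(TRUE, dims)
  hemi <- array(2L, dims)
  hemi[seq_len(dims[1] / 2), , ] <- 1L
  maps <- lapply(vals, function(v) {
    out <- lapply(timepoints, function(t) array(v, dims))
    names(out) <- as.character(timepoints)
    out
  })
  wm <- array(FALSE, dims); wm[dims[1] - 1, 1:2, 1] <- TRUE
  gm <- array(FALSE, dims); gm[dims[1], 3:4, 2] <- TRUE
  csf <- array(FALSE, dims); csf[1, 1, 1] <- TRUE
  serial_study(maps, timepoints, mask, hemi,
               ref_rois = list(wm = wm, gm = gm, csf = csf))
}

## Construct an isodata model around a plain feature matrix (for testing the
## split/merge/discard operations in isolation).
make_model <- function(X, assignments, centroids = NULL) {
  w <- stisodata:::global_diag_cov(X)
  k <- max(assignments)
  if (is.null(centroids)) {
    centroids <- rowsum(X, factor(assignments, levels = seq_len(k)))
    centroids <- unname(centroids / tabulate(assignments, k))
  }
  structure(list(centroids = centroids, assignments = assignments, cov = w,
                 sizes = tabulate(assignments, k), events = character()),
            class = "isodata_model")
}

## Wrap a plain matrix as a feature_matrix on a fake 1D grid, so operations
## that need voxel geometry (roi_rows etc.) can be tested directly.
as_feature_matrix <- function(X, timepoints = NULL, parameters = "rADC") {
  n <- nrow(X)
  if (is.null(timepoints)) timepoints <- seq_len(ncol(X))
  fi <- data.frame(column = seq_len(ncol(X)),
                   timepoint_h = rep(timepoints, each = length(parameters)),
                   parameter = rep(parameters, length(timepoints)))
  structure(list(data = X, voxel_index = cbind(seq_len(n) - 1L, 0L, 0L),
                 voxel_linear = seq_len(n), feature_index = fi,
                 standardization = NULL, grid_dim = c(n, 1L, 1L),
                 parameters = parameters, timepoints_h = timepoints),
            class = "feature_matrix")
}
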