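## Fake fitted model with interpretable (unstandardized) centroids: two
## parameters at three timepoints, constructed directly so pruning and
## normalization are tested in isolation from the clustering.
fake_model <- function(centroids, sizes) {
  n <- sum(sizes)
  asg <- rep(seq_along(sizes), sizes)
  fi <- data.frame(column = 1:6,
                   timepoint_h = rep(c(1, 24, 240), each = 2),
                   parameter = rep(c("rADC", "rT2"), 3))
  structure(list(centroids = centroids, assignments = asg,
                 cov = rep(1, 6), sizes = sizes, events = character(),
                 feature_index = fi, standardization = NULL,
                 voxel_linear = seq_len(n), grid_dim = c(n, 1L, 1L)),
            class = "isodata_model")
}

test_that("temporal CoV is sd/mean per parameter, pooled by maximum", {
  fi <- data.frame(column = 1:6, timepoint_h = rep(c(1, 24, 240), each = 2),
                   parameter = rep(c("rADC", "rT2"), 3))
  ## constant trajectories have zero CoV
  cv <- temporal_cov(c(2, 5, 2, 5, 2, 5), fi)
  expect_equal(unname(cv$per_parameter), c(0, 0))
  expect_equal(cv$pooled, 0)
  ## rADC trajectory (1, 3, 2): mean 2, population sd sqrt(2/3);
  ## rT2 trajectory (1, 3, 5): mean 3, population sd sqrt(8/3)
  cv2 <- temporal_cov(c(1, 1, 3, 3, 2, 5), fi)
  expect_equal(cv2$per_parameter[["rADC"]], sqrt(2 / 3) / 2)
  expect_equal(cv2$per_parameter[["rT2"]], sqrt(8 / 3) / 3)
  expect_equal(cv2$pooled, sqrt(8 / 3) / 3)
  ## two-point trajectory (1, 3): mean 2, population sd 1 -> CoV 0.5
  fi2 <- data.frame(column = 1:2, timepoint_h = c(1, 24),
                    parameter = c("rADC", "rADC"))
  expect_equal(temporal_cov(c(1, 3), fi2)$pooled, 0.5)
  ## scale invariance
  expect_equal(temporal_cov(c(10, 30), fi2)$pooled, 0.5)
  ## zero-mean trajectory is undefined
  expect_error(temporal_cov(c(-1, 1), fi2), "zero-mean")
  ## a single timepoint is rejected
  fi1 <- data.frame(column = 1, timepoint_h = 1, parameter = "rADC")
  expect_error(temporal_cov(1, fi1), "fewer than 2")
})

test_that("CoV pruning merges temporally flat clusters into normal", {
  cent <- rbind(c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0),    # flat
                c(0.9, 1.1, 0.9, 1.1, 0.9, 1.1),    # flat over time
                c(0.6, 1.1, 0.9, 1.6, 1.1, 1.9))    # dispersed
  m <- fake_model(cent, sizes = c(50, 30, 20))
  pr <- prune_by_cov(m, threshold = 0.05)
  expect_equal(pr$n_before, 3)
  expect_equal(pr$n_after, 2)
  expect_equal(pr$is_normal, c(TRUE, FALSE))
  ## conservation: abnormal + normal voxels = total
  expect_equal(sum(pr$sizes), 100)
  expect_equal(pr$sizes[1], 80)
  ## normal centroid is the size-weighted mean of the merged clusters
  expect_equal(pr$centroids[1, ],
               (50 * cent[1, ] + 30 * cent[2, ]) / 80)
  ## abnormal region volume picks out the dispersed cluster's voxels
  abn <- abnormal_region(pr)
  expect_equal(sum(abn), 20)
  ## all clusters flat -> a single normal cluster for any threshold > 0
  m2 <- fake_model(cent[1:2, ], sizes = c(50, 30))
  pr2 <- prune_by_cov(m2, threshold = 0.01)
  expect_equal(pr2$n_after, 1)
  expect_true(pr2$is_normal)
  ## threshold 0 retains every cluster with any temporal variation; the
  ## first two centroids are exactly time-constant, only the third varies
  pr3 <- prune_by_cov(m, threshold = 0)
  expect_equal(sum(!pr3$is_normal), 1)
  m4 <- fake_model(rbind(cent[1, ], cent[3, ] * 1e-3 + 1), c(10, 10))
  expect_equal(sum(!prune_by_cov(m4, threshold = 0)$is_normal), 1)
})

test_that("planted lesion clusters survive pruning on the phantom", {
  ph <- small_phantom(seed = 3)
  run <- run_pipeline(ph$study, out_dir = NULL, phi_N = 20, seed = 2)
  ## the lesion regions survive as abnormal clusters and overlap the truth
  expect_gte(run$summary$n_abnormal_clusters, 1)
  abn <- abnormal_region(run$pruned)
  truth_lesion <- ph$truth_labels > 0L
  ov <- dice_overlap(abn, truth_lesion,
                     run$study$hemisphere == 1L & run$study$analysis_mask)
  expect_gt(ov$DSI, 0.5)
})

test_that("normalization anchors WM to 1 and CSF to 100", {
  wm_ref <- c(1, 1, 1, 1, 1, 1)
  csf_ref <- c(4, 25, 4, 25, 4, 25)
  mid <- (wm_ref + csf_ref) / 2
  m <- fake_model(rbind(wm_ref, csf_ref, mid), sizes = c(10, 10, 10))
  vals <- normalize_clusters(m, csf_ref, wm_ref)
  expect_equal(unname(vals), c(1, 100, 50.5))
  ## invariance under a joint affine rescaling of centroids and references
  resc <- function(v) 3.7 * v - 2
  m2 <- fake_model(rbind(resc(wm_ref), resc(csf_ref), resc(mid)),
                   sizes = c(10, 10, 10))
  expect_equal(unname(normalize_clusters(m2, resc(csf_ref), resc(wm_ref))),
               c(1, 100, 50.5))
  ## monotone in relative CSF proximity
  q <- wm_ref + 0.25 * (csf_ref - wm_ref)
  m3 <- fake_model(rbind(wm_ref, q, mid, csf_ref), sizes = rep(5, 4))
  v3 <- normalize_clusters(m3, csf_ref, wm_ref)
  expect_true(all(diff(v3) > 0))
  expect_error(normalize_clusters(m, wm_ref, wm_ref), "coincident")
})

test_that("binning follows the printed tens-ranges with closed bounds", {
  expect_equal(as.character(bin_signatures(3)), "N")
  expect_equal(as.character(bin_signatures(30)), "II")
  expect_equal(as.character(bin_signatures(20)), "B2")
  expect_equal(as.character(bin_signatures(c(1, 5, 6, 15, 16, 25, 26))),
               c("N", "N", "I", "I", "B2", "B2", "II"))
  expect_equal(as.character(bin_signatures(c(36, 45, 46, 55, 56, 65, 66))),
               c("III", "III", "IV", "IV", "V", "V", "B7"))
  expect_equal(as.character(bin_signatures(c(75, 76, 85, 86, 95, 96, 100))),
               c("B7", "B8", "B8", "B9", "B9", "B10", "B10"))
  ## non-integer values use the same half-open intervals
  expect_equal(as.character(bin_signatures(c(5.5, 15.0001, 50.5))),
               c("I", "B2", "IV"))
  ## total and deterministic on the whole normalized range
  grid <- seq(1, 100, by = 0.25)
  b <- bin_signatures(grid)
  expect_false(any(is.na(b)))
  expect_identical(b, bin_signatures(grid))
  expect_error(bin_signatures(0.5), "\\[1, 100\\]")
  expect_error(bin_signatures(100.5), "\\[1, 100\\]")
})

test_that("temporal profiles recover uniform regions exactly", {
  ph <- homogeneous_phantom(noiseless = TRUE)
  st <- compute_relative_maps(apply_analysis_mask(ph$study))
  lab <- truth_label_volume(ph)
  prof <- signature_time_profiles(lab, st)
  expect_true(all(c("signature", "timepoint_h", "parameter", "mean",
                    "sd", "n") %in% names(prof)))
  ## Signature N is (1, 1, 1) at every timepoint with zero dispersion
  n_rows <- prof[prof$signature == "N", ]
  expect_equal(n_rows$mean, rep(1, nrow(n_rows)))
  expect_equal(max(n_rows$sd), 0)
  ## planted signatures recover the configured multipliers exactly
  for (i in seq_len(nrow(prof))) {
    p <- prof[i, ]
    if (p$signature == "N") next
    want <- signature_profile(p$signature, p$timepoint_h,
                              ph$config$signature_profiles)[[p$parameter]]
    expect_equal(p$mean, want, tolerance = 1e-12)
    expect_equal(p$sd, 0)
  }
  ## voxel counts are constant across timepoints per signature
  for (sig in unique(prof$signature)) {
    expect_equal(length(unique(prof$n[prof$signature == sig])), 1)
  }
})
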