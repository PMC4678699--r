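test_that("mahalanobis distance matches hand-evaluated quadratic forms", {
  expect_equal(mahalanobis_dist(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_dist(c(1, 0), c(0, 0), diag(2)), 1)
  ## cov = diag(4, 1), x - mu = (2, 0) -> sqrt(4 / 4) = 1
  expect_equal(mahalanobis_dist(c(2, 0), c(0, 0), c(4, 1)), 1)
  expect_equal(mahalanobis_dist(c(2, 0), c(0, 0), diag(c(4, 1))), 1)
  ## against the stats oracle on random full-covariance cases
  set.seed(31)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    S <- crossprod(A) + diag(3) * 0.5
    x <- rnorm(3); mu <- rnorm(3)
    expect_equal(mahalanobis_dist(x, mu, S),
                 sqrt(stats::mahalanobis(rbind(x), mu, S)[[1]]))
  }
  expect_error(mahalanobis_dist(c(1, 0), c(0, 0), matrix(0, 2, 2)),
               "singular")
})

test_that("dispersion parameters derive from WM/GM reference tissue", {
  ## 6 voxels on a fake grid; WM rows pooled values {0, 2}: population sd 1
  X <- rbind(c(0, 2), c(2, 0), c(5, 5), c(5, 7), c(1, 1), c(9, 9))
  f <- as_feature_matrix(X)
  wm <- array(FALSE, f$grid_dim); wm[1:2, 1, 1] <- TRUE
  gm <- array(FALSE, f$grid_dim); gm[3:4, 1, 1] <- TRUE
  d <- derive_dispersion_params(f, wm, gm)
  expect_equal(d$phi_S, 1)
  ## phi_C equals the Mahalanobis distance between the ROI means
  w <- stisodata:::global_diag_cov(X)
  expect_equal(d$phi_C, mahalanobis_dist(c(1, 1), c(5, 6), w))
  ## identical means -> phi_C of 0
  gm2 <- array(FALSE, f$grid_dim); gm2[c(2, 1), 1, 1] <- TRUE
  expect_equal(derive_dispersion_params(f, wm, gm2)$phi_C, 0)
  expect_error(derive_dispersion_params(f, array(FALSE, f$grid_dim), gm),
               "at least 2")
})

test_that("centroid initialization is seeded and spreads across clouds", {
  set.seed(1)
  ## two far-separated tight clouds: the second draw is proportional to the
  ## summed distance to the chosen centroids, so the opposite cloud carries
  ## nearly all of the selection mass
  cloud1 <- matrix(rnorm(60, 0, 0.1), ncol = 2)
  cloud2 <- matrix(rnorm(60, 10, 0.1), ncol = 2)
  X <- rbind(cloud1, cloud2)
  expect_equal(nrow(initialize_centroids(X, 1, seed = 3)), 1)
  expect_true(any(apply(X, 1, function(r)
    isTRUE(all.equal(r, initialize_centroids(X, 1, seed = 3)[1, ])))))
  expect_identical(initialize_centroids(X, 4, seed = 9),
                   initialize_centroids(X, 4, seed = 9))
  ## distance-proportional choice covers both clouds nearly always
  hits <- 0
  for (s in 1:100) {
    cent <- initialize_centroids(X, 2, seed = s)
    if (min(cent[, 1]) < 5 && max(cent[, 1]) > 5) hits <- hits + 1
  }
  expect_gte(hits, 95)
  expect_error(initialize_centroids(matrix(1, 4, 2), 3, seed = 1),
               "distinct")
})

test_that("voxels go to the nearest centroid with lowest-id ties", {
  X <- rbind(c(4, 0), c(0, 0), c(10, 0), c(5, 0))
  cent <- rbind(c(0, 0), c(10, 0))
  asg <- assign_voxels(X, cent, c(1, 1))
  expect_equal(asg, c(1L, 1L, 2L, 1L))  # (5,0) is equidistant -> cluster 1
  ## a single centroid takes everything
  expect_equal(assign_voxels(X, cent[1, , drop = FALSE], c(1, 1)),
               rep(1L, 4))
  ## a row equal to a centroid is assigned to it
  expect_equal(assign_voxels(rbind(c(10, 0)), cent, c(1, 1)), 2L)
})

test_that("small clusters are discarded and their voxels redistributed", {
  set.seed(7)
  X <- rbind(matrix(rnorm(200, 0, 0.3), ncol = 2),
             matrix(rnorm(200, 8, 0.3), ncol = 2),
             matrix(rnorm(6, 4, 0.1), ncol = 2))  # 3 stray rows
  asg <- c(rep(1L, 100), rep(2L, 100), rep(3L, 3))
  m <- make_model(X, asg)
  ## nothing happens when every cluster is large enough
  m_keep <- discard_small_clusters(m, X, phi_N = 3)
  expect_equal(nrow(m_keep$centroids), 3)
  ## phi_N = 100 discards the stray cluster; voxels move to the nearest
  m2 <- discard_small_clusters(m, X, phi_N = 100)
  expect_equal(nrow(m2$centroids), 2)
  expect_true(all(tabulate(m2$assignments, 2) >= 100))
  ## brute-force recount: every row is assigned, none lost
  expect_equal(length(m2$assignments), nrow(X))
  expect_equal(sum(tabulate(m2$assignments, 2)), nrow(X))
  ## all clusters undersized is degenerate
  expect_error(discard_small_clusters(m, X, phi_N = 1000), "degenerate")
})

test_that("splitting a two-blob cluster recovers the blobs", {
  set.seed(11)
  blob1 <- matrix(rnorm(100, 0, 0.2), ncol = 2)
  blob2 <- cbind(rnorm(50, 6, 0.2), rnorm(50, 0, 0.2))
  X <- rbind(blob1, blob2)
  labels <- rep(1:2, each = 50)
  m <- make_model(X, rep(1L, 100))
  m2 <- split_cluster(m, X, 1, phi_N = 10)
  expect_equal(nrow(m2$centroids), 2)
  ## children partition equals blob membership (up to label swap)
  agree <- max(mean((m2$assignments == 1) == (labels == 1)),
               mean((m2$assignments == 2) == (labels == 1)))
  expect_equal(agree, 1)
  ## split at the upper cluster bound is skipped and logged
  m3 <- split_cluster(m, X, 1, phi_N = 10, upper = 1)
  expect_equal(nrow(m3$centroids), 1)
  expect_match(m3$events, "split_skipped_bound", all = FALSE)
  ## split producing an undersized child is skipped
  m4 <- split_cluster(m, X, 1, phi_N = 60)
  expect_equal(nrow(m4$centroids), 1)
  expect_match(m4$events, "split_skipped_small", all = FALSE)
})

test_that("merging fuses the closest below-threshold pair, at most L times", {
  X <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
             matrix(rnorm(40, 1, 0.1), ncol = 2),
             matrix(rnorm(40, 2.2, 0.1), ncol = 2))
  asg <- rep(1:3, each = 20)
  m <- make_model(X, asg)
  ## distances all above phi_C: nothing merges
  m_no <- merge_clusters(m, X, phi_C = 1e-9, L = 3)
  expect_equal(nrow(m_no$centroids), 3)
  ## identical centroids merge on the first pass
  m_id <- make_model(X, asg, centroids = rbind(c(0, 0), c(0, 0), c(9, 9)))
  m_id2 <- merge_clusters(m_id, X, phi_C = 0.5, L = 3)
  expect_equal(nrow(m_id2$centroids), 2)
  ## three mutually close clusters with L = 1: exactly one merge
  m_one <- merge_clusters(m, X, phi_C = 1e6, L = 1)
  expect_equal(nrow(m_one$centroids), 2)
  expect_equal(sum(grepl("^merge", m_one$events)), 1)
  ## the lower cluster-count bound is respected
  m_low <- merge_clusters(m, X, phi_C = 1e6, L = 10, lower = 3)
  expect_equal(nrow(m_low$centroids), 3)
  ## merged centroid is the size-weighted mean (= mean of the union rows,
  ## since make_model centroids are exact cluster means)
  msz <- make_model(X, c(rep(1L, 30), rep(2L, 10), rep(3L, 20)))
  mm <- merge_clusters(msz, X, phi_C = 1e6, L = 1, lower = 1)
  ev <- grep("^merge:", mm$events, value = TRUE)[1]
  ij <- as.integer(strsplit(sub("merge:", "", ev), "\\+")[[1]])
  union_rows <- msz$assignments %in% ij
  expect_equal(mm$centroids[ij[1], ], colMeans(X[union_rows, ]))
  expect_equal(sum(mm$sizes), nrow(X))
})

test_that("ISODATA separates well-separated blobs and is deterministic", {
  set.seed(23)
  X <- rbind(matrix(rnorm(400, 0, 1), ncol = 2),
             matrix(rnorm(400, c(10, 10) * 1, 1), ncol = 2))
  labels <- rep(1:2, each = 200)
  p <- isodata_params(phi_N = 10, phi_C = 0.5, phi_S = 1e6, k = 2, K = 2,
                      I = 50)
  m <- run_isodata(X, p, seed = 4)
  expect_equal(nrow(m$centroids), 2)
  agree <- max(mean((m$assignments == 1) == (labels == 1)),
               mean((m$assignments == 2) == (labels == 1)))
  expect_equal(agree, 1)
  ## conservation at every logged iteration
  for (l in m$iteration_log) expect_equal(sum(l$sizes), nrow(X))
  ## bit-identical reruns
  m2 <- run_isodata(X, p, seed = 4)
  expect_identical(m$assignments, m2$assignments)
  expect_identical(m$centroids, m2$centroids)
})

test_that("a single blob with a large phi_C merges down to the lower bound", {
  set.seed(5)
  X <- matrix(rnorm(600, 0, 1), ncol = 2)
  p <- isodata_params(phi_N = 5, phi_C = 1e6, phi_S = 1e6, k = 4, K = 2,
                      I = 40)
  m <- run_isodata(X, p, seed = 8)
  ## lower bound for K = 2 is floor(1) + 1 = 2 clusters
  expect_equal(nrow(m$centroids), 2)
  expect_true(any(vapply(m$iteration_log,
                         function(l) any(grepl("^merge", l$events)),
                         logical(1))))
})

test_that("with discard, split and merge disabled the loop is Lloyd's algorithm", {
  set.seed(13)
  X <- matrix(rnorm(400, 0, 2), ncol = 2)
  init <- X[c(1, 2, 3), ]
  p <- isodata_params(phi_N = 1, phi_C = 1e-300, phi_S = Inf, k = 3, K = 3,
                      I = 100)
  m <- run_isodata(X, p, init_centroids = init)
  ## independent Lloyd oracle in the same whitened metric
  w <- stisodata:::global_diag_cov(X)
  Xs <- sweep(X, 2, sqrt(w), "/")
  cent <- sweep(init, 2, sqrt(w), "/")
  asg <- rep(0L, nrow(X))
  repeat {
    d2 <- sapply(seq_len(nrow(cent)), function(j)
      rowSums(sweep(Xs, 2, cent[j, ], "-")^2))
    new_asg <- max.col(-d2, ties.method = "first")
    if (identical(new_asg, asg)) break
    asg <- new_asg
    cent <- rowsum(Xs, asg) / tabulate(asg, nrow(cent))
  }
  expect_true(m$converged)
  expect_identical(m$assignments, asg)
})

test_that("reassignment never increases the within-cluster dispersion", {
  set.seed(17)
  X <- matrix(rnorm(300), ncol = 3)
  w <- stisodata:::global_diag_cov(X)
  cent <- X[sample(100, 4), ]
  total <- function(asg) {
    sum(vapply(seq_len(nrow(X)), function(i)
      mahalanobis_dist(X[i, ], cent[asg[i], ], w), numeric(1)))
  }
  for (rep_i in 1:5) {
    random_asg <- sample(4, 100, replace = TRUE)
    optimal <- assign_voxels(X, cent, w)
    expect_lte(total(optimal), total(random_asg))
  }
})

test_that("final clusters respect phi_N and the K-range on phantom data", {
  ph <- small_phantom(seed = 2)
  prep <- stisodata:::prepare_study(ph$study, c("ADC", "FA", "T2"))
  disp <- derive_dispersion_params(prep$features, prep$study$ref_rois$wm,
                                   prep$study$ref_rois$gm)
  p <- isodata_params(phi_N = 20, phi_C = disp$phi_C, phi_S = disp$phi_S)
  m <- run_isodata(prep$features, p, seed = 3)
  expect_true(all(m$sizes >= 20))
  expect_gt(nrow(m$centroids), 0.5 * p$K)
  expect_lt(nrow(m$centroids), 2 * p$K + 1)
  expect_equal(length(m$assignments), nrow(prep$features$data))
})
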