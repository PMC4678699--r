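## ISODATA clustering core: semi-randomized initialization, Mahalanobis
## assignment against a global diagonal covariance, small-cluster discard,
## dispersion-driven splitting and merging, and convergence control.

#' ISODATA control parameters
#'
#' @param phi_N Minimum voxels per cluster; smaller clusters are discarded
#'   and their voxels redistributed.
#' @param phi_C Minimum inter-cluster (centroid) Mahalanobis distance; closer
#'   pairs are merged. Typically derived from the contralateral WM-GM
#'   distance via [derive_dispersion_params()].
#' @param phi_S Maximum intra-cluster dispersion; clusters whose mean
#'   voxel-to-centroid Mahalanobis distance exceeds it are split. Typically
#'   the pooled standard deviation of WM feature values.
#' @param k Initial number of clusters.
#' @param K Cluster-range anchor: the live cluster count is kept strictly
#'   inside `(0.5 K, 2 K + 1)`, i.e. in `floor(K/2)+1 .. 2K`.
#' @param I Maximum number of iterations.
#' @param eps_r Convergence threshold on the maximum relative centroid
#'   displacement between successive iterations.
#' @param L Maximum number of merges per (merging) iteration.
#' @return List of class `isodata_params`.
#' @export
isodata_params <- function(phi_N = 100, phi_C, phi_S, k = 6, K = 8,
                           I = 100, eps_r = 1e-4, L = 1) {
  stopifnot(phi_N >= 1, phi_C > 0, phi_S > 0, k >= 1, K >= 1, I >= 1,
            eps_r > 0, L >= 1)
  structure(list(phi_N = phi_N, phi_C = phi_C, phi_S = phi_S,
                 k = as.integer(k), K = as.integer(K), I = as.integer(I),
                 eps_r = eps_r, L = as.integer(L)),
            class = "isodata_params")
}

## Allowed cluster-count range: integers strictly inside (0.5 K, 2 K + 1).
cluster_bounds <- function(K) {
  c(lower = floor(K / 2) + 1L, upper = 2L * K)
}

feature_data <- function(features) {
  if (is.matrix(features)) features else features$data
}

#' Mahalanobis distance
#'
#' `sqrt((x - mu)' cov^-1 (x - mu))`. `cov` may be a full symmetric positive
#' definite matrix or a numeric vector holding the diagonal of a diagonal
#' covariance.
#'
#' @param x,mu Numeric vectors of equal length.
#' @param cov Covariance: full matrix or diagonal vector.
#' @return Non-negative scalar; 0 iff `x == mu`.
#' @export
mahalanobis_dist <- function(x, mu, cov) {
  stopifnot(length(x) == length(mu))
  d <- x - mu
  if (is.matrix(cov)) {
    ch <- tryCatch(chol(cov), error = function(e) {
      stop("singular covariance in mahalanobis_dist")
    })
    z <- backsolve(ch, d, transpose = TRUE)
    sqrt(sum(z^2))
  } else {
    stopifnot(length(cov) == length(x))
    if (any(cov <= 0)) stop("singular covariance in mahalanobis_dist")
    sqrt(sum(d^2 / cov))
  }
}

## Global regularized diagonal covariance of the feature rows.
global_diag_cov <- function(X) {
  v <- colMeans(X^2) - colMeans(X)^2
  v <- pmax(v, 0)
  reg <- 1e-6 * mean(v)
  if (mean(v) == 0) stop("degenerate features: zero variance in every column")
  v + reg
}

## Squared Mahalanobis distances (diagonal cov w) of all rows to all
## centroids; V x k matrix.
dist2_to_centroids <- function(X, centroids, w) {
  M <- sweep(centroids, 2, w, "/")
  cross <- X %*% t(M)
  x2 <- rowSums(sweep(X^2, 2, w, "/"))
  mu2 <- rowSums(centroids * M)
  d2 <- x2 - 2 * cross + rep(mu2, each = nrow(X))
  pmax(d2, 0)
}

## Pairwise centroid Mahalanobis distances (diagonal cov w).
centroid_dist_matrix <- function(centroids, w) {
  Z <- sweep(centroids, 2, sqrt(w), "/")
  as.matrix(stats::dist(Z))
}

#' Derive the dispersion parameters from reference tissue
#'
#' `phi_C` is the Mahalanobis distance (global diagonal covariance) between
#' the mean contralateral WM and mean contralateral GM feature vectors;
#' `phi_S` is the population standard deviation of all WM-voxel feature
#' values pooled over every column.
#'
#' @param features A [build_feature_matrix()] result.
#' @param wm_roi,gm_roi Logical 3D ROIs (each must cover at least 2 feature
#'   rows).
#' @return Named list `phi_C`, `phi_S`.
#' @export
derive_dispersion_params <- function(features, wm_roi, gm_roi) {
  X <- features$data
  rw <- roi_rows(features, wm_roi)
  rg <- roi_rows(features, gm_roi)
  if (length(rw) < 2 || length(rg) < 2) {
    stop("WM and GM ROIs must each cover at least 2 in-mask voxels")
  }
  w <- global_diag_cov(X)
  phi_C <- mahalanobis_dist(colMeans(X[rw, , drop = FALSE]),
                            colMeans(X[rg, , drop = FALSE]), w)
  vals <- as.numeric(X[rw, , drop = FALSE])
  phi_S <- sqrt(mean((vals - mean(vals))^2))
  list(phi_C = phi_C, phi_S = phi_S)
}

#' Semi-randomized centroid initialization
#'
#' The first centroid is a uniformly random data row. Each subsequent
#' centroid is the candidate row at which the running sum of summed
#' Mahalanobis distances to all previously chosen centroids first exceeds a
#' uniform random fraction of the total, so rows far from the existing
#' centroids are picked with probability proportional to their distance.
#'
#' @param features Feature matrix (object or plain matrix).
#' @param k Number of centroids; must not exceed the number of distinct
#'   rows.
#' @param seed Integer seed; the draw is seed-deterministic.
#' @param cov Optional diagonal covariance; defaults to the global diagonal
#'   covariance of the rows.
#' @return `k x d` matrix of centroids.
#' @export
initialize_centroids <- function(features, k, seed = 1L, cov = NULL) {
  X <- feature_data(features)
  if (k > nrow(unique(X))) {
    stop("k = ", k, " exceeds the number of distinct feature rows")
  }
  w <- cov %||% global_diag_cov(X)
  with_seed(seed, {
    chosen <- sample.int(nrow(X), 1)
    s <- rep(0, nrow(X))
    while (length(chosen) < k) {
      mu <- X[chosen[length(chosen)], ]
      s <- s + sqrt(rowSums(sweep(sweep(X, 2, mu, "-")^2, 2, w, "/")))
      cand <- setdiff(seq_len(nrow(X)), chosen)
      tot <- sum(s[cand])
      if (tot <= 0) {
        chosen <- c(chosen, cand[1])
      } else {
        u <- stats::runif(1)
        cum <- cumsum(s[cand])
        chosen <- c(chosen, cand[which(cum > u * tot)[1]])
      }
    }
    X[chosen, , drop = FALSE]
  })
}

#' Assign rows to the nearest centroid
#'
#' Each feature row goes to the centroid with the smallest Mahalanobis
#' distance; ties break toward the lowest cluster id.
#'
#' @param features Feature matrix (object or plain matrix).
#' @param centroids `k x d` matrix.
#' @param cov Diagonal covariance vector (length d).
#' @return Integer vector of cluster ids (1..k).
#' @export
assign_voxels <- function(features, centroids, cov) {
  X <- feature_data(features)
  stopifnot(ncol(X) == ncol(centroids), nrow(centroids) >= 1)
  d2 <- dist2_to_centroids(X, centroids, cov)
  max.col(-d2, ties.method = "first")
}

## Mean Mahalanobis distance of member rows to their centroid, per cluster.
cluster_D_intra <- function(X, assignments, centroids, w) {
  rowd <- sqrt(rowSums(sweep((X - centroids[assignments, , drop = FALSE])^2,
                             2, w, "/")))
  as.numeric(tapply(rowd, factor(assignments, levels = seq_len(nrow(centroids))),
                    mean, default = NA_real_))
}

recompute_centroids <- function(model, X) {
  k <- nrow(model$centroids)
  sizes <- tabulate(model$assignments, nbins = k)
  cent <- rowsum(X, group = factor(model$assignments, levels = seq_len(k)))
  cent <- cent / pmax(sizes, 1)
  cent[sizes == 0, ] <- model$centroids[sizes == 0, ]
  model$centroids <- unname(cent)
  model$sizes <- sizes
  model
}

new_isodata_model <- function(centroids, assignments, cov) {
  m <- structure(list(centroids = centroids, assignments = assignments,
                      cov = cov, sizes = NULL, events = character()),
                 class = "isodata_model")
  m$sizes <- tabulate(assignments, nbins = nrow(centroids))
  m
}

#' Discard undersized clusters
#'
#' Removes clusters with fewer than `phi_N` members and redistributes their
#' rows to the nearest surviving centroid; surviving centroids are then
#' recomputed. Errors if every cluster is undersized.
#'
#' @param model An `isodata_model` (list with `centroids`, `assignments`,
#'   `cov`).
#' @param features Feature matrix (object or plain matrix).
#' @param phi_N Minimum cluster size.
#' @return Updated model; discarded cluster ids are appended to
#'   `model$events`.
#' @export
discard_small_clusters <- function(model, features, phi_N) {
  X <- feature_data(features)
  sizes <- tabulate(model$assignments, nbins = nrow(model$centroids))
  small <- sizes < phi_N
  if (!any(small)) {
    model$sizes <- sizes
    return(model)
  }
  if (all(small)) stop("degenerate configuration: every cluster is below phi_N")
  keep <- which(!small)
  model$events <- c(model$events, paste0("discard:", which(small)))
  new_id <- match(model$assignments, keep)
  orphan <- is.na(new_id)
  model$centroids <- model$centroids[keep, , drop = FALSE]
  if (any(orphan)) {
    new_id[orphan] <- assign_voxels(X[orphan, , drop = FALSE],
                                    model$centroids, model$cov)
  }
  model$assignments <- new_id
  recompute_centroids(model, X)
}

#' Split one overdispersed cluster
#'
#' Replaces the cluster's centroid `mu` by two children `mu +/- gamma *
#' sigma_max * e_max`, where `e_max` is the axis of largest per-column
#' standard deviation within the cluster, then reassigns the cluster's rows
#' between the children. The split is skipped (and logged) when it would
#' push the cluster count past `upper` or leave a child below `phi_N`.
#'
#' @param model An `isodata_model`.
#' @param features Feature matrix (object or plain matrix).
#' @param cluster_id Cluster to split.
#' @param phi_N Minimum size of each child.
#' @param upper Maximum allowed cluster count (default unlimited).
#' @param gamma Centroid offset as a fraction of `sigma_max` (default 0.5).
#' @return Updated model; `model$events` records `split:<id>` or the skip
#'   reason.
#' @export
split_cluster <- function(model, features, cluster_id, phi_N = 1,
                          upper = Inf, gamma = 0.5) {
  X <- feature_data(features)
  k <- nrow(model$centroids)
  if (k + 1 > upper) {
    model$events <- c(model$events, paste0("split_skipped_bound:", cluster_id))
    return(model)
  }
  rows <- which(model$assignments == cluster_id)
  sub <- X[rows, , drop = FALSE]
  sds <- sqrt(pmax(colMeans(sub^2) - colMeans(sub)^2, 0))
  ax <- which.max(sds)
  mu <- model$centroids[cluster_id, ]
  c1 <- mu; c1[ax] <- mu[ax] + gamma * sds[ax]
  c2 <- mu; c2[ax] <- mu[ax] - gamma * sds[ax]
  side <- assign_voxels(sub, rbind(c1, c2), model$cov)
  if (min(tabulate(side, 2)) < phi_N) {
    model$events <- c(model$events, paste0("split_skipped_small:", cluster_id))
    return(model)
  }
  model$centroids <- rbind(model$centroids, c2)
  model$centroids[cluster_id, ] <- c1
  model$assignments[rows[side == 2]] <- k + 1L
  model$events <- c(model$events, paste0("split:", cluster_id))
  recompute_centroids(model, X)
}

#' Merge too-close clusters
#'
#' Repeatedly merges the closest centroid pair whose Mahalanobis distance is
#' below `phi_C` (merged centroid = size-weighted mean), at most `L` times,
#' and never below `lower` clusters.
#'
#' @param model An `isodata_model`.
#' @param features Feature matrix (object or plain matrix).
#' @param phi_C Minimum inter-cluster distance.
#' @param L Maximum merges.
#' @param lower Minimum allowed cluster count.
#' @return Updated model with `merge:<i>+<j>` events recorded.
#' @export
merge_clusters <- function(model, features, phi_C, L = 1, lower = 1) {
  X <- feature_data(features)
  merges <- 0L
  repeat {
    k <- nrow(model$centroids)
    if (merges >= L || k <= max(lower, 1)) break
    D <- centroid_dist_matrix(model$centroids, model$cov)
    diag(D) <- Inf
    if (min(D) >= phi_C) break
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    si <- model$sizes[i]; sj <- model$sizes[j]
    model$centroids[i, ] <- (si * model$centroids[i, ] +
                               sj * model$centroids[j, ]) / (si + sj)
    model$assignments[model$assignments == j] <- i
    model$assignments[model$assignments > j] <-
      model$assignments[model$assignments > j] - 1L
    model$centroids <- model$centroids[-j, , drop = FALSE]
    model$sizes <- tabulate(model$assignments, nbins = k - 1L)
    model$events <- c(model$events, paste0("merge:", i, "+", j))
    merges <- merges + 1L
  }
  model
}

#' Run ISODATA clustering
#'
#' Iterates assignment, small-cluster discard, and dispersion-driven
#' splitting (odd iterations: the single worst cluster with `D_intra >
#' phi_S`) or merging (even iterations: up to `L` pairs with `D_inter <
#' phi_C`), keeping the cluster count strictly inside `(0.5 K, 2 K + 1)`.
#' Convergence is reached when an iteration makes no structural change and
#' the maximum relative centroid displacement falls below `eps_r`; hitting
#' the iteration cap `I` without convergence is logged, not an error.
#'
#' @param features A [build_feature_matrix()] result (or plain numeric
#'   matrix).
#' @param params An [isodata_params()] object.
#' @param seed Integer seed for the centroid initialization.
#' @param init_centroids Optional `k x d` matrix overriding the seeded
#'   initialization (used for controlled comparisons).
#' @return Object of class `isodata_model` with `centroids`, `assignments`,
#'   `sizes`, `cov` (global diagonal covariance), `D_intra`, `iteration_log`
#'   (per-iteration sizes, dispersions, events, convergence error),
#'   `converged`, `n_iter`, `seed`, `params`, and -- when built from a
#'   `feature_matrix` -- the `feature_index`, `standardization`,
#'   `voxel_linear`, and `grid_dim` needed by downstream stages.
#' @export
run_isodata <- function(features, params, seed = 1L, init_centroids = NULL) {
  stopifnot(inherits(params, "isodata_params"))
  X <- feature_data(features)
  if (nrow(X) < params$phi_N) {
    stop("fewer feature rows (", nrow(X), ") than phi_N (", params$phi_N, ")")
  }
  w <- global_diag_cov(X)
  bounds <- cluster_bounds(params$K)
  cent <- init_centroids %||%
    initialize_centroids(X, params$k, seed = seed, cov = w)
  model <- new_isodata_model(cent, rep(1L, nrow(X)), w)
  iteration_log <- list()
  converged <- FALSE
  prev_cent <- NULL
  D_intra <- NULL
  for (it in seq_len(params$I)) {
    model$events <- character()
    model$assignments <- assign_voxels(X, model$centroids, w)
    model <- recompute_centroids(model, X)
    model <- discard_small_clusters(model, X, params$phi_N)
    D_intra <- cluster_D_intra(X, model$assignments, model$centroids, w)
    if (it %% 2 == 1) {
      offenders <- which(D_intra > params$phi_S)
      if (length(offenders)) {
        worst <- offenders[which.max(D_intra[offenders])]
        model <- split_cluster(model, X, worst, phi_N = params$phi_N,
                               upper = bounds["upper"])
      }
    } else {
      model <- merge_clusters(model, X, params$phi_C, L = params$L,
                              lower = bounds["lower"])
    }
    structural <- length(grep("^(discard|split:|merge)", model$events)) > 0
    if (!structural && !is.null(prev_cent) &&
        nrow(prev_cent) == nrow(model$centroids)) {
      num <- sqrt(rowSums((model$centroids - prev_cent)^2))
      den <- sqrt(rowSums(prev_cent^2)) + 1e-12
      err <- max(num / den)
    } else {
      err <- Inf
    }
    iteration_log[[it]] <- list(iteration = it,
                                n_clusters = nrow(model$centroids),
                                sizes = model$sizes,
                                D_intra = D_intra,
                                events = model$events,
                                conv_error = err)
    prev_cent <- model$centroids
    if (err < params$eps_r) {
      converged <- TRUE
      break
    }
  }
  model$D_intra <- D_intra
  model$iteration_log <- iteration_log
  model$converged <- converged
  model$n_iter <- length(iteration_log)
  model$seed <- seed
  model$params <- params
  if (!is.matrix(features)) {
    model$feature_index <- features$feature_index
    model$standardization <- features$standardization
    model$voxel_linear <- features$voxel_linear
    model$grid_dim <- features$grid_dim
  }
  model
}

#' @export
print.isodata_model <- function(x, ...) {
  cat("isodata_model:", nrow(x$centroids), "clusters over",
      length(x$assignments), "voxels;",
      if (isTRUE(x$converged)) "converged" else "iteration cap reached",
      "after", x$n_iter, "iteration(s)\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster assignments as a labeled volume
#'
#' @param model An `isodata_model` fitted on a `feature_matrix`.
#' @param labels Optional per-cluster values to paint instead of cluster
#'   ids.
#' @param background Value outside the analysis mask.
#' @return 3D array on the original grid.
#' @export
assignments_volume <- function(model, labels = NULL, background = 0) {
  if (is.null(model$voxel_linear)) {
    stop("model carries no voxel geometry (fitted on a plain matrix?)")
  }
  vol <- array(background, model$grid_dim)
  vals <- if (is.null(labels)) model$assignments else labels[model$assignments]
  vol[model$voxel_linear] <- vals
  vol
}
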