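`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Ellipsoid voxel mask
#'
#' Logical 3D mask of voxels inside an axis-aligned ellipsoid. Voxel
#' coordinates are 0-based, so a grid of size `n` spans indices `0..n-1`.
#'
#' @param dim Integer vector of length 3, grid size in voxels.
#' @param center Numeric length 3, ellipsoid center in 0-based voxel
#'   coordinates.
#' @param radii Numeric length 3, semi-axes in voxels (must be positive).
#' @return Logical array of dimension `dim`; `TRUE` where
#'   `sum(((x - center) / radii)^2) <= 1`.
#' @export
ellipsoid_mask <- function(dim, center, radii) {
  stopifnot(length(dim) == 3, length(center) == 3, length(radii) == 3,
            all(radii > 0))
  gx <- ((seq_len(dim[1]) - 1 - center[1]) / radii[1])^2
  gy <- ((seq_len(dim[2]) - 1 - center[2]) / radii[2])^2
  gz <- ((seq_len(dim[3]) - 1 - center[3]) / radii[3])^2
  r2 <- outer(outer(gx, gy, `+`), gz, `+`)
  array(r2 <= 1, dim = dim)
}

## out[i, j, k] = a[i + off1, j + off2, k + off3] where in range, `fill`
## elsewhere. Used for neighborhood sums and binary dilation.
shift3 <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  dst <- lapply(1:3, function(ax) max(1L, 1L - off[ax]):min(d[ax], d[ax] - off[ax]))
  if (any(vapply(1:3, function(ax) dst[[ax]][1] > dst[[ax]][length(dst[[ax]])] ||
                 d[ax] < 1, logical(1)))) {
    return(out)
  }
  src <- lapply(1:3, function(ax) dst[[ax]] + off[ax])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Gaussian-distance-weighted neighborhood mean inside a mask.
## Out-of-mask neighbors get zero weight; the center voxel carries w(0) = 1,
## so the neighborhood is never empty for an in-mask voxel.
gaussian_neighborhood_mean <- function(vol, mask, radius = 1, decay = 1) {
  stopifnot(all(dim(vol) == dim(mask)), radius >= 1, decay > 0)
  offs <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                                dz = -radius:radius))
  num <- array(0, dim(vol))
  den <- array(0, dim(vol))
  mnum <- mask * 1
  vm <- vol * mnum
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    w <- exp(-sum(off^2) / (2 * decay^2))
    num <- num + w * shift3(vm, off)
    den <- den + w * shift3(mnum, off)
  }
  iso <- mask & abs(den - 1) < 1e-12
  if (any(iso)) {
    warning(sum(iso), " isolated in-mask voxel(s): no in-mask neighbors, ",
            "values left unchanged")
  }
  out <- vol
  out[mask] <- (num / den)[mask]
  out
}

## Deterministic per-configuration seed derived from a master seed and a
## label, stable under grid reordering. Kept below 2^31.
derive_seed <- function(master_seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master_seed) * 10007 + h * 131 + index) %% 2147483629)
}

stop_shape <- function(a, b, what = "inputs") {
  if (!all(dim(a) == dim(b))) {
    stop(what, " have mismatching grid shapes: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
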