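#' Parcel-wise correlation of MTL connectivity with an axis
#'
#' For every isocortical parcel, the product-moment correlation (across MTL
#' voxels) between voxel-to-parcel functional connectivity and the voxel's
#' axis position. Positive values mean higher connectivity towards the
#' allocortical (or posterior) end of the axis.
#'
#' @param mtl_ts `n_time x n_voxels` MTL voxel timeseries
#' @param voxel_axis axis value per MTL voxel
#' @param parcel_ts `n_time x n_parcels` parcel timeseries
#' @param covariates optional per-voxel covariates partialled out of both
#'   the connectivity column and the axis (e.g. SNR maps)
#' @return list: `r` (per-parcel correlation; `NA` sentinel where
#'   undefined), `connectivity` (voxel x parcel correlation matrix)
#' @export
axis_fc_map <- function(mtl_ts, voxel_axis, parcel_ts, covariates = NULL) {
  if (ncol(mtl_ts) < 10L) stop("need at least 10 MTL voxels")
  if (nrow(mtl_ts) != nrow(parcel_ts))
    stop("time axes differ: ", nrow(mtl_ts), " vs ", nrow(parcel_ts))
  conn <- stats::cor(mtl_ts, parcel_ts)
  if (stats::sd(voxel_axis) == 0) {
    warning("constant axis: all correlations undefined")
    return(list(r = rep(NA_real_, ncol(parcel_ts)), connectivity = conn))
  }
  r <- numeric(ncol(parcel_ts))
  for (p in seq_len(ncol(parcel_ts))) {
    col <- conn[, p]
    if (stats::sd(col) == 0) {
      warning("constant connectivity for parcel ", p, ": r set NA")
      r[p] <- NA_real_
    } else if (is.null(covariates)) {
      r[p] <- stats::cor(col, voxel_axis)
    } else {
      r[p] <- partial_correlation(col, voxel_axis, covariates)
    }
  }
  list(r = r, connectivity = conn)
}

#' Functional gradients of a parcel connectome
#'
#' Transforms a parcel-parcel correlation matrix into a normalised-angle
#' affinity `1 - acos(r)/pi`, row-sparsifies it and extracts the leading
#' diffusion-map eigenvectors (the functional gradients).
#'
#' @param connectome symmetric parcel x parcel correlation matrix with
#'   entries in `[-1, 1]`
#' @param k number of gradients to return
#' @param sparsity,alpha passed to [diffusion_embedding()]
#' @return an `embedding` with `k` components
#' @export
functional_gradients <- function(connectome, k = 3L, sparsity = 0.75,
                                 alpha = 0.5) {
  m <- as.matrix(connectome)
  if (max(abs(m)) > 1 + 1e-8) stop("correlations outside [-1, 1]")
  m <- pmin(pmax(m, -1), 1)
  ang <- 1 - acos(m) / pi
  diag(ang) <- 0
  emb <- diffusion_embedding(ang, n_components = k, alpha = alpha,
                             sparsity = sparsity)
  emb$vectors <- emb$vectors[, seq_len(k), drop = FALSE]
  emb$values <- emb$values[seq_len(k)]
  emb
}

#' Random rotation matrices (uniform over SO(3))
#' @param n_spins number of rotations
#' @param seed integer seed
#' @return list of 3 x 3 rotation matrices
#' @export
random_rotations <- function(n_spins, seed = 1L) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_spins), function(i) {
    q <- qr(matrix(stats::rnorm(9), 3, 3))
    r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(r) < 0) r[, 3] <- -r[, 3]
    r
  })
}

#' Spin permutation nulls for spherical parcel maps
#'
#' Applies uniform random 3D rotations to the parcel centroids and
#' reassigns each parcel the value of the nearest rotated centroid,
#' preserving the spatial autocorrelation of the map under the null.
#'
#' @param centroids `n x 3` unit-norm parcel centroids
#' @param values per-parcel map values
#' @param n_spins number of null maps
#' @param seed integer seed
#' @return `n x n_spins` matrix of null maps; attribute
#'   `"duplication_rate"` reports the mean fraction of source parcels
#'   reused more than once per spin.
#' @export
spin_permutation <- function(centroids, values, n_spins = 1000L, seed = 1L) {
  centroids <- as.matrix(centroids)
  stopifnot(length(values) == nrow(centroids))
  sv <- svd(scale(centroids, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-300))
    stop("degenerate centroids (collinear): spin test undefined")
  perms <- spin_assignments(centroids, n_spins, seed)
  nulls <- matrix(values[perms], nrow(centroids), n_spins)
  dup <- apply(perms, 2L, function(p) 1 - length(unique(p)) / length(p))
  attr(nulls, "duplication_rate") <- mean(dup)
  nulls
}

#' Precompute spin-permutation assignment indices
#'
#' @inheritParams spin_permutation
#' @return `n x n_spins` integer matrix: entry (p, s) is the source parcel
#'   whose value parcel `p` takes in spin `s`
#' @export
spin_assignments <- function(centroids, n_spins = 1000L, seed = 1L) {
  centroids <- as.matrix(centroids)
  rots <- random_rotations(n_spins, seed)
  out <- matrix(NA_integer_, nrow(centroids), n_spins)
  for (s in seq_len(n_spins)) {
    rot <- centroids %*% t(rots[[s]])    # rotated centroids
    ## nearest rotated centroid per original parcel = max dot product
    out[, s] <- max.col(centroids %*% t(rot), ties.method = "first")
  }
  out
}

#' Correspondence of an axis r-map with functional gradients
#'
#' Spearman correlation of the map with each gradient; significance from
#' spin permutations (two-sided by default); specificity from pairwise
#' dependent-correlation z-tests between gradients (they share the common
#' map).
#'
#' @param map per-parcel axis correlation values (e.g. `$r` from
#'   [axis_fc_map()])
#' @param gradients `embedding` or parcel x k matrix of gradient values
#' @param centroids parcel centroids on the unit sphere
#' @param n_spins number of spin permutations (warning below 100)
#' @param seed integer seed
#' @param two_sided two-sided spin p-values (default TRUE)
#' @param assignments optional precomputed [spin_assignments()] matrix
#' @return list: `rho` (per gradient), `p_spin`, `specificity` (data frame
#'   of pairwise z/p), `null_rho` (spins x gradients)
#' @export
map_gradient_correspondence <- function(map, gradients, centroids,
                                        n_spins = 1000L, seed = 1L,
                                        two_sided = TRUE,
                                        assignments = NULL) {
  g <- if (inherits(gradients, "embedding")) gradients$vectors
       else as.matrix(gradients)
  if (is.null(centroids) && is.null(assignments))
    stop("centroids required for spin permutations")
  if (n_spins < 100L) warning("n_spins < 100: p-values are coarse")
  ok <- is.finite(map)
  rho <- suppressWarnings(
    stats::cor(map[ok], g[ok, , drop = FALSE], method = "spearman"))[1, ]
  if (is.null(assignments))
    assignments <- spin_assignments(centroids, n_spins, seed)
  n_spins <- ncol(assignments)
  nulls <- matrix(map[assignments], nrow(g), n_spins)
  null_rho <- suppressWarnings(
    stats::cor(nulls[ok, , drop = FALSE], g[ok, , drop = FALSE],
               method = "spearman"))
  p_spin <- vapply(seq_along(rho), function(j) {
    obs <- rho[j]; nv <- null_rho[, j]
    if (two_sided) (1 + sum(abs(nv) >= abs(obs))) / (n_spins + 1)
    else (1 + sum(nv >= obs)) / (n_spins + 1)
  }, numeric(1))
  k <- length(rho)
  spec <- NULL
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    spec <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c0) {
      i <- pairs[1, c0]; j <- pairs[2, c0]
      ## compare |rho| on rank-transformed variables (Spearman-scale test)
      clamp <- function(r) min(max(r, -1 + 1e-12), 1 - 1e-12)
      ri <- clamp(stats::cor(rank(map[ok]), rank(g[ok, i])))
      rj <- clamp(stats::cor(rank(map[ok]), rank(g[ok, j])))
      rij <- stats::cor(rank(g[ok, i]), rank(g[ok, j]))
      si <- sign(ri); sj <- sign(rj)
      cmp <- compare_dependent_correlations(abs(ri), abs(rj), si * sj * rij,
                                            n = sum(ok))
      data.frame(gradient_a = i, gradient_b = j, z = cmp$z, p = cmp$p)
    }))
  }
  list(rho = rho, p_spin = p_spin, specificity = spec, null_rho = null_rho)
}

#' Voxelwise spatial and temporal signal-to-noise ratios
#'
#' Spatial SNR: voxel temporal mean divided by the SD of the temporal
#' means across all (grey-matter) voxels. Temporal SNR: voxel temporal
#' mean divided by the voxel's own temporal SD (NA sentinel at zero
#' temporal SD).
#'
#' @param raw_ts `n_time x n_voxels` raw (non-demeaned) voxel timeseries
#' @param gm_ts optional `n_time x n_gm` grey-matter series for the
#'   across-voxel SD (defaults to `raw_ts`)
#' @return data frame with `spatial_snr`, `temporal_snr`
#' @export
voxel_snr <- function(raw_ts, gm_ts = NULL) {
  if (is.null(gm_ts)) gm_ts <- raw_ts
  mu <- colMeans(raw_ts)
  sd_across <- stats::sd(colMeans(gm_ts))
  sd_t <- apply(raw_ts, 2L, stats::sd)
  tsnr <- mu / sd_t
  if (any(sd_t == 0)) {
    warning(sum(sd_t == 0), " voxels with zero temporal SD: tSNR set NA")
    tsnr[sd_t == 0] <- NA_real_
  }
  data.frame(spatial_snr = mu / sd_across, temporal_snr = tsnr)
}

#' SNR-controlled axis connectivity maps
#'
#' Recomputes the axis r-map with spatial and temporal SNR partialled out
#' of both the connectivity and the axis, and reports the product-moment
#' correlation between the original and controlled maps.
#'
#' @param mtl_ts_raw raw (non-demeaned) `n_time x n_voxels` MTL series
#' @param voxel_axis axis per voxel
#' @param parcel_ts `n_time x n_parcels` parcel series
#' @param gm_ts optional grey-matter series for spatial SNR
#' @return list: `snr` (per-voxel table), `map` (uncontrolled r),
#'   `map_controlled`, `agreement` (correlation of the two maps)
#' @export
snr_controls <- function(mtl_ts_raw, voxel_axis, parcel_ts, gm_ts = NULL) {
  snr <- voxel_snr(mtl_ts_raw, gm_ts)
  base <- axis_fc_map(mtl_ts_raw, voxel_axis, parcel_ts)
  cv <- as.matrix(snr)
  ok_cv <- stats::complete.cases(cv)
  ctrl <- axis_fc_map(mtl_ts_raw[, ok_cv, drop = FALSE],
                      voxel_axis[ok_cv], parcel_ts,
                      covariates = cv[ok_cv, , drop = FALSE])
  ok <- is.finite(base$r) & is.finite(ctrl$r)
  list(snr = snr, map = base$r, map_controlled = ctrl$r,
       agreement = stats::cor(base$r[ok], ctrl$r[ok]))
}

#' Recompute gradient correspondence excluding flagged parcels
#'
#' Drops flagged parcels (e.g. temporal-lobe parcels) from the map, the
#' gradients and the centroids, and recomputes [map_gradient_correspondence()].
#'
#' @param map per-parcel values
#' @param gradients `embedding` or matrix
#' @param centroids parcel centroids
#' @param flags logical: TRUE = exclude
#' @param ... passed to [map_gradient_correspondence()]
#' @return list as from [map_gradient_correspondence()], plus `n_retained`
#' @export
exclude_parcels <- function(map, gradients, centroids, flags, ...) {
  g <- if (inherits(gradients, "embedding")) gradients$vectors
       else as.matrix(gradients)
  keep <- !flags
  if (sum(keep) < 50L)
    warning("only ", sum(keep), " parcels retained (< 50)")
  out <- map_gradient_correspondence(map[keep], g[keep, , drop = FALSE],
                                     centroids[keep, , drop = FALSE], ...)
  out$n_retained <- sum(keep)
  out
}
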