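#' Evenly distributed points on the unit sphere (Fibonacci lattice)
#'
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

## Smooth orthonormal patterns on the sphere: random mixtures of first- and
## second-degree solid harmonics, Gram-Schmidt orthonormalised over the
## sample. Mixing degrees keeps spin-rotation null distributions
## non-degenerate (pure harmonics of different degree remain orthogonal
## under every rotation). Draws from the current RNG state.
smooth_sphere_patterns <- function(centroids, k) {
  x <- centroids[, 1]; y <- centroids[, 2]; z <- centroids[, 3]
  basis <- cbind(z, x, y, x * y, x^2 - y^2, x * z, y * z, 3 * z^2 - 1)
  if (k > ncol(basis)) stop("at most ", ncol(basis), " patterns supported")
  ## anchored mixtures: loading k is dominated by one harmonic (z, x, xy,
  ## ...) plus a moderate random admixture of the others, so patterns stay
  ## distinct (recoverable in order) while spanning both degrees
  anchors <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L, 8L)
  mix <- matrix(stats::rnorm(ncol(basis) * k, sd = 0.35), ncol(basis), k)
  for (j in seq_len(k)) mix[anchors[j], j] <- mix[anchors[j], j] + 1
  q <- qr.Q(qr(cbind(1, basis %*% mix)))[, -1, drop = FALSE]
  sweep(q, 2, sqrt(colSums(q^2)), "/") * sqrt(nrow(q))
}

#' Synthetic parcel + MTL voxel timeseries with programmed gradients
#'
#' Emulates the inputs of the macroscale analyses: parcel timeseries whose
#' correlation matrix has programmed low-rank structure over smooth
#' spherical patterns (the ground-truth functional gradients), and MTL voxel
#' timeseries whose connectivity to parcels varies linearly with programmed
#' voxel axes against chosen patterns.
#'
#' Each latent source `S_k` (variance `latent_sd[k]^2`) projects onto
#' parcels through loading pattern `k` and onto MTL voxels with weight
#' `base_coupling + sum_a interactions[a, k] * (axis_a - 0.5)`, so the
#' parcel-wise correlation between voxel->parcel connectivity and axis `a`
#' is proportional to `sum_k interactions[a, k] * loading_k` across parcels.
#'
#' @param n_parcels number of isocortical parcels (>= 10)
#' @param n_mtl_voxels number of MTL voxels
#' @param loadings either an integer k (generate k smooth orthonormal
#'   spherical patterns) or an `n_parcels x k` matrix of patterns
#' @param seed integer seed
#' @param n_time number of timepoints
#' @param latent_sd SDs of the k latent sources (decreasing; sets gradient
#'   order)
#' @param interactions `n_axes x k` matrix of programmed axis-pattern
#'   interaction strengths (default: axis A with pattern 1, axis B with
#'   pattern 3)
#' @param base_coupling common voxel-source coupling
#' @param noise_sd observation noise SD for both parcels and voxels
#' @param background_rank number of weak smooth background factors mixed
#'   into the parcel timeseries (voxels do not couple to them). Real
#'   connectomes are not low-rank; without background structure the
#'   finite-sample noise of the voxel-parcel correlations concentrates
#'   along the few programmed patterns and masquerades as signal.
#' @param background_sd SD of each background factor
#' @param offset mean raw-signal level of the voxel series; each voxel gets
#'   an offset jittered uniformly within +/-20% of this value so that
#'   spatial and temporal SNR vary across voxels (axis-independently)
#' @return list with `parcel_ts` (time x parcel), `mtl_ts` (time x voxel),
#'   `centroids` (unit sphere), `loadings` (ground-truth gradient patterns),
#'   `voxel_axes` (voxel x n_axes), `interactions`, `latent_sd`
#' @export
make_gradient_parcel_data <- function(n_parcels = 1000L, n_mtl_voxels = 300L,
                                      loadings = 3L, seed = 1L,
                                      n_time = 2400L,
                                      latent_sd = c(1, 0.8, 0.65),
                                      interactions = NULL,
                                      base_coupling = 0.4,
                                      noise_sd = 0.7,
                                      background_rank = 40L,
                                      background_sd = 0.3, offset = 100) {
  if (n_parcels < 10) stop("n_parcels must be >= 10")
  set.seed(as.integer(seed))
  centroids <- fibonacci_sphere(n_parcels)
  if (is.matrix(loadings)) {
    L <- loadings
    stopifnot(nrow(L) == n_parcels)
  } else {
    L <- smooth_sphere_patterns(centroids, as.integer(loadings))
  }
  k <- ncol(L)
  if (length(latent_sd) < k) latent_sd <- rep_len(latent_sd, k)
  latent_sd <- latent_sd[seq_len(k)]
  if (is.null(interactions)) {
    interactions <- matrix(0, 2, k)
    interactions[1, 1] <- 0.8
    if (k >= 3) interactions[2, 3] <- 0.8 else interactions[2, k] <- 0.8
  }
  n_axes <- nrow(interactions)
  ## latent sources: exactly orthonormal in sample (QR), so finite-sample
  ## cross-covariances between factors vanish identically and programmed
  ## structure cannot masquerade along other patterns
  kb <- as.integer(background_rank)
  ## include the constant vector in the QR so all factors are exactly
  ## sample-mean-zero (correlation centring then cannot break orthogonality)
  q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_time * (k + kb)),
                               n_time))))[, -1, drop = FALSE] * sqrt(n_time)
  S <- q[, seq_len(k), drop = FALSE] %*% diag(latent_sd, k)
  parcel_ts <- S %*% t(L) +
    matrix(stats::rnorm(n_time * n_parcels, sd = noise_sd), n_time, n_parcels)
  if (kb > 0L) {
    lbg <- .rng_smooth_fields(centroids, kb, bandwidth = 0.3)
    lbg <- sweep(lbg, 2L, sqrt(colSums(lbg^2)), "/") * sqrt(n_parcels)
    parcel_ts <- parcel_ts +
      (q[, k + seq_len(kb), drop = FALSE] * background_sd) %*% t(lbg)
  }
  ## voxel axes: independent uniforms, then exactly decorrelated
  ## (Gram-Schmidt on centred columns) so programmed interactions do not
  ## leak across axes through finite-sample axis correlation
  voxel_axes <- matrix(stats::runif(n_mtl_voxels * n_axes),
                       n_mtl_voxels, n_axes)
  if (n_axes > 1L) {
    ctr <- scale(voxel_axes, scale = FALSE)
    qa <- qr.Q(qr(ctr))
    qa <- sweep(qa, 2L, apply(qa, 2L, stats::sd), "/")
    voxel_axes <- sweep(qa * rep(apply(ctr, 2L, stats::sd), each = nrow(qa)),
                        2L, colMeans(voxel_axes), "+")
  }
  W <- matrix(base_coupling, n_mtl_voxels, k) +
    (voxel_axes - 0.5) %*% interactions
  ## variance-equalised voxels: per-voxel noise tops the signal variance up
  ## to a common total, so voxel-parcel correlation is exactly linear in W
  ## and programmed interactions cannot leak across axes through the
  ## correlation normalisation
  sig_var <- drop(W^2 %*% latent_sd^2)
  tot_var <- max(sig_var) + noise_sd^2
  vox_noise <- sqrt(tot_var - sig_var)
  ## voxel noise sample-orthogonalised against all latent factors, removing
  ## the finite-sample noise-factor covariance that would otherwise imprint
  ## the latent patterns onto null connectivity maps
  eps <- matrix(stats::rnorm(n_time * n_mtl_voxels), n_time, n_mtl_voxels)
  eps <- scale(eps, scale = FALSE)               # exact zero sample mean
  eps <- eps - q %*% crossprod(q, eps) / n_time
  eps <- sweep(eps, 2L, sqrt(colMeans(eps^2)), "/")  # exact unit sample SD
  ## per-voxel offsets and fluctuation amplitudes vary independently so
  ## spatial and temporal SNR are non-degenerate, non-collinear voxel
  ## fields; correlations are invariant to the amplitude factor
  offsets <- offset * stats::runif(n_mtl_voxels, 0.8, 1.2)
  amp <- stats::runif(n_mtl_voxels, 0.85, 1.15)
  mtl_ts <- (S %*% t(W) + eps * rep(vox_noise, each = n_time)) *
    rep(amp, each = n_time) + rep(offsets, each = n_time)
  list(parcel_ts = parcel_ts, mtl_ts = mtl_ts, centroids = centroids,
       loadings = L, voxel_axes = voxel_axes, interactions = interactions,
       latent_sd = latent_sd)
}

## smooth fields drawn from the current RNG state (no seed reset)
.rng_smooth_fields <- function(centroids, n_maps, bandwidth = 0.3,
                               noise = 0.1) {
  n <- nrow(centroids)
  d2 <- pmax(2 - 2 * tcrossprod(centroids), 0)
  k <- exp(-d2 / (2 * bandwidth^2))
  k %*% matrix(stats::rnorm(n * n_maps), n, n_maps) +
    noise * matrix(stats::rnorm(n * n_maps), n, n_maps)
}

#' Spatially autocorrelated random fields on the sphere
#'
#' Kernel-smoothed white noise at the given centroids: generic smooth maps
#' with a small white-noise floor, used to calibrate spin-permutation
#' inference (independent draws are null pairs with realistic spatial
#' autocorrelation).
#'
#' @param centroids `n x 3` unit vectors
#' @param n_maps number of independent fields
#' @param bandwidth Gaussian kernel bandwidth on chordal distance
#'   (default 0.3, about 17 degrees)
#' @param noise white-noise floor relative to the smooth component
#' @param seed integer seed
#' @return `n x n_maps` matrix
#' @export
smooth_sphere_field <- function(centroids, n_maps = 1L, bandwidth = 0.3,
                                noise = 0.1, seed = 1L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  d2 <- pmax(2 - 2 * tcrossprod(centroids), 0)
  k <- exp(-d2 / (2 * bandwidth^2))
  set.seed(as.integer(seed))
  k %*% matrix(stats::rnorm(n * n_maps), n, n_maps) +
    noise * matrix(stats::rnorm(n * n_maps), n, n_maps)
}
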