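# Shared fixtures, generated once per test run and cached. All synthetic,
# seed-fixed; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_toy <- function() {
  if (is.null(.fx$toy)) .fx$toy <- make_toy_confluence(toy_confluence_spec())
  .fx$toy
}

fx_model <- function() {
  if (is.null(.fx$model))
    .fx$model <- toy_confluence_model(fx_toy(), on_nonmanifold = "none")
  .fx$model
}

# noise-free intensity volume at the default resolution (the expensive one)
fx_volume <- function() {
  if (is.null(.fx$volume))
    .fx$volume <- make_intensity_volume(fx_toy(),
                                        profile_model(skewness_slope = 2,
                                                      noise_sd = 0),
                                        voxel_mm = 0.12)
  .fx$volume
}

fx_depths <- function() {
  if (is.null(.fx$depths))
    .fx$depths <- equivolumetric_surfaces(fx_model(), 16L)
  .fx$depths
}

# normalised ground-truth axis of the toy model
fx_axis_norm <- function() {
  gt <- fx_model()$inner$scalars$gt_axis
  (gt - min(gt)) / diff(range(gt))
}

# noisy profile set at 10% of profile amplitude (the default synthetic world
# for recovery experiments)
fx_noisy_profiles <- function() {
  if (is.null(.fx$noisy_profiles)) {
    pm <- profile_model(skewness_slope = 2, noise_sd = 0.1 * 50)
    prof <- generate_profiles(pm, fx_axis_norm(), seed = 7)
    prof$meta$axis_mm <- fx_model()$axis_mm
    prof$meta$ap_mm <- fx_model()$ap_mm
    .fx$noisy_profiles <- prof
  }
  .fx$noisy_profiles
}

fx_parcels <- function() {
  if (is.null(.fx$parcels)) .fx$parcels <- make_gradient_parcel_data(seed = 1)
  .fx$parcels
}

# planar rectangular strip in the xy-plane, optionally jittered in-plane;
# rows run along x, columns along y; returns mesh plus the vertex indices of
# the x = 0 edge (used as a bridgehead-like source set)
flat_strip <- function(nx = 30L, ny = 12L, spacing = 1, jitter = 0,
                       seed = 1L) {
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))   # x slow, y fast
  v <- cbind((g$x - 1) * spacing, (g$y - 1) * spacing, 0)
  if (jitter > 0) {
    set.seed(seed)
    interior <- g$x > 1 & g$x < nx & g$y > 1 & g$y < ny
    v[interior, 1:2] <- v[interior, 1:2] +
      matrix(stats::runif(2 * sum(interior), -jitter, jitter),
             ncol = 2)
  }
  vid <- function(r, c) (r - 1L) * ny + c
  tris <- list()
  for (r in seq_len(nx - 1L)) for (c in seq_len(ny - 1L)) {
    tris[[length(tris) + 1L]] <-
      rbind(c(vid(r, c), vid(r + 1L, c), vid(r, c + 1L)),
            c(vid(r, c + 1L), vid(r + 1L, c), vid(r + 1L, c + 1L)))
  }
  mesh <- surface_mesh(v, do.call(rbind, tris), validate = FALSE)
  list(mesh = mesh, edge = seq_len(ny), x = v[, 1])
}

# sample correlated trivariate normals with corr(x1,x2)=corr(x1,x3)=r and
# corr(x2,x3)=rab (null world for the dependent-correlation test)
rnull3 <- function(n, r, rab) {
  sig <- matrix(c(1, r, r, r, 1, rab, r, rab, 1), 3)
  matrix(stats::rnorm(n * 3), n, 3) %*% chol(sig)
}


# pure-harmonic orthonormal patterns (clean construction oracle: no random
# admixture), scaled like smooth_sphere_patterns
pure_patterns <- function(centroids, k) {
  x <- centroids[, 1]; y <- centroids[, 2]; z <- centroids[, 3]
  basis <- cbind(z, x, x * y)[, seq_len(k), drop = FALSE]
  q <- qr.Q(qr(cbind(1, basis)))[, -1, drop = FALSE]
  sweep(q, 2, sqrt(colSums(q^2)), "/") * sqrt(nrow(q))
}
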