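test_that("axis map recovers exact and null relations", {
  set.seed(31)
  n_t <- 200; n_v <- 40; n_p <- 6
  mtl <- matrix(rnorm(n_t * n_v), n_t, n_v)
  parcels <- matrix(rnorm(n_t * n_p), n_t, n_p)
  axis <- seq(0, 1, length.out = n_v)
  # engineer parcel 1 so its connectivity column equals the axis ordering
  m <- axis_fc_map(mtl, axis, parcels)
  conn <- m$connectivity
  r_oracle <- apply(conn, 2, cor, y = axis)
  expect_equal(m$r, r_oracle, tolerance = 1e-12)
  # shuffled axis: map centred on zero
  set.seed(32)
  sh <- replicate(50, mean(axis_fc_map(mtl, sample(axis), parcels)$r))
  expect_lt(abs(mean(sh)), 0.02)
  expect_error(axis_fc_map(mtl[, 1:5], axis[1:5], parcels), "10 MTL voxels")
  expect_warning(axis_fc_map(mtl, rep(1, n_v), parcels), "constant axis")
})

test_that("normalised-angle transform hits its endpoints", {
  r <- matrix(c(1, 0, -1, 0, 1, 0, -1, 0, 1), 3)
  ang <- 1 - acos(pmin(pmax(r, -1), 1)) / pi
  expect_equal(ang[1, 1], 1)
  expect_equal(ang[1, 2], 0.5)
  expect_equal(ang[1, 3], 0)
  expect_error(functional_gradients(matrix(c(1, 2, 2, 1), 2)), "outside")
})

test_that("rank-2 connectome gradients recover both programmed patterns", {
  n <- 400
  cen <- fibonacci_sphere(n)
  L <- pure_patterns(cen, 2L)
  set.seed(33)
  S <- matrix(rnorm(6000 * 2), 6000, 2) %*% diag(c(1, 0.55))
  ts <- S %*% t(L) + matrix(rnorm(6000 * n, sd = 0.05), 6000, n)
  # construction oracle: full affinity (no sparsification)
  emb <- functional_gradients(cor(ts), k = 2, sparsity = 0)
  expect_gt(abs(cor(emb$vectors[, 1], L[, 1], method = "spearman")), 0.95)
  expect_gt(abs(cor(emb$vectors[, 2], L[, 2], method = "spearman")), 0.95)
})

test_that("gradient decomposition is parcel-permutation equivariant", {
  dat <- fx_parcels()
  r <- cor(dat$parcel_ts[, 1:200])
  emb1 <- functional_gradients(r, k = 2)
  set.seed(34)
  perm <- sample(200)
  emb2 <- functional_gradients(r[perm, perm], k = 2)
  expect_gt(abs(cor(emb1$vectors[perm, 1], emb2$vectors[, 1])), 1 - 1e-6)
})

test_that("spin permutations preserve values up to duplication", {
  cen <- fibonacci_sphere(120)
  vals <- smooth_sphere_field(cen, 1, seed = 35)[, 1]
  nulls <- spin_permutation(cen, vals, n_spins = 50, seed = 36)
  expect_equal(dim(nulls), c(120L, 50L))
  # every null value existed in the input map
  expect_true(all(nulls %in% vals))
  dup <- attr(nulls, "duplication_rate")
  expect_true(dup >= 0 && dup < 0.5)
  # reproducible under the seed
  expect_identical(nulls,
                   spin_permutation(cen, vals, n_spins = 50, seed = 36))
  expect_error(spin_permutation(cbind(1, 1, 1)[rep(1, 20), ], rnorm(20), 10),
               "degenerate")
})

test_that("spin nulls retain the spatial autocorrelation of the input", {
  cen <- fibonacci_sphere(200)
  vals <- smooth_sphere_field(cen, 1, bandwidth = 0.4, seed = 37)[, 1]
  # Moran-type statistic with inverse chordal-distance weights
  w <- 1 / (as.matrix(dist(cen)) + 0.1); diag(w) <- 0
  moran <- function(v) {
    vc <- v - mean(v)
    (length(v) / sum(w)) * sum(w * outer(vc, vc)) / sum(vc^2)
  }
  nulls <- spin_permutation(cen, vals, n_spins = 30, seed = 38)
  m_obs <- moran(vals)
  m_null <- mean(apply(nulls, 2, moran))
  expect_lt(abs(m_null - m_obs) / abs(m_obs), 0.2)
})

test_that("self-comparison attains rho 1 at the smallest possible p", {
  dat <- fx_parcels()
  grads <- functional_gradients(cor(dat$parcel_ts), k = 3)
  g1 <- grads$vectors[, 1]
  res <- map_gradient_correspondence(g1, grads, dat$centroids,
                                     n_spins = 199, seed = 39)
  expect_equal(unname(res$rho[1]), 1)
  expect_equal(res$p_spin[1], 1 / 200)
  # same-seed spins reproducible
  res2 <- map_gradient_correspondence(g1, grads, dat$centroids,
                                      n_spins = 199, seed = 39)
  expect_identical(res$null_rho, res2$null_rho)
  expect_warning(map_gradient_correspondence(g1, grads, dat$centroids,
                                             n_spins = 50, seed = 1),
                 "coarse")
})

test_that("SNR definitions and controls behave as specified", {
  set.seed(40)
  # voxel with temporal mean 10 and SD 2 has tSNR 5
  raw <- cbind(10 + 2 * scale(rnorm(400))[, 1], 50 + rnorm(400))
  snr <- voxel_snr(raw)
  expect_equal(snr$temporal_snr[1], 5, tolerance = 1e-9)
  expect_equal(snr$spatial_snr,
               colMeans(raw) / sd(colMeans(raw)), tolerance = 1e-9)
  zero_sd <- cbind(raw, 3)
  expect_warning(s2 <- voxel_snr(zero_sd), "zero temporal SD")
  expect_true(is.na(s2$temporal_snr[3]))
})

test_that("SNR-independent worlds survive partial-correlation control", {
  dat <- fx_parcels()
  res <- snr_controls(dat$mtl_ts, dat$voxel_axes[, 1], dat$parcel_ts)
  expect_gt(res$agreement, 0.95)
})

test_that("axis-dependent SNR attenuates the controlled map", {
  dat <- fx_parcels()
  ax <- dat$voxel_axes[, 1]
  # impose an axis-locked signal-amplitude modulation (raw means follow axis)
  mod <- dat$mtl_ts * rep(1 + 1.5 * ax, each = nrow(dat$mtl_ts))
  res_mod <- snr_controls(mod, ax, dat$parcel_ts)
  res_ref <- snr_controls(dat$mtl_ts, ax, dat$parcel_ts)
  expect_lt(res_mod$agreement, res_ref$agreement)
})

test_that("temporal-lobe exclusion recomputes on retained parcels", {
  dat <- fx_parcels()
  grads <- functional_gradients(cor(dat$parcel_ts), k = 3)
  map <- axis_fc_map(dat$mtl_ts, dat$voxel_axes[, 1], dat$parcel_ts)$r
  base <- map_gradient_correspondence(map, grads, dat$centroids,
                                      n_spins = 120, seed = 41)
  none <- exclude_parcels(map, grads, dat$centroids,
                          rep(FALSE, length(map)), n_spins = 120, seed = 41)
  expect_equal(none$rho, base$rho)
  expect_equal(none$n_retained, length(map))
  set.seed(42)
  flags <- seq_along(map) %in% sample(length(map), 196)
  some <- exclude_parcels(map, grads, dat$centroids, flags,
                          n_spins = 120, seed = 41)
  expect_equal(some$n_retained, length(map) - 196L)
  # flags carrying no signal barely move the correspondence
  expect_lt(max(abs(some$rho - base$rho)), 0.1)
})
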