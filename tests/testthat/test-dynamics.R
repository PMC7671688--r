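# small axis volume used across binning tests
bin_axis_vol <- function(vals = seq(0, 1, length.out = 32)) {
  ax <- array(NA_real_, dim = c(8, 8, 4))
  ax[2:5, 2:5, 2:3] <- vals
  volume(ax)
}

test_that("bin atlas interval arithmetic and guards", {
  vol <- bin_axis_vol()
  atlas <- make_bin_atlas(vol, 8)
  # axis uniform on [0,1]: value 0.13 falls in bin 2 of 8
  v13 <- which.min(abs(vol$data - 0.13))
  expect_equal(atlas$labels$data[v13], 2L)
  expect_equal(atlas$n_bins, 8L)
  expect_true(all(atlas$counts > 0))
  # labelled voxels fall inside their bin interval
  lab <- atlas$labels$data; ax <- vol$data
  for (b in 1:8) {
    vals <- ax[lab == b]
    expect_true(all(vals >= atlas$edges[b] - 1e-12 &
                    vals <= atlas$edges[b + 1] + 1e-12))
  }
  expect_error(make_bin_atlas(vol, 3), "4..14")
  expect_s3_class(make_bin_atlas(vol, 3, force = TRUE), "axis_bin_atlas")
  # empty bin: values clustered at the ends
  gap <- bin_axis_vol(rep(c(0, 1), 16))
  expect_error(make_bin_atlas(gap, 8), "empty bin")
  # composition table from subregion labels
  sub <- volume(array(ifelse(is.na(vol$data), NA, 1L), dim(vol$data)))
  at2 <- make_bin_atlas(vol, 4, subregion_vol = sub)
  expect_equal(unname(rowSums(at2$composition)), rep(1, 4))
})

test_that("deviation labels span 0..6 in the 8-bin model", {
  ed <- ec_edge_table(chain_coupling(8))
  expect_setequal(unique(ed$deviation), 0:6)
  expect_equal(nrow(ed), 56L)
  # symmetric deviation, equal-size direction classes
  key <- paste(pmin(ed$seed, ed$target), pmax(ed$seed, ed$target))
  dev_by_pair <- tapply(ed$deviation, key, function(d) length(unique(d)))
  expect_true(all(dev_by_pair == 1L))
  expect_equal(sum(ed$direction == "to_isocortex"),
               sum(ed$direction == "to_allocortex"))
})

test_that("choose_n_bins returns the finest feasible resolution", {
  gen <- bin_axis_vol()
  expect_equal(as.integer(choose_n_bins(gen, min_voxels = 1)), 14L)
  # mask sized so that > 8 bins starve: 32 voxels, min 4 per bin
  expect_equal(as.integer(choose_n_bins(gen, min_voxels = 4)), 8L)
  expect_error(choose_n_bins(gen, min_voxels = 1000), "no candidate")
  lg <- attr(choose_n_bins(gen, min_voxels = 4), "log")
  expect_true(is.data.frame(lg) && nrow(lg) == 11L)
})

test_that("bin timeseries extraction averages and demeans correctly", {
  vol <- bin_axis_vol()
  atlas <- make_bin_atlas(vol, 4)
  # constant signal -> zero after demeaning
  dm <- dim(vol$data)
  fmri <- volume(array(7, c(dm, 5)), vol$affine)
  ts <- extract_bin_timeseries(fmri, atlas)
  expect_equal(max(abs(ts)), 0)
  # two-voxel bin: series is the voxel mean before demeaning
  ax <- array(NA_real_, dim = c(4, 4, 2))
  ax[1:2, 1, 1] <- c(0.1, 0.2); ax[3, 1, 1] <- 0.9
  at2 <- make_bin_atlas(volume(ax), 2, force = TRUE)
  a <- c(1, 2, 3); b <- c(5, 1, 0)
  f <- array(0, c(4, 4, 2, 3))
  f[1, 1, 1, ] <- a; f[2, 1, 1, ] <- b
  ts2 <- extract_bin_timeseries(volume(f, at2$labels$affine), at2,
                                demean = FALSE)
  expect_equal(unname(ts2[, 1]), (a + b) / 2)
})

test_that("grid mismatch between fmri and atlas is reported", {
  vol <- bin_axis_vol()
  atlas <- make_bin_atlas(vol, 4)
  wrong <- volume(array(0, c(4, 4, 4, 5)), vol$affine)
  expect_error(extract_bin_timeseries(wrong, atlas), "mismatch")
})

test_that("EC inversion recovers known coupling and rejects bad input", {
  a <- chain_coupling(8)
  ts <- simulate_linear_dynamics(linear_dynamics_spec(a, dt = 0.1,
                                                      n_samples = 50000,
                                                      seed = 13))
  ec <- estimate_ec(ts, dt = 0.1)
  off <- function(m) m[row(m) != col(m)]
  expect_gt(cor(off(ec$coupling), off(a)), 0.8)
  # adjacent estimates dominate distant ones
  ed <- ec_edge_table(ec)
  expect_gt(mean(ed$coupling[ed$deviation == 0]),
            mean(ed$coupling[ed$deviation >= 4]))
  expect_error(estimate_ec(ts[1:100, ], dt = 0.1), "too short")
})

test_that("white-noise nodes give near-zero off-diagonal estimates", {
  set.seed(14)
  ts <- matrix(rnorm(20000 * 5), ncol = 5)
  ec <- suppressWarnings(estimate_ec(ts, dt = 1))
  offv <- abs(ec$coupling[row(ec$coupling) != col(ec$coupling)])
  # permutation null: re-estimate on time-shuffled series
  null_max <- replicate(20, {
    tsp <- ts[sample(nrow(ts)), ]
    ecp <- suppressWarnings(estimate_ec(tsp, dt = 1))
    quantile(abs(ecp$coupling[row(ecp$coupling) != col(ecp$coupling)]), 0.975)
  })
  expect_gte(mean(offv <= mean(null_max)), 0.95)
})

test_that("deviation analysis orders and contrasts directions", {
  # coupling linearly decreasing in deviation, both directions
  dev <- abs(outer(1:8, 1:8, "-")) - 1
  a <- 1 - 0.12 * dev
  diag(a) <- -1
  dv <- deviation_analysis(a)
  expect_equal(dv$r_to_iso, -1, tolerance = 1e-6)
  expect_equal(dv$r_to_allo, -1, tolerance = 1e-6)
  expect_lt(abs(dv$z_difference), 1e-6)
  expect_error(deviation_analysis(matrix(1, 4, 4) - diag(4)), "equal")
})

test_that("deviation p-values are roughly uniform under the null", {
  set.seed(15)
  ps <- replicate(300, {
    a <- matrix(rnorm(64), 8); diag(a) <- -1
    deviation_analysis(a)$p_to_iso
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("full deviation analysis on chain dynamics is negative both ways", {
  a <- chain_coupling(8)
  ts <- simulate_linear_dynamics(linear_dynamics_spec(a, dt = 0.1,
                                                      n_samples = 50000,
                                                      seed = 16))
  dv <- deviation_analysis(estimate_ec(ts, dt = 0.1))
  expect_lt(dv$r_to_iso, 0)
  expect_lt(dv$r_to_allo, 0)
})

test_that("EC estimation error shrinks with series length", {
  a <- chain_coupling(6)
  off <- function(m) m[row(m) != col(m)]
  errs <- vapply(c(4000, 16000, 64000), function(n) {
    ts <- simulate_linear_dynamics(linear_dynamics_spec(a, dt = 0.1,
                                                        n_samples = n,
                                                        seed = 17))
    ec <- estimate_ec(ts, dt = 0.1)
    sqrt(mean((off(ec$coupling) - off(a))^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("anterior-posterior thirds partition voxels and replicate EC", {
  set.seed(18)
  ax <- array(NA_real_, dim = c(12, 9, 6))
  mask <- expand.grid(i = 2:11, j = 2:8, k = 2:5)
  ax[as.matrix(mask)] <- runif(nrow(mask))
  ap <- array(NA_real_, dim = dim(ax))
  ap[as.matrix(mask)] <- mask$j + runif(nrow(mask), -0.2, 0.2)
  axv <- volume(ax); apv <- volume(ap)
  atlas <- make_bin_atlas(axv, 4)
  a <- chain_coupling(4, strength = 0.3)
  node_ts <- simulate_linear_dynamics(linear_dynamics_spec(a, dt = 0.1,
                                                           n_samples = 30000,
                                                           seed = 19))
  fmri <- make_bin_fmri(atlas, node_ts, noise_sd = 0.01, seed = 20)
  # 4-bin models have 6 edges per direction: the directional z is
  # unavailable and each third warns accordingly
  res <- suppressWarnings(ap_thirds_analysis(axv, apv, fmri, n_bins = 4,
                                             dt = 0.1))
  expect_warning(deviation_analysis(res$thirds$anterior$ec),
                 "fewer than 10 edges")
  expect_true(is.na(res$thirds$anterior$deviation$z_difference))
  # AP-homogeneous dynamics: per-third EC matches the full model
  for (th in res$thirds) expect_gt(th$cor_with_full, 0.8)
  # partition: every labelled voxel in exactly one third
  apvals <- ap[is.finite(ax)]
  terc <- findInterval(apvals, res$tercile_edges) + 1L
  expect_equal(sort(unique(terc)), 1:3)
  expect_equal(length(apvals), sum(tabulate(terc, 3)))
})

test_that("functional homogeneity contrasts within versus between bins", {
  vol <- bin_axis_vol()
  atlas <- make_bin_atlas(vol, 4)
  set.seed(21)
  # identical series within bins, independent across bins
  node_ts <- matrix(rnorm(200 * 4), 200, 4)
  fmri <- make_bin_fmri(atlas, node_ts, noise_sd = 0)
  fh <- functional_homogeneity(fmri, atlas)
  expect_equal(unname(fh$within), rep(1, 4), tolerance = 1e-6)
  expect_lt(max(abs(fh$between[row(fh$between) != col(fh$between)])), 0.2)
  expect_gt(fh$contrast, 0.8)
  # globally identical series -> zero contrast
  one <- matrix(rep(rnorm(200), 4), 200, 4)
  fh1 <- functional_homogeneity(make_bin_fmri(atlas, one, noise_sd = 0), atlas)
  expect_equal(fh1$contrast, 0, tolerance = 1e-9)
})

test_that("homogeneity contrast falls as bins are mixed", {
  vol <- bin_axis_vol()
  atlas <- make_bin_atlas(vol, 4)
  set.seed(22)
  base <- matrix(rnorm(150 * 4), 150, 4)
  common <- rnorm(150)
  contrasts <- vapply(c(0, 0.5, 1), function(mix) {
    node_ts <- (1 - mix) * base + mix * common
    fh <- functional_homogeneity(make_bin_fmri(atlas, node_ts,
                                               noise_sd = 0.05, seed = 1),
                                 atlas)
    fh$contrast
  }, numeric(1))
  expect_true(all(diff(contrasts) < 0))
})
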