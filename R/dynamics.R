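#' Divide an axis volume into discrete bins
#'
#' Labels every finite-axis voxel with a bin index over equal-width
#' (default) or equal-count intervals of the axis range. Bin 1 is the most
#' isocortical (most negative axis), bin `n_bins` the most allocortical.
#'
#' @param axis_vol a 3D [volume()] with finite axis values on the tissue
#'   mask and `NA` elsewhere
#' @param n_bins number of bins; the canonical range is 4..14 (the 8-bin
#'   model is the default downstream), enforced unless `force = TRUE`
#' @param mode `"equal_width"` (default) or `"equal_count"`
#' @param subregion_vol optional label [volume()] for the composition table
#' @param edges optional explicit bin edges (overrides `mode`; used to hold
#'   bins fixed across anterior-posterior subsets)
#' @param force allow `n_bins` outside 4..14
#' @return object of class `axis_bin_atlas`: `labels` ([volume()] of 0 =
#'   background / 1..n_bins), `n_bins`, `edges`, `composition` (proportion
#'   of each subregion per bin, when labels given)
#' @export
make_bin_atlas <- function(axis_vol, n_bins = 8L, mode = c("equal_width",
                                                           "equal_count"),
                           subregion_vol = NULL, edges = NULL,
                           force = FALSE) {
  mode <- match.arg(mode)
  n_bins <- as.integer(n_bins)
  if (!force && (n_bins < 4L || n_bins > 14L))
    stop("n_bins = ", n_bins, " outside the canonical 4..14 range ",
         "(use force = TRUE to override)")
  ax <- axis_vol$data
  mask <- which(is.finite(ax))
  if (!length(mask)) stop("no finite axis values in the volume")
  v <- ax[mask]
  if (is.null(edges)) {
    edges <- if (mode == "equal_width")
      seq(min(v), max(v), length.out = n_bins + 1L)
    else stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1L),
                         names = FALSE)
  }
  if (length(edges) != n_bins + 1L) stop("edges must have n_bins + 1 values")
  b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(b, n_bins)
  if (any(counts == 0L))
    stop("empty bin(s): ", paste(which(counts == 0L), collapse = ", "),
         "; use fewer bins")
  lab <- array(0L, dim = dim(ax))
  lab[mask] <- b
  composition <- NULL
  if (!is.null(subregion_vol)) {
    sr <- subregion_vol$data[mask]
    composition <- prop.table(table(bin = b, subregion = sr), margin = 1L)
  }
  structure(list(labels = volume(lab, axis_vol$affine), n_bins = n_bins,
                 edges = edges, counts = counts, composition = composition),
            class = "axis_bin_atlas")
}

#' @export
print.axis_bin_atlas <- function(x, ...) {
  cat("axis_bin_atlas:", x$n_bins, "bins, voxel counts",
      paste(x$counts, collapse = "/"), "\n")
  invisible(x)
}

#' Choose the finest feasible number of axis bins
#'
#' Returns the largest candidate bin count such that every bin holds at
#' least `min_voxels` voxels in every provided mask (subject), emulating
#' the selection of the finest resolution still supporting the
#' hierarchical model.
#'
#' @param axis_vol axis [volume()]
#' @param candidates candidate bin counts (default 4..14)
#' @param min_voxels minimum voxels per bin per mask
#' @param masks optional list of logical arrays (subject masks); default:
#'   the axis volume's own finite mask
#' @param mode binning mode, as in [make_bin_atlas()]
#' @return chosen bin count; attribute `"log"` holds the per-candidate
#'   decision table
#' @export
choose_n_bins <- function(axis_vol, candidates = 4:14, min_voxels = 10L,
                          masks = NULL, mode = "equal_width") {
  ax <- axis_vol$data
  if (is.null(masks)) masks <- list(is.finite(ax))
  log_rows <- list()
  ok_n <- integer(0)
  for (nb in sort(candidates)) {
    feasible <- TRUE
    for (m in masks) {
      v <- ax[m & is.finite(ax)]
      if (!length(v)) { feasible <- FALSE; break }
      edges <- if (mode == "equal_width")
        seq(min(v), max(v), length.out = nb + 1L)
      else stats::quantile(v, probs = seq(0, 1, length.out = nb + 1L),
                           names = FALSE)
      b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
      if (min(tabulate(b, nb)) < min_voxels) { feasible <- FALSE; break }
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(n_bins = nb,
                                                    feasible = feasible)
    if (feasible) ok_n <- c(ok_n, nb)
  }
  if (!length(ok_n))
    stop("no candidate bin count keeps >= ", min_voxels,
         " voxels per bin in every mask")
  out <- max(ok_n)
  attr(out, "log") <- do.call(rbind, log_rows)
  out
}

#' Extract mean timeseries per axis bin
#'
#' @param fmri 4D [volume()] (time last)
#' @param atlas an `axis_bin_atlas` on the same grid
#' @param demean subtract each bin's temporal mean (default TRUE)
#' @return `n_time x n_bins` matrix
#' @export
extract_bin_timeseries <- function(fmri, atlas, demean = TRUE) {
  dm_f <- dim(fmri$data); dm_a <- dim(atlas$labels$data)
  if (!all(dm_f[1:3] == dm_a) ||
      max(abs(fmri$affine - atlas$labels$affine)) > 1e-6)
    stop("fmri/atlas grid mismatch: fmri ", paste(dm_f[1:3], collapse = "x"),
         " vs atlas ", paste(dm_a, collapse = "x"),
         " (or affines differ)")
  lab <- as.vector(atlas$labels$data)
  vox <- which(lab > 0L)
  b <- lab[vox]
  Tt <- dm_f[4]
  mat <- matrix(fmri$data, prod(dm_f[1:3]), Tt)[vox, , drop = FALSE]
  out <- t(rowsum(mat, group = b) / as.vector(table(b)))
  colnames(out) <- paste0("bin", seq_len(atlas$n_bins))
  if (demean) out <- sweep(out, 2L, colMeans(out))
  out
}

## Principal matrix logarithm via eigendecomposition (matrices assumed
## diagonalisable; complex pairs handled, result real up to tolerance).
matrix_log <- function(m, tol = 1e-6) {
  e <- eigen(m)
  if (any(Mod(e$values) < 1e-12))
    stop("matrix logarithm undefined: (near-)zero eigenvalue")
  neg_real <- Re(e$values) < 0 & abs(Im(e$values)) < 1e-9 * Mod(e$values)
  if (any(neg_real))
    stop("matrix logarithm: real negative eigenvalue(s) ",
         "(principal branch undefined); the fitted transition matrix is ",
         "not consistent with a real continuous-time generator")
  lg <- e$vectors %*% diag(log(e$values), nrow(m)) %*% solve(e$vectors)
  if (max(abs(Im(lg))) > tol * max(1, max(abs(Re(lg)))))
    warning("matrix logarithm has imaginary residue ",
            format(max(abs(Im(lg)))), "; taking real part")
  Re(lg)
}

#' Estimate directed (effective) connectivity from bin timeseries
#'
#' Inverts a stable linear stochastic (Ornstein-Uhlenbeck) model: a
#' discrete first-order transition matrix is estimated by least squares
#' (optional ridge) on lagged samples and mapped to a continuous-time
#' coupling via the principal matrix logarithm divided by `dt`. Columns are
#' seeds and rows are targets: entry (i, j) is the influence of bin j on
#' bin i.
#'
#' @param ts `n_time x n_bins` timeseries matrix
#' @param dt sampling interval (s)
#' @param ridge ridge penalty added to the Gram matrix (fraction of its
#'   mean diagonal; default 0)
#' @param method `"logm"` (default: principal matrix logarithm / dt) or
#'   `"linear"` (first-order Euler inversion `(A_d - I) / dt`). When the
#'   principal logarithm is undefined (real negative eigenvalues of the
#'   transition matrix, e.g. for temporally unstructured data), `"logm"`
#'   falls back to the linear inversion with a warning.
#' @return object of class `directed_connectivity`: `coupling`
#'   (bins x bins), `dt`, `discrete` (fitted transition matrix), `method`
#' @export
estimate_ec <- function(ts, dt, ridge = 0, method = c("logm", "linear")) {
  method <- match.arg(method)
  ts <- as.matrix(ts)
  n <- ncol(ts); Tt <- nrow(ts)
  if (Tt < 10 * n^2)
    stop("n_time = ", Tt, " too short for ", n,
         " bins (need >= 10 * n_bins^2 = ", 10 * n^2, ")")
  x0 <- ts[-Tt, , drop = FALSE]
  x1 <- ts[-1L, , drop = FALSE]
  g <- crossprod(x0)
  if (ridge > 0) g <- g + diag(ridge * mean(diag(g)), n)
  a_d <- t(solve(g, crossprod(x0, x1)))
  if (any(!is.finite(a_d))) stop("non-finite transition estimate")
  ev <- eigen(a_d, only.values = TRUE)$values
  if (max(Mod(ev)) >= 1)
    stop("unstable estimate: spectral radius ", format(max(Mod(ev))),
         " >= 1 (eigenvalues: ",
         paste(format(ev, digits = 3), collapse = ", "), ")")
  if (method == "logm") {
    coupling <- tryCatch(matrix_log(a_d) / dt, error = function(e) {
      warning("principal matrix logarithm undefined (",
              conditionMessage(e), "); falling back to linear inversion")
      NULL
    })
    if (is.null(coupling)) {
      coupling <- (a_d - diag(n)) / dt
      method <- "linear_fallback"
    }
  } else {
    coupling <- (a_d - diag(n)) / dt
  }
  dimnames(coupling) <- list(target = paste0("bin", seq_len(n)),
                             seed = paste0("bin", seq_len(n)))
  structure(list(coupling = coupling, dt = dt, discrete = a_d,
                 method = method),
            class = "directed_connectivity")
}

#' @export
print.directed_connectivity <- function(x, ...) {
  cat("directed_connectivity:", ncol(x$coupling),
      "bins (columns = seeds, rows = targets)\n")
  invisible(x)
}

#' Edge table of a directed connectivity matrix
#'
#' Off-diagonal edges labelled by deviation from the iso-to-allocortical
#' axis (`|i - j| - 1`, so an adjacent step has deviation 0) and direction
#' (`to_isocortex` when the target bin index is below the seed,
#' `to_allocortex` otherwise).
#'
#' @param ec a `directed_connectivity` or a square coupling matrix
#' @return data frame: `seed`, `target`, `coupling`, `deviation`,
#'   `direction`
#' @export
ec_edge_table <- function(ec) {
  a <- if (inherits(ec, "directed_connectivity")) ec$coupling else as.matrix(ec)
  n <- ncol(a)
  seed <- rep(seq_len(n), each = n)
  target <- rep(seq_len(n), times = n)
  keep <- seed != target
  data.frame(seed = seed[keep], target = target[keep],
             coupling = as.vector(t(a))[keep],
             deviation = abs(seed - target)[keep] - 1L,
             direction = ifelse(target[keep] < seed[keep],
                                "to_isocortex", "to_allocortex"))
}

#' Relate coupling strength to deviation from the axis
#'
#' Product-moment correlation between edge deviation and coupling, per
#' direction, with the directional contrast tested via the
#' dependent-correlation z-test (edges paired across directions by
#' (seed, target) transposition share their deviation labels).
#'
#' @param ec a `directed_connectivity` or coupling matrix
#' @param use `"signed"` (default: raw coupling values) or `"magnitude"`
#' @return list: `r_to_iso`, `r_to_allo`, `p_to_iso`, `p_to_allo`,
#'   `z_difference`, `p_difference`, `edges` (full edge table)
#' @export
deviation_analysis <- function(ec, use = c("signed", "magnitude")) {
  use <- match.arg(use)
  ed <- ec_edge_table(ec)
  if (use == "magnitude") ed$coupling <- abs(ed$coupling)
  if (stats::sd(ed$coupling) == 0)
    stop("all couplings equal: deviation correlation undefined")
  iso <- ed[ed$direction == "to_isocortex", ]
  allo <- ed[ed$direction == "to_allocortex", ]
  ct_iso <- stats::cor.test(iso$deviation, iso$coupling)
  ct_allo <- stats::cor.test(allo$deviation, allo$coupling)
  ## pair edges (i -> j) with (j -> i): same deviation, opposite direction
  key_iso <- paste(pmin(iso$seed, iso$target), pmax(iso$seed, iso$target))
  key_allo <- paste(pmin(allo$seed, allo$target), pmax(allo$seed, allo$target))
  mallo <- allo$coupling[match(key_iso, key_allo)]
  r_ab <- stats::cor(iso$coupling, mallo)
  cmp <- if (nrow(iso) >= 10) {
    compare_dependent_correlations(
      min(max(ct_iso$estimate, -1 + 1e-12), 1 - 1e-12),
      min(max(ct_allo$estimate, -1 + 1e-12), 1 - 1e-12),
      r_ab, n = nrow(iso))
  } else {
    warning("fewer than 10 edges per direction: directional z not computed")
    list(z = NA_real_, p = NA_real_)
  }
  list(r_to_iso = unname(ct_iso$estimate), r_to_allo = unname(ct_allo$estimate),
       p_to_iso = ct_iso$p.value, p_to_allo = ct_allo$p.value,
       z_difference = cmp$z, p_difference = cmp$p, edges = ed)
}

#' Repeat the dynamic model within anterior-posterior thirds
#'
#' Splits the labelled voxels into thirds by voxel-count terciles of the
#' anterior-posterior coordinate, re-estimates directed connectivity per
#' third (bin edges held fixed at the full-model edges so bins are
#' comparable), and correlates each third's off-diagonal coupling with the
#' full model's.
#'
#' @param axis_vol axis [volume()]
#' @param ap_vol anterior-posterior coordinate [volume()] (same grid)
#' @param fmri 4D [volume()]
#' @param n_bins bins for all models
#' @param dt sampling interval (s)
#' @param ridge ridge passed to [estimate_ec()]
#' @return list with `full` (directed_connectivity), `thirds` (list of
#'   per-third lists: `ec`, `cor_with_full`, `deviation`), `tercile_edges`
#' @export
ap_thirds_analysis <- function(axis_vol, ap_vol, fmri, n_bins = 8L, dt = 1,
                               ridge = 0) {
  stopifnot(all(dim(axis_vol$data) == dim(ap_vol$data)))
  atlas_full <- make_bin_atlas(axis_vol, n_bins)
  ts_full <- extract_bin_timeseries(fmri, atlas_full)
  ec_full <- estimate_ec(ts_full, dt, ridge)
  off <- function(m) m[row(m) != col(m)]

  mask <- is.finite(axis_vol$data)
  apv <- ap_vol$data[mask]
  cuts <- stats::quantile(apv, c(1 / 3, 2 / 3))
  tercile <- findInterval(apv, cuts) + 1L   # 1, 2, 3
  thirds <- lapply(1:3, function(k) {
    sel <- which(mask)[tercile == k]
    if (!length(sel)) stop("empty anterior-posterior third ", k)
    ax3 <- array(NA_real_, dim = dim(axis_vol$data))
    ax3[sel] <- axis_vol$data[sel]
    atlas3 <- make_bin_atlas(volume(ax3, axis_vol$affine), n_bins,
                             edges = atlas_full$edges)
    ts3 <- extract_bin_timeseries(fmri, atlas3)
    ec3 <- estimate_ec(ts3, dt, ridge)
    list(ec = ec3,
         cor_with_full = stats::cor(off(ec3$coupling), off(ec_full$coupling)),
         deviation = deviation_analysis(ec3))
  })
  names(thirds) <- c("anterior", "middle", "posterior")
  structure(list(full = ec_full, thirds = thirds, tercile_edges = cuts),
            class = "ap_thirds_analysis")
}

#' Functional homogeneity of voxel timeseries within axis bins
#'
#' Mean pairwise voxel-voxel correlation within each bin versus between
#' bins, and their contrast. Bins with fewer than 2 voxels are excluded
#' with a warning.
#'
#' @param fmri 4D [volume()]
#' @param atlas an `axis_bin_atlas` on the same grid
#' @return list: `within` (per-bin mean correlation), `between` (bin x bin
#'   mean correlation matrix, diagonal = within), `contrast`
#'   (mean within - mean between)
#' @export
functional_homogeneity <- function(fmri, atlas) {
  dm <- dim(fmri$data)
  lab <- as.vector(atlas$labels$data)
  vox <- which(lab > 0L)
  b <- lab[vox]
  counts <- tabulate(b, atlas$n_bins)
  ok_bins <- which(counts >= 2L)
  if (length(ok_bins) < atlas$n_bins)
    warning("bins with < 2 voxels excluded: ",
            paste(setdiff(seq_len(atlas$n_bins), ok_bins), collapse = ", "))
  keep <- b %in% ok_bins
  vox <- vox[keep]; b <- b[keep]
  mat <- matrix(fmri$data, prod(dm[1:3]), dm[4])[vox, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(mat)))
  cc[!is.finite(cc)] <- 0
  nb <- atlas$n_bins
  between <- matrix(NA_real_, nb, nb)
  for (i in ok_bins) for (j in ok_bins) {
    block <- cc[b == i, b == j, drop = FALSE]
    if (i == j) {
      between[i, j] <- mean(block[lower.tri(block)])
    } else between[i, j] <- mean(block)
  }
  within <- diag(between)
  off <- between[row(between) != col(between)]
  list(within = within, between = between,
       contrast = mean(within, na.rm = TRUE) - mean(off, na.rm = TRUE))
}
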