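#' Microstructure profile covariance (MPC) matrix
#'
#' Vertex-pair similarity of depth profiles: the pairwise partial
#' correlation of profiles controlling for the dataset-average profile,
#' Fisher r-to-z transformed, with negative values set to zero. With
#' `method = "covariance"` a plain profile covariance is returned instead
#' (diagnostic alternative).
#'
#' @param profiles a [profile_matrix()] or vertex x depth matrix
#' @param method `"partial"` (default) or `"covariance"`
#' @return symmetric non-negative vertex x vertex matrix (class `matrix`)
#'   with zero diagonal; attributes record the construction.
#' @export
mpc_matrix <- function(profiles, method = c("partial", "covariance")) {
  method <- match.arg(method)
  x <- if (inherits(profiles, "profile_matrix")) profiles$intensities
       else as.matrix(profiles)
  if (nrow(x) < 3L) stop("need at least 3 vertices")
  if (ncol(x) < 4L) stop("need at least 4 depths")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant profile rows (correlation undefined): ",
         paste(utils::head(which(sds == 0), 10L), collapse = ", "))
  if (method == "covariance") {
    m <- stats::cov(t(x))
    diag(m) <- 0
    attr(m, "mpc_method") <- "covariance"
    return(m)
  }
  mp <- colMeans(x)
  r <- stats::cor(t(x))
  rm_ <- as.vector(stats::cor(t(x), mp))
  denom <- sqrt(pmax(1 - rm_^2, 1e-12))
  pr <- (r - outer(rm_, rm_)) / outer(denom, denom)
  pr <- pmin(pmax(pr, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(pr)
  z[z < 0] <- 0
  z <- (z + t(z)) / 2
  diag(z) <- 0
  attr(z, "mpc_method") <- "partial correlation vs mean profile, r-to-z, negatives zeroed"
  z
}

#' Diffusion map embedding of an affinity matrix
#'
#' Row-sparsifies the affinity (keeping the strongest `1 - sparsity`
#' fraction of entries per row, then re-symmetrising by averaging), applies
#' anisotropic diffusion normalisation with parameter `alpha`, and
#' eigendecomposes the diffusion operator. The trivial constant eigenvector
#' is dropped; variance explained is the eigenvalue fraction over the
#' retained non-trivial spectrum.
#'
#' @param affinity symmetric non-negative matrix
#' @param n_components number of eigenvectors to return
#' @param alpha anisotropic normalisation exponent (0.5 default)
#' @param sparsity per-row sparsity level in `[0, 1)` (0.9 default: keep the
#'   top 10% of each row)
#' @param align_to optional numeric vector: flip eigenvector signs so each
#'   correlates non-negatively with it (flags recorded)
#' @return object of class `embedding`: `vectors` (n x k), `values`,
#'   `variance_explained`, `sign_flipped`
#' @export
diffusion_embedding <- function(affinity, n_components = 10L, alpha = 0.5,
                                sparsity = 0.9, align_to = NULL) {
  w <- as.matrix(affinity)
  n <- nrow(w)
  if (n != ncol(w)) stop("affinity must be square")
  if (max(abs(w - t(w))) > 1e-8) stop("affinity must be symmetric")
  if (min(w) < 0) stop("affinity must be non-negative")
  if (sparsity > 0) {
    keep <- max(1L, ceiling((1 - sparsity) * (n - 1L)))
    ws <- w
    for (i in seq_len(n)) {
      row <- w[i, ]
      row[i] <- 0
      thr <- sort(row, decreasing = TRUE)[keep]
      row[row < thr] <- 0
      ws[i, ] <- row
    }
    w <- (ws + t(ws)) / 2
  } else diag(w) <- 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected"))
  if (comp$no > 1L)
    stop("affinity graph disconnected after sparsification (",
         comp$no, " components); lower sparsity")
  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  s <- w1 / outer(sqrt(d1), sqrt(d1))      # symmetric conjugate of operator
  es <- eigen(s, symmetric = TRUE)
  k <- min(n_components + 1L, n)
  vals <- es$values[seq_len(k)]
  vecs <- es$vectors[, seq_len(k), drop = FALSE] / sqrt(d1)
  ## drop trivial constant eigenvector (eigenvalue 1)
  vals <- vals[-1L]; vecs <- vecs[, -1L, drop = FALSE]
  vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), "/")
  pos <- pmax(vals, 0)
  ve <- pos / sum(pmax(es$values[-1L], 0))
  flipped <- logical(ncol(vecs))
  if (!is.null(align_to)) {
    for (j in seq_len(ncol(vecs))) {
      if (stats::cor(vecs[, j], align_to) < 0) {
        vecs[, j] <- -vecs[, j]; flipped[j] <- TRUE
      }
    }
  }
  structure(list(vectors = vecs, values = vals, variance_explained = ve,
                 sign_flipped = flipped),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", nrow(x$vectors), "observations x", ncol(x$vectors),
      "components; variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 3L)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Polynomial model selection by the adjusted-R-squared elbow
#'
#' Fits least-squares polynomials of degree 1..`max_degree` of `y` on `x`
#' and selects the degree at the elbow of the adjusted-R-squared sequence:
#' the degree whose gain over the previous degree most exceeds the gain of
#' the next degree (discrete second difference of the sequence, boundary
#' gains zero-padded), ties resolved to the lowest degree. A flat sequence
#' therefore selects degree 1.
#'
#' @param x,y numeric vectors
#' @param max_degree highest degree tried (default 5)
#' @return list: `degree` (selected), `adj_r2` (per degree), `residuals`
#'   (selected fit), `fits` (lm objects)
#' @export
select_polynomial <- function(x, y, max_degree = 5L) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in x or y")
  n <- length(x)
  if (n < max_degree + 2L)
    stop("need at least max_degree + 2 = ", max_degree + 2L, " points, got ", n)
  fits <- lapply(seq_len(max_degree), function(d)
    stats::lm(y ~ stats::poly(x, d, raw = TRUE)))
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1))
  adj <- vapply(seq_len(max_degree), function(d) adjusted_r2(r2[d], n, d),
                numeric(1))
  gain <- c(0, diff(adj), 0)               # gain[d] = adj[d] - adj[d-1]
  score <- gain[seq_len(max_degree)] - gain[seq_len(max_degree) + 1L]
  ## tolerance so numerically flat sequences tie to degree 1
  best <- which(score > max(score) - 1e-10)[1L]
  list(degree = best, adj_r2 = adj,
       residuals = stats::residuals(fits[[best]]), fits = fits)
}

#' Per-slice polynomial goodness of fit along the anterior-posterior axis
#'
#' Cuts the model into coronal slices of width `slice_width_mm` along the
#' anterior-posterior coordinate and fits a polynomial of `degree` between
#' each feature and the iso-to-allocortical axis within each slice,
#' reporting the adjusted R-squared per (feature, slice).
#'
#' @param features named list or data frame of per-vertex feature vectors
#' @param axis_mm per-vertex iso-to-allocortical axis
#' @param ap_mm per-vertex anterior-posterior coordinate
#' @param slice_width_mm coronal slice width (default 1 mm)
#' @param degree polynomial degree (default 3, the cubic)
#' @return list: `table` (data frame feature/slice/n/adj_r2), `summary`
#'   (mean and SD of adjusted R-squared per feature)
#' @export
per_slice_fits <- function(features, axis_mm, ap_mm, slice_width_mm = 1,
                           degree = 3L) {
  features <- as.data.frame(features)
  edges <- seq(floor(min(ap_mm)), ceiling(max(ap_mm)) + slice_width_mm,
               by = slice_width_mm)
  slice <- cut(ap_mm, breaks = edges, include.lowest = TRUE, labels = FALSE)
  rows <- list()
  min_n <- degree + 2L
  for (s in sort(unique(slice))) {
    ix <- which(slice == s)
    if (length(ix) < min_n) {
      warning("slice ", s, " skipped: ", length(ix), " < ", min_n, " vertices")
      next
    }
    for (f in names(features)) {
      fit <- stats::lm(features[[f]][ix] ~
                         stats::poly(axis_mm[ix], degree, raw = TRUE))
      r2 <- summary(fit)$r.squared
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, slice = s, n = length(ix),
                   adj_r2 = adjusted_r2(r2, length(ix), degree))
    }
  }
  if (!length(rows)) stop("no slice holds enough vertices")
  tab <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(tab, tab$feature), function(d)
    data.frame(feature = d$feature[1], mean_adj_r2 = mean(d$adj_r2),
               sd_adj_r2 = stats::sd(d$adj_r2), n_slices = nrow(d))))
  rownames(smry) <- NULL
  list(table = tab, summary = smry)
}
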