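#' Specification of a stable multivariate linear stochastic system
#'
#' Ground truth for directed-connectivity estimation: an Ornstein-Uhlenbeck
#' process `dx = A x dt + sigma dW` with known coupling matrix `A`.
#'
#' @param coupling square coupling matrix with negative diagonal; all
#'   eigenvalues must have negative real part (stable system).
#' @param noise_sd innovation SD `sigma` (> 0)
#' @param dt integration step in seconds (> 0)
#' @param n_samples number of samples to simulate
#' @param seed integer seed
#' @return object of class `linear_dynamics_spec`
#' @export
linear_dynamics_spec <- function(coupling, noise_sd = 1, dt = 0.1,
                                 n_samples = 10000L, seed = 1L) {
  coupling <- as.matrix(coupling)
  stopifnot(nrow(coupling) == ncol(coupling), noise_sd > 0, dt > 0,
            n_samples >= 2)
  ev <- eigen(coupling, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("unstable coupling: eigenvalue real parts must all be negative ",
         "(max Re = ", format(max(Re(ev))), ")")
  structure(list(coupling = coupling, noise_sd = noise_sd, dt = dt,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "linear_dynamics_spec")
}

#' Chain coupling matrix decaying with axis deviation
#'
#' Convenience ground truth for the axis-bin analyses: off-diagonal coupling
#' `a_ij = strength * decay^(|i-j|-1)`, negative `diag_value` on the
#' diagonal, so coupling strength decreases monotonically with deviation
#' from the axis in both directions.
#'
#' @param n_nodes number of nodes (axis bins)
#' @param strength adjacent-edge coupling
#' @param decay multiplicative decay per unit deviation, in (0, 1)
#' @param diag_value self-coupling (negative)
#' @return n x n coupling matrix
#' @export
chain_coupling <- function(n_nodes = 8L, strength = 0.2, decay = 0.5,
                           diag_value = -1) {
  stopifnot(n_nodes >= 2, decay > 0, decay < 1, diag_value < 0)
  dev <- abs(outer(seq_len(n_nodes), seq_len(n_nodes), "-"))
  a <- strength * decay^(dev - 1)
  diag(a) <- diag_value
  a
}

#' Simulate the linear stochastic system (Euler-Maruyama)
#'
#' @param spec a [linear_dynamics_spec()]
#' @return `n_samples x n_nodes` matrix of node timeseries
#' @export
simulate_linear_dynamics <- function(spec) {
  stopifnot(inherits(spec, "linear_dynamics_spec"))
  A <- spec$coupling; n <- nrow(A); Tt <- spec$n_samples
  set.seed(spec$seed)
  eps <- matrix(stats::rnorm(Tt * n, sd = spec$noise_sd * sqrt(spec$dt)),
                Tt, n)
  Ad <- diag(n) + A * spec$dt
  x <- matrix(0, Tt, n)
  x[1, ] <- eps[1, ]
  for (t in 2:Tt) x[t, ] <- Ad %*% x[t - 1, ] + eps[t, ]
  x
}

#' Simulate a discrete first-order multivariate autoregression
#'
#' Cross-check generator: `x_t = A_d x_{t-1} + e_t` with spectral radius of
#' `A_d` below 1.
#'
#' @param A_d discrete transition matrix
#' @param noise_sd innovation SD
#' @param n_samples samples
#' @param seed integer seed
#' @return `n_samples x n_nodes` matrix
#' @export
simulate_mar <- function(A_d, noise_sd = 1, n_samples = 10000L, seed = 1L) {
  A_d <- as.matrix(A_d)
  ev <- abs(eigen(A_d, only.values = TRUE)$values)
  if (max(ev) >= 1) stop("unstable transition matrix (spectral radius ",
                         format(max(ev)), " >= 1)")
  n <- nrow(A_d)
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(n_samples * n, sd = noise_sd), n_samples, n)
  x <- matrix(0, n_samples, n)
  x[1, ] <- eps[1, ]
  for (t in 2:n_samples) x[t, ] <- A_d %*% x[t - 1, ] + eps[t, ]
  x
}

#' Stationary covariance of the OU process (Lyapunov solution)
#'
#' Solves `A S + S A' + sigma^2 I = 0` by vectorisation; the independent
#' oracle for simulated stationary covariances.
#'
#' @param coupling stable coupling matrix `A`
#' @param noise_sd innovation SD `sigma`
#' @return stationary covariance matrix
#' @export
lyapunov_covariance <- function(coupling, noise_sd = 1) {
  A <- as.matrix(coupling); n <- nrow(A)
  M <- kronecker(diag(n), A) + kronecker(A, diag(n))
  S <- solve(M, -as.vector(noise_sd^2 * diag(n)))
  matrix(S, n, n)
}

#' Paint node timeseries into an axis-bin atlas as a 4D volume
#'
#' Every voxel of bin `b` receives node series `b` plus optional i.i.d.
#' noise and a constant offset (so SNR analyses have a raw mean signal).
#'
#' @param atlas an `axis_bin_atlas` (see [make_bin_atlas()])
#' @param node_series `n_time x n_bins` matrix
#' @param noise_sd per-voxel additive noise SD
#' @param offset constant added to all tissue voxels
#' @param seed integer seed
#' @return 4D [volume()] with time as the fourth dimension
#' @export
make_bin_fmri <- function(atlas, node_series, noise_sd = 0, offset = 0,
                          seed = 1L) {
  lab <- atlas$labels$data
  n_bins <- atlas$n_bins
  stopifnot(ncol(node_series) == n_bins)
  Tt <- nrow(node_series)
  dm <- dim(lab)
  out <- array(0, dim = c(dm, Tt))
  set.seed(as.integer(seed))
  vox <- which(lab > 0)
  b <- lab[vox]
  for (t in seq_len(Tt)) {
    frame <- array(0, dim = dm)
    frame[vox] <- node_series[t, b] + offset
    if (noise_sd > 0)
      frame[vox] <- frame[vox] + stats::rnorm(length(vox), sd = noise_sd)
    out[, , , t] <- frame
  }
  volume(out, atlas$labels$affine)
}
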