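#' Build the z-standardised cytoarchitectural feature table
#'
#' Assembles the 16 depth-wise intensities (named by their nominal depth
#' percentage) and the four central moments into a vertex x 20 feature
#' matrix, z-standardised per column on the full table (the standardisation
#' order used throughout the supervised analyses; parameters are stored for
#' the inverse transform).
#'
#' @param profiles a [profile_matrix()]
#' @param target per-vertex regression target (iso-to-allocortical axis,
#'   mm); defaults to `profiles$meta$axis_mm` if present
#' @return object of class `feature_table`: `x` (standardised matrix),
#'   `target`, `center`, `scale`, `feature_names`
#' @export
build_feature_table <- function(profiles, target = NULL) {
  stopifnot(inherits(profiles, "profile_matrix"))
  ints <- profiles$intensities
  nd <- ncol(ints)
  pct <- round(100 * profiles$depth_fractions)
  colnames(ints) <- sprintf("intensity_%02dpct", pct)
  mom <- central_moments(profiles)
  x <- cbind(ints, mean = mom$mean, sd = mom$sd,
             skewness = mom$skewness, kurtosis = mom$kurtosis)
  if (is.null(target)) target <- profiles$meta$axis_mm
  if (is.null(target)) stop("no target: supply `target` or meta$axis_mm")
  if (length(target) != nrow(x)) stop("target length mismatch")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (any(scl == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  structure(list(x = xs, target = as.numeric(target), center = ctr,
                 scale = scl, feature_names = colnames(x)),
            class = "feature_table")
}

#' Invert the feature standardisation
#' @param table a `feature_table`
#' @return the unstandardised feature matrix
#' @export
unstandardise_features <- function(table) {
  sweep(sweep(table$x, 2L, table$scale, "*"), 2L, table$center, "+")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$x), "vertices x", ncol(x$x), "features\n")
  invisible(x)
}

#' Default random-forest hyperparameter grid
#'
#' Fixed, logged grid used by [train_axis_regressor()] when none is given
#' (tree count 100; mtry around p/3, sqrt(p) and p/2; two leaf sizes).
#'
#' @param p number of features
#' @return data frame of hyperparameter combinations
#' @export
default_rf_grid <- function(p) {
  expand.grid(mtry = unique(pmax(1L, c(ceiling(p / 3), ceiling(sqrt(p)), p %/% 2))),
              min_node = c(3L, 10L),
              max_depth = 25L, n_trees = 100L)
}

rf_fit <- function(x, y, hyper, seed) {
  fit <- .rf_train(as.matrix(x), as.numeric(y), as.integer(hyper$n_trees),
                   as.integer(hyper$mtry), as.integer(hyper$min_node),
                   as.integer(hyper$max_depth), as.integer(seed))
  structure(list(trees = fit$trees, importance = as.numeric(fit$importance),
                 hyper = hyper), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  .rf_predict(object$trees, as.matrix(newdata))
}

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

## 5-fold CV grid search; returns the winning hyperparameter row.
rf_grid_search <- function(x, y, grid, seed, n_folds = 5L) {
  n <- nrow(x)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  cv <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      fit <- rf_fit(x[tr, , drop = FALSE], y[tr], grid[g, ],
                    seed + 1000L * g + f)
      r_squared(y[!tr], predict(fit, x[!tr, , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(cv), ]
}

#' Random-forest regression of axis position with repeated splits
#'
#' Repeats `n_repeats` random 70/30 train/test splits; a grid-searched
#' random forest (5-fold CV on the first split's training set; the chosen
#' hyperparameters are reused across repeats) predicts the target, scoring
#' out-of-sample R-squared and impurity-based feature importance
#' (normalised mean decrease in variance, summing to 1 per repeat).
#'
#' @param table a [build_feature_table()] result
#' @param train_fraction fraction of vertices used for training
#' @param n_repeats number of random splits (100 in the full protocol)
#' @param seed integer seed
#' @param grid hyperparameter grid (data frame with `mtry`, `min_node`,
#'   `max_depth`, `n_trees`); defaults to [default_rf_grid()]
#' @param hyper optional fixed hyperparameters (skips the grid search)
#' @return object of class `axis_regression`: `r2` (per repeat),
#'   `importance` (repeat x feature), `hyper`, summary stats
#' @export
train_axis_regressor <- function(table, train_fraction = 0.7,
                                 n_repeats = 100L, seed = 1L, grid = NULL,
                                 hyper = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x; y <- table$target
  n <- nrow(x)
  if (n < 50L) stop("need at least 50 vertices")
  if (stats::sd(y) == 0) stop("degenerate constant target")
  if (is.null(grid)) grid <- default_rf_grid(ncol(x))
  set.seed(seed)
  split_seeds <- sample.int(2^30, n_repeats)
  n_tr <- round(train_fraction * n)
  if (is.null(hyper)) {
    set.seed(split_seeds[1L])
    tr <- sample.int(n, n_tr)
    hyper <- rf_grid_search(x[tr, , drop = FALSE], y[tr], grid,
                            seed = split_seeds[1L])
  }
  r2 <- numeric(n_repeats)
  imp <- matrix(NA_real_, n_repeats, ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (rep_i in seq_len(n_repeats)) {
    set.seed(split_seeds[rep_i])
    tr <- sample.int(n, n_tr)
    fit <- rf_fit(x[tr, , drop = FALSE], y[tr], hyper, split_seeds[rep_i])
    r2[rep_i] <- r_squared(y[-tr], predict(fit, x[-tr, , drop = FALSE]))
    imp[rep_i, ] <- fit$importance
  }
  structure(list(r2 = r2, importance = imp, hyper = hyper,
                 mean_r2 = mean(r2), sd_r2 = stats::sd(r2),
                 mean_importance = colMeans(imp),
                 split_seeds = split_seeds,
                 train_fraction = train_fraction),
            class = "axis_regression")
}

#' @export
print.axis_regression <- function(x, ...) {
  cat(sprintf("axis_regression: out-of-sample R2 = %.3f +/- %.3f (%d repeats)\n",
              x$mean_r2, x$sd_r2, length(x$r2)))
  top <- sort(x$mean_importance, decreasing = TRUE)[1:3]
  cat("  top features:",
      paste(sprintf("%s (%.0f%%)", names(top), 100 * top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Select above-average-importance features and refit
#'
#' Features whose mean importance exceeds the uniform average `1/p` are
#' retained; the model is refit on the reduced feature set with the same
#' hyperparameters and scored over repeated splits in the same manner.
#' A selection-stability score (mean pairwise Jaccard overlap of the
#' per-repeat above-average sets) is reported.
#'
#' @param fit an `axis_regression`
#' @param table the [build_feature_table()] the fit came from
#' @param n_repeats number of refit splits (defaults to the original)
#' @param seed integer seed
#' @return list: `selected` (feature names), `fit` (reduced
#'   `axis_regression`), `stability`
#' @export
select_and_refit <- function(fit, table, n_repeats = length(fit$r2),
                             seed = 1L) {
  p <- ncol(table$x)
  thr <- 1 / p
  mi <- fit$mean_importance
  sel <- names(mi)[mi > thr]
  if (!length(sel)) {
    warning("all importances at/below the uniform average; keeping all")
    sel <- names(mi)
  }
  per_rep <- fit$importance > thr
  nr <- nrow(per_rep)
  if (nr > 1L) {
    jac <- 0; cnt <- 0
    for (i in seq_len(nr - 1L)) for (j in seq(i + 1L, nr)) {
      a <- per_rep[i, ]; b <- per_rep[j, ]
      u <- sum(a | b)
      jac <- jac + if (u == 0) 1 else sum(a & b) / u
      cnt <- cnt + 1
    }
    stability <- jac / cnt
  } else stability <- NA_real_
  red <- table
  red$x <- table$x[, sel, drop = FALSE]
  red$feature_names <- sel
  refit <- train_axis_regressor(red, train_fraction = fit$train_fraction,
                                n_repeats = n_repeats, seed = seed,
                                hyper = fit$hyper)
  list(selected = sel, fit = refit, stability = stability)
}

#' Cubic fits of selected features against the axis
#'
#' Least-squares cubic of each selected (z-scored) feature on the axis,
#' with a monotonicity summary: the fraction of the axis range over which
#' the fitted derivative is positive.
#'
#' @param table a `feature_table`
#' @param selected feature names to fit (default: all)
#' @param degree polynomial degree (default 3, matching the unsupervised
#'   model choice)
#' @param n_grid evaluation grid size for the monotonicity summary
#' @return data frame: one row per feature with coefficients
#'   `c0..c<degree>`, `frac_increasing`, `adj_r2`
#' @export
feature_axis_curves <- function(table, selected = NULL, degree = 3L,
                                n_grid = 201L) {
  x <- table$target
  if (is.null(selected)) selected <- colnames(table$x)
  grid <- seq(min(x), max(x), length.out = n_grid)
  rows <- lapply(selected, function(f) {
    y <- table$x[, f]
    fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    dcf <- cf[-1] * seq_len(degree)
    deriv <- drop(outer(grid, seq_len(degree) - 1, "^") %*% dcf)
    r2 <- summary(fit)$r.squared
    out <- data.frame(feature = f, frac_increasing = mean(deriv > 0),
                      adj_r2 = adjusted_r2(r2, length(x), degree))
    cfm <- as.data.frame(t(cf))
    names(cfm) <- paste0("c", 0:degree)
    cbind(out, cfm)
  })
  do.call(rbind, rows)
}
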