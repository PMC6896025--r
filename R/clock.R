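# Tissue-specific epigenetic clock: epsilon-insensitive support vector
# regression of chronological age on the selected CpG markers, with
# hyperparameters chosen by k-fold cross-validated grid search scored by
# mean absolute deviation (MAD, years).

#' Default SVR hyperparameter grid
#'
#' Linear and RBF kernels; cost C in \{0.1, 1, 10, 100\}; epsilon in
#' \{0.1, 0.5, 1, 2\} years; for the RBF kernel gamma in \{1/m, scale\}
#' where m is the number of markers and `scale` = 1 / (m * var(X)).
#'
#' @param n_markers number of marker features m.
#' @param x_var overall variance of the training feature matrix (used for
#'   the scale-style gamma); default 1.
#' @return data.frame with columns kernel, C, epsilon, gamma.
#' @export
svr_grid <- function(n_markers, x_var = 1) {
  C <- c(0.1, 1, 10, 100)
  eps <- c(0.1, 0.5, 1, 2)
  lin <- expand.grid(kernel = "linear", C = C, epsilon = eps, gamma = NA_real_,
                     stringsAsFactors = FALSE)
  gam <- unique(c(1 / n_markers, 1 / (n_markers * max(x_var, 1e-12))))
  rbf <- expand.grid(kernel = "radial", C = C, epsilon = eps, gamma = gam,
                     stringsAsFactors = FALSE)
  rbind(lin, rbf)
}

svm_fit <- function(x, y, hp) {
  args <- list(x = x, y = y, type = "eps-regression", kernel = hp$kernel,
               cost = hp$C, epsilon = hp$epsilon, scale = FALSE)
  if (hp$kernel == "radial") args$gamma <- hp$gamma
  do.call(e1071::svm, args)
}

#' Grid-search SVR hyperparameters by k-fold cross-validation
#'
#' Exhaustive search over `grid`, scoring each combination by mean CV MAD
#' (years) over a seeded k-fold partition. Ties are broken in favor of the
#' linear kernel, then smaller C, then smaller epsilon, then smaller gamma.
#'
#' @param X samples x markers numeric matrix.
#' @param y ages in years.
#' @param k number of folds (10 by default).
#' @param grid hyperparameter grid as from [svr_grid()].
#' @param seed RNG seed for the fold assignment.
#' @return list with `best` (one-row data.frame) and `scores` (the grid
#'   with a `cv_mad` column).
#' @export
grid_search_svr <- function(X, y, k = 10, grid = NULL, seed = 1L) {
  n <- nrow(X)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k samples for k-fold cross-validation")
  if (is.null(grid)) grid <- svr_grid(ncol(X), stats::var(as.vector(X)))
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  cv_mad <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, ]
    err <- numeric(k)
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- svm_fit(X[!test, , drop = FALSE], y[!test], hp)
      pred <- as.numeric(stats::predict(fit, X[test, , drop = FALSE]))
      err[f] <- mean(abs(pred - y[test]))
    }
    cv_mad[g] <- mean(err)
  }
  scores <- cbind(grid, cv_mad = cv_mad)
  ord <- order(cv_mad,
               grid$kernel != "linear",   # linear preferred on ties
               grid$C, grid$epsilon, grid$gamma)
  list(best = scores[ord[1], , drop = FALSE], scores = scores)
}

#' Train a tissue-specific SVR age model
#'
#' Fits epsilon-insensitive SVR of age on the marker submatrix. Linear
#' kernels see the raw beta values; for the RBF kernel each marker is
#' standardized with training statistics that are stored in the model and
#' re-applied at prediction time.
#'
#' @param mat [beta_matrix] containing at least the marker probes.
#' @param samples sample table paired with `mat`.
#' @param marker_ids probe IDs to use as features (order preserved).
#' @param hyperparams one-row data.frame (kernel, C, epsilon, gamma), e.g.
#'   `grid_search_svr(...)$best`; `NULL` to run the default grid search.
#' @param tissue tissue label stored in the model.
#' @param seed seed for the internal grid search when `hyperparams` is NULL.
#' @return a `clock_model` object.
#' @export
train_clock <- function(mat, samples, marker_ids, hyperparams = NULL,
                        tissue = NA_character_, seed = 1L) {
  if (!length(marker_ids)) stop("marker_ids must be nonempty")
  absent <- setdiff(marker_ids, probe_ids(mat))
  if (length(absent))
    stop("markers absent from matrix: ", paste(absent, collapse = ", "))
  samples <- validate_sample_table(samples, mat)
  X <- t(unclass(mat)[marker_ids, , drop = FALSE])
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  y <- samples$age
  if (is.null(hyperparams))
    hyperparams <- grid_search_svr(X, y, seed = seed)$best
  center <- scale_sd <- NULL
  if (hyperparams$kernel == "radial") {
    center <- colMeans(X)
    scale_sd <- apply(X, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_sd, "/")
  }
  fit <- svm_fit(X, y, hyperparams)
  structure(list(tissue = tissue, marker_ids = marker_ids,
                 hyperparams = hyperparams[, c("kernel", "C", "epsilon", "gamma")],
                 fit = fit, center = center, scale = scale_sd),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf("clock_model (%s): %d markers, %s kernel, C=%g, epsilon=%g\n",
              x$tissue, length(x$marker_ids), hp$kernel, hp$C, hp$epsilon))
  invisible(x)
}

#' Predict chronological age from methylation
#'
#' @param model a `clock_model`.
#' @param mat [beta_matrix] containing every model marker (extra probes
#'   are ignored; sample order is preserved).
#' @return named numeric vector of predicted ages (years), one per sample.
#' @export
predict_age <- function(model, mat) {
  absent <- setdiff(model$marker_ids, probe_ids(mat))
  if (length(absent))
    stop("markers absent from matrix: ", paste(absent, collapse = ", "))
  if (ncol(mat) == 0) return(stats::setNames(numeric(0), character(0)))
  X <- t(unclass(mat)[model$marker_ids, , drop = FALSE])
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pred <- as.numeric(stats::predict(model$fit, X))
  stats::setNames(pred, sample_ids(mat))
}

#' Regression metrics for age prediction
#'
#' RMSE = sqrt(mean squared error); MAD = mean absolute deviation from the
#' y = x line; Pearson's r between predicted and observed; MAPE =
#' 100 * mean(|pred - obs| / |obs|) in percent; Theil's U = model RMSE
#' divided by the RMSE of the naive predictor that outputs the observed
#' mean (U < 1 means the model beats that baseline).
#'
#' @param predicted,observed numeric vectors of equal nonzero length
#'   (years). MAPE requires all observed values nonzero; Pearson's r is
#'   `NA` when either vector is constant.
#' @return list of class `clock_metrics`: rmse, mad, pearson_r, mape,
#'   theil_u, n; `theil_u_variant` names the baseline used.
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (!length(predicted)) stop("empty vectors")
  resid <- predicted - observed
  rmse <- sqrt(mean(resid^2))
  mad <- mean(abs(resid))
  r <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) NA_real_
       else stats::cor(predicted, observed)
  if (any(observed == 0)) stop("MAPE undefined: observed value of 0")
  mape <- 100 * mean(abs(resid) / abs(observed))
  rmse_naive <- sqrt(mean((mean(observed) - observed)^2))
  theil_u <- if (rmse_naive == 0) ifelse(rmse == 0, 0, Inf) else rmse / rmse_naive
  structure(list(rmse = rmse, mad = mad, pearson_r = r, mape = mape,
                 theil_u = theil_u, theil_u_variant = "rmse_vs_mean_baseline",
                 n = length(predicted)),
            class = "clock_metrics")
}

#' @export
print.clock_metrics <- function(x, ...) {
  cat(sprintf(
    "n=%d  RMSE=%.3f yr  MAD=%.3f yr  r=%.4f  MAPE=%.2f%%  Theil's U=%.3f\n",
    x$n, x$rmse, x$mad, x$pearson_r, x$mape, x$theil_u))
  invisible(x)
}
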