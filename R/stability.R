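# Bootstrap elastic-net stability selection. The dataset (samples x
# FDR-passing probes) is resampled with replacement; an elastic net of age
# on the probes is fitted per resample at fixed penalties; probes with a
# nonzero coefficient in more than `freq_threshold` of the fits are the
# tissue's markers.

COEF_ZERO_TOL <- 1e-8

#' Choose elastic-net penalties by cross-validation
#'
#' Penalties are tuned once on the full dataset and then held fixed across
#' all bootstrap fits: for each mixing value in `alpha_grid` a
#' cross-validated lambda path is fitted with shared fold assignments, and
#' the (alpha, lambda.min) pair with the lowest CV mean-squared error is
#' kept. Ties go to the smaller alpha (more ridge-like, preserving groups
#' of correlated probes).
#'
#' @param x samples x probes numeric matrix.
#' @param y ages in years.
#' @param alpha_grid candidate L1 mixing proportions.
#' @param nfolds CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return list with `penalty_mix` (alpha) and `penalty_strength` (lambda).
#' @export
choose_elastic_net_penalty <- function(x, y, alpha_grid = c(0.2, 0.5, 0.8),
                                       nfolds = 10, seed = 1L) {
  nfolds <- min(nfolds, nrow(x))
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    best <- NULL
    for (a in sort(alpha_grid)) {
      cv <- glmnet::cv.glmnet(x, y, alpha = a, foldid = foldid)
      score <- min(cv$cvm)
      if (is.null(best) || score < best$score - 1e-12)
        best <- list(penalty_mix = a, penalty_strength = cv$lambda.min,
                     score = score)
    }
    best[c("penalty_mix", "penalty_strength")]
  })
}

#' Bootstrap elastic-net stability selection
#'
#' For each of `n_boot` bootstrap resamples (columns drawn with
#' replacement, size n), fits an elastic net of age on the probe matrix
#' with penalty `penalty_strength * [penalty_mix * L1 + (1 - penalty_mix)/2 * L2]`
#' and records which coefficients are nonzero (|coef| > 1e-8). A resample
#' with zero age variance is redrawn and counted; more than 10% redraws is
#' an error. Penalties default to [choose_elastic_net_penalty()] on the
#' full data.
#'
#' @param mat [beta_matrix] restricted to the FDR-passing probes.
#' @param samples sample table paired with `mat` (or a numeric age vector).
#' @param n_boot number of bootstrap resamples (500 by default).
#' @param freq_threshold selection-frequency cutoff, strict `>` (0.95).
#' @param penalty_mix,penalty_strength elastic-net alpha and lambda; both
#'   `NULL` to tune on the full data.
#' @param seed RNG seed; frequencies are reproducible from it.
#' @return data.frame: probe_id, selection_frequency, mean_coefficient,
#'   selected; with attributes `penalty` and `n_redraws`.
#' @export
bootstrap_elastic_net <- function(mat, samples, n_boot = 500,
                                  freq_threshold = 0.95,
                                  penalty_mix = NULL, penalty_strength = NULL,
                                  seed = 1L) {
  if (nrow(mat) < 1) stop("need at least one probe")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (freq_threshold < 0 || freq_threshold > 1)
    stop("freq_threshold must lie in [0, 1]")
  ages <- if (is.numeric(samples)) samples
          else validate_sample_table(samples, mat)$age
  x <- t(unclass(mat))                       # samples x probes
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  n <- nrow(x)
  if (is.null(penalty_mix) || is.null(penalty_strength)) {
    pen <- choose_elastic_net_penalty(x, ages, seed = seed)
  } else {
    pen <- list(penalty_mix = penalty_mix, penalty_strength = penalty_strength)
  }
  # glmnet prefers a decreasing lambda path; coefficients are read off at
  # the final (target) lambda
  lam_path <- pen$penalty_strength * c(8, 4, 2, 1)
  p <- ncol(x)
  counts <- numeric(p)
  coef_sum <- numeric(p)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::var(ages[idx]) > 0) break
        redraws <- redraws + 1L
        if (redraws > 0.1 * n_boot)
          stop("more than 10% of bootstrap resamples had zero age variance")
      }
      fit <- glmnet::glmnet(x[idx, , drop = FALSE], ages[idx],
                            alpha = pen$penalty_mix, lambda = lam_path)
      cf <- as.numeric(stats::coef(fit, s = pen$penalty_strength))[-1]
      nz <- abs(cf) > COEF_ZERO_TOL
      counts <- counts + nz
      coef_sum <- coef_sum + cf
    }
  })
  freq <- counts / n_boot
  out <- data.frame(probe_id = probe_ids(mat),
                    selection_frequency = freq,
                    mean_coefficient = coef_sum / n_boot,
                    selected = freq > freq_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "penalty") <- pen
  attr(out, "n_redraws") <- redraws
  attr(out, "n_boot") <- n_boot
  attr(out, "freq_threshold") <- freq_threshold
  out
}

#' Extract the selected marker list
#'
#' Probes whose selection frequency strictly exceeds the threshold, sorted
#' by frequency descending then probe ID.
#'
#' @param stability result of [bootstrap_elastic_net()] (any data.frame
#'   with `probe_id` and `selection_frequency` columns works).
#' @param freq_threshold cutoff; defaults to the one recorded on
#'   `stability`, else 0.95.
#' @return character vector of probe IDs (possibly empty).
#' @export
select_markers <- function(stability,
                           freq_threshold = attr(stability, "freq_threshold")) {
  if (is.null(freq_threshold)) freq_threshold <- 0.95
  if (!nrow(stability)) return(character(0))
  sel <- stability[stability$selection_frequency > freq_threshold, , drop = FALSE]
  sel <- sel[order(-sel$selection_frequency, sel$probe_id), , drop = FALSE]
  sel$probe_id
}
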