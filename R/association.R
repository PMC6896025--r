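# Genome-wide per-probe association of methylation with age: univariate OLS
# of beta on age, F-test of the slope (identical to the squared slope
# t-test for a single regressor), Benjamini-Hochberg FDR over the probe
# family, and selection at q < threshold.

#' Per-probe linear regression of beta values on age
#'
#' Ordinary least squares of one probe's beta values on chronological age.
#' The F statistic is `(SST - SSE) / (SSE / (n - 2))`, the usual test of
#' the null that the regression coefficient is zero, and equals the square
#' of the slope's t statistic; the p-value is the upper tail of F(1, n-2).
#'
#' @param betas numeric vector of beta values, one per sample.
#' @param ages numeric vector of ages in years, same length.
#' @return one-row data.frame: slope, intercept, f_statistic, p_value.
#' @export
fit_probe_regression <- function(betas, ages) {
  res <- probe_association(matrix(betas, nrow = 1,
                                  dimnames = list("probe", NULL)), ages)
  res$probe_id <- NULL
  res
}

#' Vectorized per-probe regression over a whole matrix
#'
#' Closed-form OLS applied to every row at once; used by
#' [select_age_probes()] and exposed for genome-scale scans.
#'
#' @param mat numeric probes x samples matrix (no missing values).
#' @param ages numeric vector of ages, one per column.
#' @return data.frame: probe_id, slope, intercept, f_statistic, p_value.
#' @export
probe_association <- function(mat, ages) {
  v <- unclass(mat)
  n <- ncol(v)
  if (length(ages) != n) stop("length(ages) must equal ncol(mat)")
  if (n < 3) stop("need at least 3 samples for the per-probe F-test")
  if (stats::var(ages) == 0) stop("ages have zero variance")
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  ym <- rowMeans(v)
  sxy <- as.vector(v %*% xc)
  slope <- sxy / sxx
  intercept <- ym - slope * mean(ages)
  sst <- rowSums((v - ym)^2)
  const <- sst <= 1e-24                  # constant probe up to roundoff
  slope[const] <- 0
  sse <- pmax(sst - slope * sxy, 0)      # guard tiny negatives from roundoff
  f <- ifelse(sse > 0, (sst - sse) / (sse / (n - 2)),
              ifelse(slope == 0, 0, Inf))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[f == 0] <- 1
  data.frame(probe_id = rownames(v), slope = slope, intercept = intercept,
             f_statistic = f, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m * p_(j) / j` on the
#' sorted scale, capped at 1, returned in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select age-associated probes at an FDR threshold
#'
#' Runs [probe_association()] on every probe, adjusts the full probe family
#' with [bh_fdr()], and returns probes with `q < fdr_threshold` (strict),
#' sorted by q then probe ID.
#'
#' @param mat a harmonized [beta_matrix] (no missing values).
#' @param samples sample table paired with `mat`.
#' @param fdr_threshold FDR cutoff, default 0.05.
#' @param all_results if `TRUE`, return every probe with a `selected`
#'   column instead of only the selected ones.
#' @return data.frame of association results with a `q_value` column.
#' @export
select_age_probes <- function(mat, samples, fdr_threshold = 0.05,
                              all_results = FALSE) {
  if (fdr_threshold < 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in [0, 1)")
  samples <- validate_sample_table(samples, mat)
  res <- probe_association(mat, samples$age)
  res$q_value <- bh_fdr(res$p_value)
  res$selected <- res$q_value < fdr_threshold
  res <- res[order(res$q_value, res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  if (all_results) res else res[res$selected, setdiff(names(res), "selected"),
                                drop = FALSE]
}
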