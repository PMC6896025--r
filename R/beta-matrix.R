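#' Beta-value matrix container
#'
#' A `beta_matrix` is a numeric probes x samples matrix of methylation beta
#' values in \[0, 1\], with `NA` marking missing (masked) entries, unique
#' probe IDs as rownames, unique sample IDs as colnames, and a free-text
#' platform tag (e.g. `"450K"`).
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#'   Rownames and colnames are required and must be unique.
#' @param platform character scalar tagging the array dialect the values
#'   came from; `NA` when unknown or mixed.
#' @return a `beta_matrix` object.
#' @export
beta_matrix <- function(values, platform = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("'values' must carry probe IDs as rownames")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0)
      stop("'values' must carry sample IDs as colnames")
    colnames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicated probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop("beta values must lie in [0, 1]; found values outside the range")
  structure(values, platform = as.character(platform)[1], class = c("beta_matrix", "matrix"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (platform: %s, %.2f%% missing)\n",
              nrow(x), ncol(x), attr(x, "platform"),
              100 * mean(is.na(x))))
  invisible(x)
}

probe_ids <- function(mat) rownames(mat)
sample_ids <- function(mat) colnames(mat)

# Subset while keeping class + platform attribute.
subset_beta <- function(mat, rows = NULL, cols = NULL) {
  platform <- attr(mat, "platform")
  v <- unclass(mat)
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  beta_matrix(v, platform)
}

#' Validate a sample table against a beta matrix
#'
#' A sample table is a data.frame with columns `sample_id`, `age` (years)
#' and `tissue`. When `mat` is given, its sample IDs must each appear
#' exactly once in the table.
#'
#' @param samples data.frame with columns `sample_id`, `age`, `tissue`.
#' @param mat optional `beta_matrix` to cross-check IDs against.
#' @return the validated sample table, rows ordered to match `mat` when given.
#' @export
validate_sample_table <- function(samples, mat = NULL) {
  need <- c("sample_id", "age", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id in sample table")
  if (!is.numeric(samples$age) || any(!is.finite(samples$age)))
    stop("ages must be finite numbers")
  if (any(samples$age < 0)) stop("ages must be nonnegative")
  if (!is.null(mat)) {
    idx <- match(sample_ids(mat), samples$sample_id)
    if (anyNA(idx))
      stop("samples absent from sample table: ",
           paste(sample_ids(mat)[is.na(idx)], collapse = ", "))
    samples <- samples[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  samples
}
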