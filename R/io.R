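#' Read a beta-value matrix from a delimited text file
#'
#' Expects a TSV with probe IDs in the first column, a header row of sample
#' IDs, and beta values in \[0, 1\]. Empty fields and the token `NA` are
#' treated as missing (masked) entries. Values outside \[0, 1\], duplicated
#' probe IDs and ragged rows are rejected.
#'
#' @param path path to the TSV file.
#' @param platform platform tag to attach (e.g. `"27K"`, `"450K"`).
#' @return a [beta_matrix].
#' @export
read_beta_matrix <- function(path, platform = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1) stop("parse error in ", path, ": empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("parse error in ", path, " at line 1: no sample columns")
  samples <- header[-1]
  n <- length(samples)
  body <- lines[-1]
  probes <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = n)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad them back
    if (length(f) < n + 1) f <- c(f, rep("", n + 1 - length(f)))
    if (length(f) != n + 1)
      stop("parse error in ", path, " at line ", i + 1,
           ": expected ", n + 1, " fields, found ", length(f))
    probes[i] <- f[1]
    x <- f[-1]
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
    bad <- !is.na(x) & x != "NA" & is.na(v)
    if (any(bad))
      stop("parse error in ", path, " at line ", i + 1,
           ": non-numeric value '", x[which(bad)[1]], "'")
    vals[i, ] <- v
  }
  if (anyDuplicated(probes))
    stop("validation error in ", path, ": duplicated probe ID ",
         probes[duplicated(probes)][1])
  out <- vals[!is.na(vals)]
  if (length(out) && (min(out) < 0 || max(out) > 1))
    stop("validation error in ", path, ": beta value outside [0, 1]")
  dimnames(vals) <- list(probes, samples)
  beta_matrix(vals, platform)
}

#' Write a beta matrix as TSV
#'
#' Inverse of [read_beta_matrix()]; missing entries are written as `NA`.
#' Values are written at full double precision so a round trip is exact.
#'
#' @param mat a [beta_matrix].
#' @param path output path.
#' @export
write_beta_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", sample_ids(mat)), collapse = "\t"), con)
  body <- apply(unclass(mat), 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(probe_ids(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a sample table (sample_id, age, tissue)
#' @param path TSV path.
#' @return data.frame with columns sample_id, age, tissue.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param samples sample table to write.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Columns: probe_id, gene_structure, island_relation, chrom, start, end,
#' mean_conservation. Coordinates are 0-based half-open; mean_conservation
#' is a phastCons-style score in \[0, 1\].
#'
#' @param path TSV path.
#' @return validated annotation data.frame.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(df)
}

validate_annotation <- function(ann) {
  need <- c("probe_id", "gene_structure", "island_relation", "chrom",
            "start", "end", "mean_conservation")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicated probe_id in annotation")
  if (any(ann$start >= ann$end)) stop("annotation regions must satisfy start < end")
  if (any(ann$mean_conservation < 0 | ann$mean_conservation > 1, na.rm = TRUE))
    stop("mean_conservation must lie in [0, 1]")
  ann
}

#' @rdname read_probe_annotation
#' @param ann annotation table to write.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict matrices to their common probes
#'
#' Platform harmonization step: every matrix is restricted to the sorted
#' intersection of all probe ID sets, so downstream stages see one shared
#' probe universe in identical order.
#'
#' @param matrices list of [beta_matrix] objects.
#' @return list of [beta_matrix] objects over the common probes.
#' @export
intersect_platforms <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix")
  common <- Reduce(intersect, lapply(matrices, probe_ids))
  if (!length(common)) stop("empty probe intersection across platforms")
  common <- sort(common)
  lapply(matrices, subset_beta, rows = common)
}

#' Drop probes with too many missing values
#'
#' Keeps exactly the probes with fewer than `max_missing` masked entries
#' (strict `<`), preserving probe order.
#'
#' @param mat a [beta_matrix].
#' @param max_missing integer threshold; a probe with this many or more
#'   missing entries is dropped. Default 10. `max_missing = 0` keeps only
#'   fully observed probes.
#' @return filtered [beta_matrix].
#' @export
filter_missing <- function(mat, max_missing = 10) {
  if (max_missing < 0) stop("max_missing must be >= 0")
  n_miss <- rowSums(is.na(mat))
  keep <- if (max_missing == 0) n_miss == 0 else n_miss < max_missing
  subset_beta(mat, rows = which(keep))
}

#' Mean-impute residual missing values
#'
#' Each masked entry is replaced by the probe's observed mean, which leaves
#' per-probe means unchanged. Probes with no observed value are an error;
#' run [filter_missing()] first.
#'
#' @param mat a [beta_matrix].
#' @return [beta_matrix] with no missing values.
#' @export
impute_missing <- function(mat) {
  v <- unclass(mat)
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0))
    stop("probes with all values missing (filter first): ",
         paste(utils::head(rownames(v)[n_obs == 0], 5), collapse = ", "))
  miss <- which(is.na(v), arr.ind = TRUE)
  if (nrow(miss)) {
    means <- rowMeans(v, na.rm = TRUE)
    v[miss] <- means[miss[, 1]]
  }
  beta_matrix(v, attr(mat, "platform"))
}

#' Per-probe quantile normalization to the uniform distribution
#'
#' Maps each probe's values across samples to their empirical-quantile
#' positions on \[0, 1\] (rank - 1)/(n - 1), with average ranks for ties, so
#' within-probe sample ranks are preserved and every probe has the same
#' marginal distribution. Applied per platform batch before merging
#' datasets to remove platform-level distribution shift.
#'
#' @param mat a [beta_matrix] with no missing values.
#' @return normalized [beta_matrix].
#' @export
quantile_normalize <- function(mat) {
  if (anyNA(mat)) stop("impute missing values before quantile normalization")
  v <- unclass(mat)
  n <- ncol(v)
  if (n == 1) {
    v[] <- 0.5
  } else {
    v <- t(apply(v, 1, function(r) (rank(r, ties.method = "average") - 1) / (n - 1)))
    dimnames(v) <- dimnames(mat)
  }
  beta_matrix(v, attr(mat, "platform"))
}

#' Merge harmonized datasets column-wise
#'
#' Matrices must share an identical probe set (run [intersect_platforms()]
#' first); sample IDs must be globally unique. Sample tables are
#' concatenated with a `dataset` provenance column.
#'
#' @param matrices list of [beta_matrix] objects over identical probes.
#' @param sample_tables list of sample tables, parallel to `matrices`.
#' @return list with elements `beta` (merged [beta_matrix]) and `samples`.
#' @export
merge_datasets <- function(matrices, sample_tables) {
  if (length(matrices) != length(sample_tables))
    stop("matrices and sample_tables must have equal length")
  ref <- probe_ids(matrices[[1]])
  for (m in matrices[-1])
    if (!identical(probe_ids(m), ref)) stop("probe sets differ; run intersect_platforms first")
  ids <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(ids))
    stop("duplicate sample IDs across datasets: ", ids[duplicated(ids)][1])
  merged <- do.call(cbind, lapply(matrices, unclass))
  platforms <- unique(vapply(matrices, function(m) attr(m, "platform"), character(1)))
  tag <- if (length(platforms) == 1) platforms else "merged"
  names(sample_tables) <- NULL
  st <- do.call(rbind, lapply(seq_along(sample_tables), function(i) {
    s <- validate_sample_table(sample_tables[[i]], matrices[[i]])
    s$dataset <- i
    s
  }))
  rownames(st) <- NULL
  list(beta = beta_matrix(merged, tag), samples = st)
}

#' One-call harmonization pipeline
#'
#' Intersects probe sets across input matrices, filters high-missingness
#' probes per matrix, mean-imputes the rest, optionally quantile-normalizes
#' each platform batch, and merges. Normalization defaults to "whenever
#' more than one dataset is merged".
#'
#' @param matrices list of [beta_matrix] objects (one per platform batch).
#' @param sample_tables parallel list of sample tables.
#' @param max_missing per-probe missing-value cutoff (strict `<`).
#' @param normalize `"auto"` (normalize iff >1 dataset), `TRUE` or `FALSE`.
#' @return list with `beta` and `samples` as in [merge_datasets()].
#' @export
harmonize <- function(matrices, sample_tables, max_missing = 10, normalize = "auto") {
  mats <- intersect_platforms(matrices)
  mats <- lapply(mats, filter_missing, max_missing = max_missing)
  # keep a shared probe set after per-batch filtering
  mats <- intersect_platforms(mats)
  mats <- lapply(mats, impute_missing)
  do_norm <- if (identical(normalize, "auto")) length(mats) > 1 else isTRUE(normalize)
  if (do_norm) mats <- lapply(mats, quantile_normalize)
  merge_datasets(mats, sample_tables)
}
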