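# Small fixture builders shared across test files.

# beta_matrix from a plain matrix, inventing IDs when absent
bm <- function(values, platform = NA_character_) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cg%08d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  beta_matrix(values, platform)
}

# sample table for a matrix with given ages
stab <- function(mat, ages, tissue = "t1") {
  data.frame(sample_id = colnames(mat), age = ages, tissue = tissue,
             stringsAsFactors = FALSE)
}

# one-tissue panel with planted markers, no missing values, no 27K split
one_tissue_cfg <- function(n = 150, n_probes = 500, n_markers = 30,
                           seed = 1, ...) {
  sim_config(n_tissues = 1, n_samples_per_tissue = n, n_probes = n_probes,
             n_common_markers = 0, n_specific_markers_per_tissue = n_markers,
             missing_rate = 0, platform_split = 0, seed = seed, ...)
}

planted_ids <- function(panel) {
  panel$truth$probes$probe_id[panel$truth$probes$label != "null"]
}
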