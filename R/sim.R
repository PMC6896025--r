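# Synthetic multi-tissue methylation panels with planted age-associated CpGs.
#
# The generator emulates the structure the downstream stages assume: beta
# values linear in age on the beta scale with Gaussian noise and clamping to
# [0, 1]; markers shared by all tissues vs private to one tissue, with
# positive and negative directions; island/shore annotation and
# conservation scores that differ between the two marker classes; missing
# values; and a two-dialect (27K-subset vs 450K-superset) export.

#' Simulation configuration
#'
#' @param n_tissues number of tissues.
#' @param n_samples_per_tissue samples per tissue.
#' @param n_probes total probe universe size (shared across tissues).
#' @param n_common_markers probes planted age-linear in all tissues.
#' @param n_specific_markers_per_tissue probes planted in exactly one tissue.
#' @param frac_positive_common,frac_positive_specific fraction of planted
#'   markers whose methylation increases with age, per class.
#' @param age_range numeric length-2, min and max age in years.
#' @param slope_magnitude absolute planted slope, beta-units per year.
#' @param noise_sd residual standard deviation, beta-units.
#' @param island_prob_common,island_prob_specific,island_prob_background
#'   probability a probe in each class is annotated as a CpG island;
#'   non-island probes split evenly between shore and other.
#' @param conservation_mean_common,conservation_mean_specific mean
#'   phastCons-style conservation score per class (Beta-distributed with
#'   concentration `conservation_concentration`); background probes use the
#'   specific-class mean.
#' @param conservation_concentration Beta concentration (a + b) of the
#'   conservation-score distribution.
#' @param missing_rate per-entry masking probability.
#' @param platform_split proportion of samples exported in the 27K dialect.
#' @param probe_27k_frac fraction of null probes also present on the
#'   27K-dialect manifest (planted markers are always present on both).
#' @param seed integer RNG seed; the whole panel is reproducible from it.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_tissues = 3,
                       n_samples_per_tissue = 150,
                       n_probes = 2000,
                       n_common_markers = 20,
                       n_specific_markers_per_tissue = 15,
                       frac_positive_common = 0.8,
                       frac_positive_specific = 0.4,
                       age_range = c(20, 90),
                       slope_magnitude = 0.005,
                       noise_sd = 0.02,
                       island_prob_common = 0.7,
                       island_prob_specific = 0.3,
                       island_prob_background = 0.35,
                       conservation_mean_common = 0.6,
                       conservation_mean_specific = 0.5,
                       conservation_concentration = 10,
                       missing_rate = 0.01,
                       platform_split = 0.5,
                       probe_27k_frac = 0.8,
                       seed = 1L) {
  cfg <- list(n_tissues = n_tissues,
              n_samples_per_tissue = n_samples_per_tissue,
              n_probes = n_probes,
              n_common_markers = n_common_markers,
              n_specific_markers_per_tissue = n_specific_markers_per_tissue,
              frac_positive_common = frac_positive_common,
              frac_positive_specific = frac_positive_specific,
              age_range = age_range,
              slope_magnitude = slope_magnitude,
              noise_sd = noise_sd,
              island_prob_common = island_prob_common,
              island_prob_specific = island_prob_specific,
              island_prob_background = island_prob_background,
              conservation_mean_common = conservation_mean_common,
              conservation_mean_specific = conservation_mean_specific,
              conservation_concentration = conservation_concentration,
              missing_rate = missing_rate,
              platform_split = platform_split,
              probe_27k_frac = probe_27k_frac,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < min || v != round(v))
      stop("configuration error: '", field, "' must be an integer >= ", min)
  }
  chk_prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("configuration error: '", field, "' must be a proportion in [0, 1]")
  }
  chk_count("n_tissues", 1); chk_count("n_samples_per_tissue", 1)
  chk_count("n_probes", 1); chk_count("n_common_markers")
  chk_count("n_specific_markers_per_tissue")
  for (f in c("frac_positive_common", "frac_positive_specific",
              "island_prob_common", "island_prob_specific",
              "island_prob_background", "conservation_mean_common",
              "conservation_mean_specific", "missing_rate",
              "platform_split", "probe_27k_frac"))
    chk_prop(f)
  planted <- cfg$n_common_markers + cfg$n_tissues * cfg$n_specific_markers_per_tissue
  if (planted > cfg$n_probes)
    stop("configuration error: 'n_probes' must be >= n_common_markers + ",
         "n_tissues * n_specific_markers_per_tissue (", planted, ")")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    stop("configuration error: 'age_range' must be (min, max) with min < max")
  if (cfg$slope_magnitude <= 0)
    stop("configuration error: 'slope_magnitude' must be > 0")
  if (cfg$noise_sd < 0)
    stop("configuration error: 'noise_sd' must be >= 0")
  if (cfg$conservation_concentration <= 0)
    stop("configuration error: 'conservation_concentration' must be > 0")
  structure(cfg, class = "sim_config")
}

# Run expr with a private RNG state seeded from `seed`; restores the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-tissue methylation panel
#'
#' Ages are uniform over `age_range`. A planted probe j in tissue t follows
#' `beta = clamp(b0_j + s_jt * age + eps, 0, 1)` with
#' `eps ~ N(0, noise_sd)` and `s_jt = direction * slope_magnitude` where
#' planted and 0 elsewhere. Intercepts are sampled so the mean trajectory
#' stays at least `3 * noise_sd + 0.02` away from both boundaries over the
#' age range, keeping clamping rare. Common markers keep one direction in
#' every tissue; specific markers have nonzero slope in exactly one tissue.
#'
#' @param config a [sim_config].
#' @return list with `beta` (list of [beta_matrix] per tissue), `samples`
#'   (list of sample tables), `annotation` (probe annotation data.frame)
#'   and `truth` (ground-truth list; see Details).
#' @details `truth` carries `probes` (data.frame: probe_id, label,
#'   tissue, direction, island_relation, mean_conservation), `slopes`
#'   (probes x tissues matrix of planted slopes, beta-units/year),
#'   `probes_27k` (the probe subset on the 27K-dialect manifest) and the
#'   generating `config`.
#' @export
generate_panel <- function(config) {
  config <- validate_sim_config(unclass(config))
  with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  p <- cfg$n_probes
  tiss <- paste0("tissue", seq_len(cfg$n_tissues))
  probes <- sprintf("cg%08d", seq_len(p))

  label <- rep("null", p)
  marker_tissue <- rep(NA_character_, p)
  direction <- integer(p)
  idx <- sample.int(p)  # random placement of planted probes
  common_idx <- idx[seq_len(cfg$n_common_markers)]
  off <- cfg$n_common_markers
  spec_idx <- vector("list", cfg$n_tissues)
  for (t in seq_len(cfg$n_tissues)) {
    spec_idx[[t]] <- idx[off + seq_len(cfg$n_specific_markers_per_tissue)]
    off <- off + cfg$n_specific_markers_per_tissue
  }
  label[common_idx] <- "common"
  direction[common_idx] <- ifelse(
    stats::runif(length(common_idx)) < cfg$frac_positive_common, 1L, -1L)
  for (t in seq_len(cfg$n_tissues)) {
    label[spec_idx[[t]]] <- "specific"
    marker_tissue[spec_idx[[t]]] <- tiss[t]
    direction[spec_idx[[t]]] <- ifelse(
      stats::runif(length(spec_idx[[t]])) < cfg$frac_positive_specific, 1L, -1L)
  }

  slopes <- matrix(0, nrow = p, ncol = cfg$n_tissues,
                   dimnames = list(probes, tiss))
  slopes[common_idx, ] <- direction[common_idx] * cfg$slope_magnitude
  for (t in seq_len(cfg$n_tissues))
    slopes[spec_idx[[t]], t] <- direction[spec_idx[[t]]] * cfg$slope_magnitude

  # intercepts: keep the mean trajectory >= margin from both boundaries
  # over the age range wherever any tissue has a nonzero slope
  margin <- 3 * cfg$noise_sd + 0.02
  a1 <- cfg$age_range[1]; a2 <- cfg$age_range[2]
  s_abs <- cfg$slope_magnitude
  if (1 - 2 * margin < s_abs * (a2 - a1))
    stop("configuration error: 'slope_magnitude' too large for the age ",
         "range; planted trajectories cannot stay inside (0, 1)")
  b0 <- stats::runif(p, margin, 1 - margin)   # null probes: flat baseline
  # planted probes: sample b0 so b0 + s*age stays in [margin, 1 - margin]
  pos <- which(direction > 0)
  neg <- which(direction < 0)
  b0[pos] <- stats::runif(length(pos), margin - s_abs * a1, 1 - margin - s_abs * a2)
  b0[neg] <- stats::runif(length(neg), margin + s_abs * a2, 1 - margin + s_abs * a1)

  # annotation
  p_island <- rep(cfg$island_prob_background, p)
  p_island[label == "common"] <- cfg$island_prob_common
  p_island[label == "specific"] <- cfg$island_prob_specific
  u <- stats::runif(p)
  relation <- ifelse(u < p_island, "island",
                     ifelse(u < p_island + (1 - p_island) / 2, "shore", "other"))
  gs_levels <- c("TSS/promoter", "5'UTR", "exon", "gene body", "3'UTR", "intergenic")
  gs_probs <- c(0.15, 0.05, 0.10, 0.35, 0.05, 0.30)
  gene_structure <- sample(gs_levels, p, replace = TRUE, prob = gs_probs)
  cons_mean <- rep(cfg$conservation_mean_specific, p)
  cons_mean[label == "common"] <- cfg$conservation_mean_common
  kappa <- cfg$conservation_concentration
  conservation <- stats::rbeta(p, cons_mean * kappa, (1 - cons_mean) * kappa)
  start <- sample.int(2e8, p)
  annotation <- data.frame(
    probe_id = probes,
    gene_structure = gene_structure,
    island_relation = relation,
    chrom = paste0("chr", sample.int(22, p, replace = TRUE)),
    start = start,
    end = start + 500L,
    mean_conservation = conservation,
    stringsAsFactors = FALSE)

  # per-tissue matrices
  n <- cfg$n_samples_per_tissue
  beta_list <- vector("list", cfg$n_tissues)
  sample_list <- vector("list", cfg$n_tissues)
  names(beta_list) <- names(sample_list) <- tiss
  for (t in seq_len(cfg$n_tissues)) {
    ages <- stats::runif(n, a1, a2)
    sid <- sprintf("%s_s%03d", tiss[t], seq_len(n))
    mu <- outer(b0, rep(1, n)) + outer(slopes[, t], ages)
    v <- mu + stats::rnorm(p * n, 0, cfg$noise_sd)
    v <- pmin(pmax(v, 0), 1)
    if (cfg$missing_rate > 0)
      v[stats::runif(p * n) < cfg$missing_rate] <- NA_real_
    dimnames(v) <- list(probes, sid)
    beta_list[[t]] <- beta_matrix(v, "450K")
    sample_list[[t]] <- data.frame(sample_id = sid, age = ages,
                                   tissue = tiss[t], stringsAsFactors = FALSE)
  }

  # 27K-dialect manifest: all planted markers plus a fraction of null probes
  null_probes <- probes[label == "null"]
  n27_null <- round(cfg$probe_27k_frac * length(null_probes))
  probes_27k <- sort(c(probes[label != "null"],
                       sample(null_probes, n27_null)))

  truth <- list(
    probes = data.frame(probe_id = probes, label = label,
                        tissue = marker_tissue, direction = direction,
                        island_relation = relation,
                        mean_conservation = conservation,
                        stringsAsFactors = FALSE),
    slopes = slopes,
    probes_27k = probes_27k,
    config = cfg)

  list(beta = beta_list, samples = sample_list,
       annotation = annotation, truth = truth)
}

#' Export a panel as two platform-dialect TSV files per tissue
#'
#' Samples are partitioned by `platform_split` (that proportion goes into
#' the 27K-dialect file); the 27K file carries only the probes on the
#' 27K-dialect manifest (`truth$probes_27k`), a strict subset of the 450K
#' file's probes, so the probe ID sets overlap but are not identical.
#'
#' @param panel output of [generate_panel()].
#' @param dir output directory (created if needed).
#' @return data.frame listing the written files (tissue, platform, path).
#' @export
export_platform_dialects <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- panel$truth$config
  files <- list()
  for (t in names(panel$beta)) {
    mat <- panel$beta[[t]]
    n <- ncol(mat)
    n27 <- round(cfg$platform_split * n)
    cols27 <- seq_len(n27)            # deterministic partition
    paths <- c(`27K` = file.path(dir, paste0(t, "_27K.tsv")),
               `450K` = file.path(dir, paste0(t, "_450K.tsv")))
    if (n27 > 0) {
      m27 <- subset_beta(mat, rows = panel$truth$probes_27k, cols = cols27)
      attr(m27, "platform") <- "27K"
      write_beta_matrix(m27, paths["27K"])
    } else {
      paths <- paths["450K"]
    }
    m450 <- if (n27 < n) subset_beta(mat, cols = setdiff(seq_len(n), cols27)) else NULL
    if (!is.null(m450) && ncol(m450) > 0) {
      write_beta_matrix(m450, paths[["450K"]])
    } else {
      paths <- paths[names(paths) != "450K"]
    }
    files[[t]] <- data.frame(tissue = t, platform = names(paths),
                             path = unname(paths), stringsAsFactors = FALSE)
    write_sample_table(panel$samples[[t]], file.path(dir, paste0(t, "_samples.tsv")))
  }
  write_probe_annotation(panel$annotation, file.path(dir, "annotation.tsv"))
  out <- do.call(rbind, files)
  rownames(out) <- NULL
  out
}
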