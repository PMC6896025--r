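# End-to-end orchestration: simulate -> harmonize -> associate -> select ->
# train -> evaluate -> characterize, as one reproducible, logged run.
# Every stochastic stage derives its seed from the master seed and the
# stage name, so stages are individually reproducible and the whole run is
# reproducible from one integer.

PIPELINE_STAGES <- c("simulate", "harmonize", "associate", "select",
                     "train", "evaluate", "characterize")

# each stage requires its predecessor in this DAG
STAGE_DEPS <- list(simulate = character(0),
                   harmonize = "simulate",
                   associate = "harmonize",
                   select = "associate",
                   train = "select",
                   evaluate = "train",
                   characterize = "select")

stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 131 + h * 7919) %% 2147483611)
}

#' Pipeline run configuration
#'
#' Stage parameters default to the workflow's standard values: probes with
#' fewer than 10 missing values retained, FDR < 0.05 probe selection, 500
#' bootstrap elastic-net fits with a 0.95 selection-frequency threshold,
#' 10-fold cross-validated SVR grid search, and 5 samples per extreme
#' group in the young/old contrast.
#'
#' @param out_dir run directory for stage outputs and the manifest.
#' @param sim a [sim_config] describing the synthetic panel.
#' @param max_missing per-probe missing-value cutoff (strict `<`).
#' @param normalize `"auto"`, `TRUE` or `FALSE`; see [harmonize()].
#' @param fdr FDR threshold for probe selection.
#' @param n_boot bootstrap resamples for stability selection.
#' @param freq selection-frequency threshold (strict `>`).
#' @param cv cross-validation folds for the SVR grid search.
#' @param k_young_old samples per extreme group in the young/old contrast.
#' @param train_frac fraction of samples used for training; the rest form
#'   the held-out evaluation set.
#' @param seed master seed.
#' @param stages character vector of enabled stages (prefix of the DAG).
#' @return validated `run_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            max_missing = 10,
                            normalize = "auto",
                            fdr = 0.05,
                            n_boot = 500,
                            freq = 0.95,
                            cv = 10,
                            k_young_old = 5,
                            train_frac = 0.8,
                            seed = 1L,
                            stages = PIPELINE_STAGES) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (s in stages) {
    dep <- STAGE_DEPS[[s]]
    if (length(dep) && !dep %in% stages)
      stop("configuration error: stage '", s, "' requires stage '", dep, "'")
  }
  if (train_frac <= 0 || train_frac > 1) stop("train_frac must lie in (0, 1]")
  structure(list(out_dir = out_dir, sim = validate_sim_config(unclass(sim)),
                 max_missing = max_missing, normalize = normalize, fdr = fdr,
                 n_boot = n_boot, freq = freq, cv = cv,
                 k_young_old = k_young_old, train_frac = train_frac,
                 seed = as.integer(seed), stages = stages),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` key
#' mirrors [sim_config()] fields.
#'
#' @param path YAML (`.yml`/`.yaml`, requires the yaml package) or JSON file.
#' @return a `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full tissue-clock pipeline
#'
#' Executes the enabled stages in order on a synthetic panel, writing each
#' stage's tables under `config$out_dir` and a `manifest.json` recording
#' package version, parameters, per-stage seeds, output checksums and row
#' counts. Rerunning with the same configuration reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`panel`, `harmonized`, `association`, `stability`, `markers`,
#'   `clocks`, `metrics`, `characterization`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  on_stage <- function(s) s %in% config$stages
  res <- list()
  manifest <- list(package = "tissueclock",
                   version = as.character(utils::packageVersion("tissueclock")),
                   parameters = config[setdiff(names(config), "out_dir")],
                   seeds = stats::setNames(
                     lapply(config$stages, stage_seed, master_seed = config$seed),
                     config$stages),
                   stages = list())
  note <- function(stage, files, counts) {
    manifest$stages[[stage]] <<- list(
      files = stats::setNames(as.list(unname(tools::md5sum(files))), basename(files)),
      rows = counts)
  }

  # --- simulate ---------------------------------------------------------
  if (on_stage("simulate")) {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    panel <- generate_panel(sim_cfg)
    sim_dir <- file.path(config$out_dir, "sim")
    exported <- export_platform_dialects(panel, sim_dir)
    res$panel <- panel
    res$exported <- exported
    note("simulate", c(exported$path, file.path(sim_dir, "annotation.tsv")),
         list(probes = sim_cfg$n_probes, tissues = sim_cfg$n_tissues))
  }

  tissues <- names(res$panel$beta)

  # --- harmonize: reload the exported dialects and merge per tissue -----
  if (on_stage("harmonize")) {
    res$harmonized <- list()
    files <- character(0)
    for (t in tissues) {
      ex <- res$exported[res$exported$tissue == t, , drop = FALSE]
      mats <- Map(read_beta_matrix, ex$path, ex$platform)
      st <- read_sample_table(file.path(config$out_dir, "sim",
                                        paste0(t, "_samples.tsv")))
      tabs <- lapply(mats, function(m)
        st[st$sample_id %in% sample_ids(m), , drop = FALSE])
      res$harmonized[[t]] <- harmonize(mats, tabs,
                                       max_missing = config$max_missing,
                                       normalize = config$normalize)
      f <- file.path(config$out_dir, paste0(t, "_merged.tsv"))
      write_beta_matrix(res$harmonized[[t]]$beta, f)
      files <- c(files, f)
    }
    note("harmonize", files,
         lapply(res$harmonized, function(h) nrow(h$beta)))
  }

  # train/test split (seeded once, reused by associate/select/train/evaluate)
  if (on_stage("associate")) {
    split_seed <- stage_seed(config$seed, "split")
    res$split <- lapply(res$harmonized, function(h) {
      n <- ncol(h$beta)
      n_train <- max(3, round(config$train_frac * n))
      idx <- with_seed(split_seed, sample.int(n, n_train))
      list(train = sort(idx), test = sort(setdiff(seq_len(n), idx)))
    })
  }

  # --- associate --------------------------------------------------------
  if (on_stage("associate")) {
    res$association <- list()
    files <- character(0)
    for (t in tissues) {
      h <- res$harmonized[[t]]
      tr <- res$split[[t]]$train
      mat_tr <- subset_beta(h$beta, cols = tr)
      st_tr <- h$samples[tr, , drop = FALSE]
      res$association[[t]] <- select_age_probes(mat_tr, st_tr,
                                                fdr_threshold = config$fdr,
                                                all_results = TRUE)
      f <- write_tsv(res$association[[t]],
                     file.path(config$out_dir, paste0(t, "_assoc.tsv")))
      files <- c(files, f)
    }
    note("associate", files,
         lapply(res$association, function(a) sum(a$selected)))
  }

  # --- select -----------------------------------------------------------
  if (on_stage("select")) {
    res$stability <- list(); res$markers <- list()
    files <- character(0)
    for (t in tissues) {
      h <- res$harmonized[[t]]
      tr <- res$split[[t]]$train
      sel <- res$association[[t]]
      keep <- sel$probe_id[sel$selected]
      if (!length(keep)) {
        res$stability[[t]] <- NULL
        res$markers[[t]] <- character(0)
        next
      }
      mat_tr <- subset_beta(h$beta, rows = keep, cols = tr)
      st_tr <- h$samples[tr, , drop = FALSE]
      stab <- bootstrap_elastic_net(mat_tr, st_tr,
                                    n_boot = config$n_boot,
                                    freq_threshold = config$freq,
                                    seed = stage_seed(config$seed,
                                                      paste0("select_", t)))
      res$stability[[t]] <- stab
      res$markers[[t]] <- select_markers(stab)
      f <- write_tsv(stab, file.path(config$out_dir, paste0(t, "_markers.tsv")))
      files <- c(files, f)
    }
    note("select", files, lapply(res$markers, length))
  }

  # --- train ------------------------------------------------------------
  if (on_stage("train")) {
    res$clocks <- list()
    for (t in tissues) {
      ids <- res$markers[[t]]
      if (!length(ids)) next
      h <- res$harmonized[[t]]
      tr <- res$split[[t]]$train
      res$clocks[[t]] <- train_clock(subset_beta(h$beta, cols = tr),
                                     h$samples[tr, , drop = FALSE],
                                     marker_ids = ids, tissue = t,
                                     seed = stage_seed(config$seed,
                                                       paste0("train_", t)))
    }
    manifest$stages[["train"]] <- list(
      files = list(),
      rows = lapply(res$clocks, function(m) length(m$marker_ids)))
  }

  # --- evaluate ---------------------------------------------------------
  if (on_stage("evaluate")) {
    res$metrics <- list()
    rows <- list()
    for (t in names(res$clocks)) {
      h <- res$harmonized[[t]]
      te <- res$split[[t]]$test
      if (!length(te)) next
      pred <- predict_age(res$clocks[[t]], subset_beta(h$beta, cols = te))
      obs <- h$samples$age[te]
      res$metrics[[t]] <- evaluate_predictions(pred, obs)
      rows[[t]] <- res$metrics[[t]]$n
    }
    mt <- do.call(rbind, lapply(names(res$metrics), function(t) {
      m <- res$metrics[[t]]
      data.frame(tissue = t, n = m$n, rmse = m$rmse, mad = m$mad,
                 pearson_r = m$pearson_r, mape = m$mape, theil_u = m$theil_u)
    }))
    f <- write_tsv(mt, file.path(config$out_dir, "metrics.tsv"))
    note("evaluate", f, rows)
  }

  # --- characterize -----------------------------------------------------
  if (on_stage("characterize")) {
    marker_lists <- res$markers[vapply(res$markers, length, 1L) > 0]
    if (length(marker_lists) >= 2) {
      catalog <- classify_markers(marker_lists)
      raw_mats <- lapply(res$panel$beta[names(marker_lists)], function(m)
        impute_missing(m))
      dirs <- catalog_directions(catalog, raw_mats,
                                 res$panel$samples[names(marker_lists)])
      ratio <- positive_ratio_by_occurrence(dirs)
      common <- catalog$markers$probe_id[catalog$markers$group == "common"]
      specific <- catalog$markers$probe_id[catalog$markers$group == "specific"]
      ann <- res$panel$annotation
      enr <- cons <- NULL
      if (length(common) >= 2 && length(specific) >= 2) {
        enr <- location_enrichment(common, specific, ann,
                                   field = "island_relation",
                                   levels = c("island", "shore"))
        cons <- conservation_compare(common, specific, ann)
      }
      bg <- background_location_comparison(catalog$markers$probe_id, ann,
                                           field = "gene_structure")
      yo <- lapply(names(marker_lists), function(t)
        young_old_contrast(raw_mats[[t]], res$panel$samples[[t]],
                           marker_lists[[t]], k = config$k_young_old))
      names(yo) <- names(marker_lists)
      top <- catalog$markers$probe_id[order(-catalog$markers$occurrence)][1]
      slopes <- marker_slope_by_tissue(top, raw_mats,
                                       res$panel$samples[names(marker_lists)])
      res$characterization <- list(catalog = catalog, directions = dirs,
                                   positive_ratio = ratio,
                                   island_enrichment = enr,
                                   background_enrichment = bg,
                                   conservation = cons,
                                   young_old = yo,
                                   top_marker = top,
                                   top_marker_slopes = slopes)
      f1 <- write_tsv(dirs, file.path(config$out_dir, "marker_catalog.tsv"))
      f2 <- write_tsv(ratio, file.path(config$out_dir, "positive_ratio.tsv"))
      f3 <- write_tsv(slopes, file.path(config$out_dir, "top_marker_slopes.tsv"))
      note("characterize", c(f1, f2, f3),
           list(common = length(common), specific = length(specific)))
    }
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
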