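# Tissue-common vs tissue-specific marker characterization: occurrence
# counts across tissue models, positive/negative ageCG directions,
# island/shore and gene-structure enrichment (Fisher's exact test),
# conservation-score comparison (two-sample Kolmogorov-Smirnov), young/old
# methylation contrast, and per-tissue slopes of a single marker.

#' Partition markers into tissue-common and tissue-specific groups
#'
#' Counts, for every distinct marker, the number of tissue models it
#' appears in. Markers used by two or more tissue models form the
#' tissue-common group; markers used by exactly one model form the
#' tissue-specific group (set `min_common = 3` for the stricter
#' more-than-two reading, which leaves occurrence-2 markers specific).
#'
#' @param per_tissue_markers named list of character vectors, one marker
#'   list per tissue model (at least two).
#' @param min_common smallest occurrence counted as tissue-common (2).
#' @return `marker_catalog`: list with `markers` (data.frame: probe_id,
#'   occurrence, group), `histogram` (occurrence level -> marker count)
#'   and `per_tissue` (the input lists).
#' @export
classify_markers <- function(per_tissue_markers, min_common = 2) {
  if (length(per_tissue_markers) < 2)
    stop("need marker lists from at least two tissue models")
  per_tissue_markers <- lapply(per_tissue_markers, unique)
  all_ids <- sort(unique(unlist(per_tissue_markers)))
  if (!length(all_ids)) stop("empty marker union")
  occ <- rowSums(vapply(per_tissue_markers, function(m) all_ids %in% m,
                        logical(length(all_ids))))
  markers <- data.frame(
    probe_id = all_ids,
    occurrence = as.integer(occ),
    group = ifelse(occ >= min_common, "common", "specific"),
    stringsAsFactors = FALSE)
  hist <- table(factor(markers$occurrence,
                       levels = seq_len(length(per_tissue_markers))))
  structure(list(markers = markers, histogram = hist,
                 per_tissue = per_tissue_markers),
            class = "marker_catalog")
}

#' Assign positive/negative ageCG directions
#'
#' A marker is a positive ageCG when its methylation increases with age
#' (positive Pearson correlation between raw beta values and age) and a
#' negative ageCG when it decreases. Exact zero correlation or a constant
#' marker is flagged `ambiguous`.
#'
#' @param mat [beta_matrix] (raw beta values of the training tissue).
#' @param samples sample table paired with `mat`.
#' @param marker_ids probes to assign directions to.
#' @return data.frame: probe_id, correlation, direction in
#'   \{positive, negative, ambiguous\}.
#' @export
age_direction <- function(mat, samples, marker_ids) {
  absent <- setdiff(marker_ids, probe_ids(mat))
  if (length(absent))
    stop("markers absent from matrix: ", paste(absent, collapse = ", "))
  samples <- validate_sample_table(samples, mat)
  if (nrow(samples) < 3) stop("need at least 3 samples")
  v <- unclass(mat)[marker_ids, , drop = FALSE]
  cc <- suppressWarnings(as.vector(stats::cor(t(v), samples$age,
                                              use = "pairwise.complete.obs")))
  dir <- ifelse(is.na(cc) | cc == 0, "ambiguous",
                ifelse(cc > 0, "positive", "negative"))
  data.frame(probe_id = marker_ids, correlation = cc, direction = dir,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Direction of a common marker by per-tissue majority vote
#'
#' For markers appearing in several tissue models the direction is computed
#' per tissue where selected and the majority sign reported; exact ties are
#' `ambiguous`.
#'
#' @param catalog a [classify_markers()] result.
#' @param mats,sample_tables named lists (by tissue) of matrices and sample
#'   tables covering every catalog tissue.
#' @return data.frame: probe_id, occurrence, group, direction.
#' @export
catalog_directions <- function(catalog, mats, sample_tables) {
  per_t <- catalog$per_tissue
  votes <- list()
  for (t in names(per_t)) {
    ids <- intersect(per_t[[t]], probe_ids(mats[[t]]))
    if (!length(ids)) next
    d <- age_direction(mats[[t]], sample_tables[[t]], ids)
    votes[[t]] <- d
  }
  all <- do.call(rbind, votes)
  agg <- function(dirs) {
    npos <- sum(dirs == "positive"); nneg <- sum(dirs == "negative")
    if (npos > nneg) "positive" else if (nneg > npos) "negative" else "ambiguous"
  }
  dir <- tapply(all$direction, all$probe_id, agg)
  out <- catalog$markers
  out$direction <- unname(dir[out$probe_id])
  out$direction[is.na(out$direction)] <- "ambiguous"
  out
}

#' Positive-ageCG fraction by occurrence level
#'
#' For each occurrence level k (number of tissue models sharing a marker),
#' the fraction of positive ageCGs among markers with occurrence k and an
#' unambiguous direction.
#'
#' @param directions data.frame with columns `occurrence` and `direction`,
#'   e.g. from [catalog_directions()].
#' @return data.frame: occurrence, n_markers, positive_fraction.
#' @export
positive_ratio_by_occurrence <- function(directions) {
  keep <- directions$direction %in% c("positive", "negative")
  d <- directions[keep, , drop = FALSE]
  levs <- sort(unique(directions$occurrence))
  out <- do.call(rbind, lapply(levs, function(k) {
    dk <- d[d$occurrence == k, , drop = FALSE]
    data.frame(occurrence = k, n_markers = nrow(dk),
               positive_fraction = if (nrow(dk)) mean(dk$direction == "positive")
                                   else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# Two-sided Fisher exact p for a 2x2 table by summing hypergeometric
# probabilities of tables as or more extreme than the observed one, with
# the customary (1 + 1e-7) relative tolerance on "as extreme". Vectorizing
# over the support makes exhaustive verification over all small tables
# cheap; stats::fisher.test is the cross-check in the test suite and the
# engine for r x c tables.
fisher_exact_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pmf <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Location enrichment between two marker groups
#'
#' Builds the group x category contingency table over an annotation field
#' and tests association. 2x2 tables use the exact two-sided Fisher test
#' (hypergeometric enumeration); larger tables use `stats::fisher.test`,
#' falling back to a seeded Monte-Carlo p-value (>= 1e5 draws) when exact
#' network enumeration is infeasible. The method used is recorded.
#'
#' @param groupA_ids,groupB_ids probe ID vectors (e.g. tissue-common vs
#'   tissue-specific markers).
#' @param annotation probe annotation table covering all IDs.
#' @param field annotation column: `"island_relation"` or
#'   `"gene_structure"`.
#' @param levels optional subset/order of categories (e.g.
#'   `c("island", "shore")` for the island-vs-shore contrast).
#' @param mc_draws Monte-Carlo replicates for large r x c tables.
#' @param seed seed for the Monte-Carlo fallback.
#' @return `enrichment_result`: list with `table`, `p_value`, `odds_ratio`
#'   (2x2 only, cross-product ratio), `method`, `field`.
#' @export
location_enrichment <- function(groupA_ids, groupB_ids, annotation,
                                field = c("island_relation", "gene_structure"),
                                levels = NULL, mc_draws = 1e5, seed = 1L) {
  field <- match.arg(field)
  if (!length(groupA_ids) || !length(groupB_ids)) stop("empty marker group")
  ids <- c(groupA_ids, groupB_ids)
  missing_ann <- setdiff(ids, annotation$probe_id)
  if (length(missing_ann))
    stop("probes without annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  cat_of <- function(g) annotation[[field]][match(g, annotation$probe_id)]
  ca <- cat_of(groupA_ids); cb <- cat_of(groupB_ids)
  if (is.null(levels)) levels <- sort(unique(c(ca, cb)))
  ca <- factor(ca, levels = levels); cb <- factor(cb, levels = levels)
  tab <- rbind(groupA = table(ca[!is.na(ca)]), groupB = table(cb[!is.na(cb)]))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) stop("need at least two categories with observations")
  if (ncol(tab) == 2) {
    p <- fisher_exact_2x2(tab)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    method <- "fisher_exact_2x2"
  } else {
    or <- NA_real_
    ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                   error = function(e) NULL)
    if (!is.null(ft)) {
      p <- ft$p.value
      method <- "fisher_exact_rxc"
    } else {
      p <- with_seed(seed,
        stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value)
      method <- sprintf("fisher_montecarlo_B%g", mc_draws)
    }
  }
  structure(list(table = tab, p_value = p, odds_ratio = or,
                 method = method, field = field),
            class = "enrichment_result")
}

#' Compare marker locations against the probe background
#'
#' As [location_enrichment()] with group B set to the full probe universe
#' minus the markers (e.g. aging markers vs all array probes, the
#' gene-body enrichment contrast).
#'
#' @inheritParams location_enrichment
#' @param marker_ids the marker set of interest.
#' @return `enrichment_result`.
#' @export
background_location_comparison <- function(marker_ids, annotation,
                                           field = c("island_relation",
                                                     "gene_structure"),
                                           levels = NULL, mc_draws = 1e5,
                                           seed = 1L) {
  if (!length(marker_ids)) stop("empty marker set")
  background <- setdiff(annotation$probe_id, marker_ids)
  if (!length(background)) stop("markers exhaust the probe universe")
  location_enrichment(marker_ids, background, annotation, field = field,
                      levels = levels, mc_draws = mc_draws, seed = seed)
}

#' Compare conservation scores between marker groups
#'
#' Two-sample Kolmogorov-Smirnov test on the per-region mean conservation
#' scores of the two groups; D is the supremum distance between the two
#' empirical CDFs, p is asymptotic.
#'
#' @param groupA_ids,groupB_ids probe ID vectors (each of length >= 2).
#' @param annotation probe annotation with `mean_conservation`.
#' @return list: ks_statistic, p_value, n_a, n_b, scores_a, scores_b.
#' @export
conservation_compare <- function(groupA_ids, groupB_ids, annotation) {
  if (length(groupA_ids) < 2 || length(groupB_ids) < 2)
    stop("each group needs at least 2 probes")
  missing_ann <- setdiff(c(groupA_ids, groupB_ids), annotation$probe_id)
  if (length(missing_ann))
    stop("probes without annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  sa <- annotation$mean_conservation[match(groupA_ids, annotation$probe_id)]
  sb <- annotation$mean_conservation[match(groupB_ids, annotation$probe_id)]
  kt <- suppressWarnings(stats::ks.test(sa, sb, exact = FALSE))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(sa), n_b = length(sb), scores_a = sa, scores_b = sb)
}

#' Mean conservation of a genomic region
#'
#' Arithmetic mean of per-base phastCons-style scores over a region.
#'
#' @param per_base_scores numeric vector of per-base scores in \[0, 1\].
#' @return the mean score.
#' @export
mean_region_conservation <- function(per_base_scores) {
  if (!length(per_base_scores)) stop("empty region")
  if (any(per_base_scores < 0 | per_base_scores > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  mean(per_base_scores)
}

#' Methylation contrast between the oldest and youngest samples
#'
#' Selects the k oldest and k youngest samples (age ties at the boundary
#' broken by sample ID for determinism) and reports the mean beta
#' difference (old - young) per marker and overall, together with the age
#' gap between group means. The gap is flagged when it is not greater than
#' 40 years, the regime in which the contrast is considered informative.
#'
#' @param mat [beta_matrix] (no missing values among the markers used).
#' @param samples sample table paired with `mat`.
#' @param marker_ids probes to contrast.
#' @param k samples per extreme group (5 by default; `2k <= n`).
#' @return list: age_gap_years, gap_gt_40, per_marker (data.frame),
#'   overall_difference.
#' @export
young_old_contrast <- function(mat, samples, marker_ids, k = 5) {
  samples <- validate_sample_table(samples, mat)
  n <- nrow(samples)
  if (2 * k > n) stop("need at least 2k samples (k = ", k, ", n = ", n, ")")
  absent <- setdiff(marker_ids, probe_ids(mat))
  if (length(absent))
    stop("markers absent from matrix: ", paste(absent, collapse = ", "))
  ord <- order(samples$age, samples$sample_id)
  young <- samples$sample_id[ord[seq_len(k)]]
  old <- samples$sample_id[ord[n + 1 - seq_len(k)]]
  v <- unclass(mat)[marker_ids, , drop = FALSE]
  d_young <- rowMeans(v[, young, drop = FALSE], na.rm = TRUE)
  d_old <- rowMeans(v[, old, drop = FALSE], na.rm = TRUE)
  gap <- mean(samples$age[match(old, samples$sample_id)]) -
         mean(samples$age[match(young, samples$sample_id)])
  per_marker <- data.frame(probe_id = marker_ids,
                           mean_young = unname(d_young),
                           mean_old = unname(d_old),
                           difference = unname(d_old - d_young),
                           stringsAsFactors = FALSE)
  list(age_gap_years = gap, gap_gt_40 = gap > 40,
       per_marker = per_marker,
       overall_difference = mean(per_marker$difference))
}

#' Per-tissue slope of a single marker
#'
#' OLS slope (with standard error) of one probe's beta values on age,
#' fitted separately in every tissue; quantifies how fast the marker's
#' methylation drifts with age in each tissue.
#'
#' @param probe_id the marker.
#' @param mats named list of per-tissue [beta_matrix] objects.
#' @param sample_tables parallel named list of sample tables.
#' @return data.frame: tissue, slope (beta-units/year), std_error, n.
#' @export
marker_slope_by_tissue <- function(probe_id, mats, sample_tables) {
  out <- lapply(names(mats), function(t) {
    mat <- mats[[t]]
    if (!probe_id %in% probe_ids(mat))
      stop("probe ", probe_id, " missing from tissue ", t)
    s <- validate_sample_table(sample_tables[[t]], mat)
    y <- as.numeric(unclass(mat)[probe_id, ])
    keep <- !is.na(y)
    y <- y[keep]; age <- s$age[keep]
    n <- length(y)
    if (n < 3) stop("need at least 3 observed samples in tissue ", t)
    xc <- age - mean(age)
    slope <- sum(xc * y) / sum(xc^2)
    resid <- y - mean(y) - slope * xc
    se <- sqrt(sum(resid^2) / (n - 2) / sum(xc^2))
    data.frame(tissue = t, slope = slope, std_error = se, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
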