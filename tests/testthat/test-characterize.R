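test_that("markers partition into common and specific by occurrence", {
  lists <- list(t1 = c("a", "b", "c"), t2 = c("b", "c", "d"),
                t3 = c("c", "e"), t4 = c("c"), t5 = c("c"),
                t6 = c("c"), t7 = c("c"), t8 = c("c"), t9 = c("c"))
  cat9 <- classify_markers(lists)
  mk <- cat9$markers
  # a marker in all nine lists is common with occurrence 9
  expect_equal(mk$occurrence[mk$probe_id == "c"], 9L)
  expect_equal(mk$group[mk$probe_id == "c"], "common")
  # exactly one list -> specific; two lists -> common
  expect_equal(mk$group[mk$probe_id == "a"], "specific")
  expect_equal(mk$group[mk$probe_id == "b"], "common")
  # literal more-than-two reading available behind the flag
  strict <- classify_markers(lists, min_common = 3)$markers
  expect_equal(strict$group[strict$probe_id == "b"], "specific")
  # partition completeness: every marker in exactly one group, histogram
  # reconciles with the counts
  expect_setequal(mk$group, c("common", "specific"))
  expect_equal(sum(mk$group == "common") + sum(mk$group == "specific"),
               nrow(mk))
  expect_equal(sum(cat9$histogram), nrow(mk))
  expect_equal(unname(cat9$histogram[["2"]]), sum(mk$occurrence == 2))
  expect_error(classify_markers(list(t1 = "a")), "two tissue")
})

test_that("age directions recover planted signs; degenerate markers flagged", {
  cfg <- one_tissue_cfg(n = 150, n_probes = 120, n_markers = 60, seed = 14)
  p <- generate_panel(cfg)
  ids <- planted_ids(p)
  d <- age_direction(p$beta[[1]], p$samples[[1]], ids)
  truth_dir <- ifelse(
    p$truth$probes$direction[match(ids, p$truth$probes$probe_id)] > 0,
    "positive", "negative")
  expect_gte(mean(d$direction == truth_dir), 0.99)
  # constant marker is ambiguous, not an error
  v <- matrix(c(rep(0.5, 10), runif(10)), 2, 10, byrow = TRUE)
  m <- bm(v)
  dc <- age_direction(m, stab(m, seq(20, 65, length.out = 10)),
                      probe_ids(m))
  expect_equal(dc$direction[1], "ambiguous")
})

test_that("positive-ageCG ratios track planted fractions by occurrence", {
  dirs <- data.frame(occurrence = c(1, 1, 1, 2, 2, 3),
                     direction = c("positive", "negative", "positive",
                                   "positive", "positive", "positive"))
  tab <- positive_ratio_by_occurrence(dirs)
  expect_equal(tab$positive_fraction, c(2 / 3, 1, 1))
  # planted fractions recovered from a generated panel (two groups)
  cfg <- sim_config(n_tissues = 2, n_samples_per_tissue = 100, n_probes = 600,
                    n_common_markers = 250,
                    n_specific_markers_per_tissue = 125,
                    frac_positive_common = 0.8, frac_positive_specific = 0.4,
                    missing_rate = 0, platform_split = 0, seed = 25)
  p <- generate_panel(cfg)
  tr <- p$truth$probes
  frac <- function(lab) {
    ids <- tr$probe_id[tr$label == lab]
    mean(tr$direction[match(ids, tr$probe_id)] > 0)
  }
  expect_lt(abs(frac("common") - 0.8), 0.05)
  expect_lt(abs(frac("specific") - 0.4), 0.05)
  # and the computed directions agree with the planted ones per group
  catalogish <- rbind(
    data.frame(probe_id = tr$probe_id[tr$label == "common"], occurrence = 2),
    data.frame(probe_id = tr$probe_id[tr$label == "specific"], occurrence = 1))
  d1 <- age_direction(p$beta[[1]], p$samples[[1]], catalogish$probe_id)
  catalogish$direction <- d1$direction
  est <- positive_ratio_by_occurrence(catalogish)
  expect_lt(abs(est$positive_fraction[est$occurrence == 2] - 0.8), 0.05)
  # specific markers of tissue 2 are null in tissue 1, so restrict to its own
  own <- tr$probe_id[tr$label == "specific" & tr$tissue == "tissue1"]
  d_own <- age_direction(p$beta[[1]], p$samples[[1]], own)
  expect_lt(abs(mean(d_own$direction == "positive") - 0.4), 0.1)
})

test_that("2x2 enrichment matches the hypergeometric enumeration oracle", {
  ann <- data.frame(probe_id = sprintf("p%02d", 1:30),
                    gene_structure = "exon",
                    island_relation = rep(c("island", "shore"), 15),
                    chrom = "chr1", start = 1:30, end = 2:31,
                    mean_conservation = 0.5)
  # equal proportions ([[5,5],[10,10]]) -> no association
  ga <- c(sprintf("p%02d", c(1, 3, 5, 7, 9)), sprintf("p%02d", c(2, 4, 6, 8, 10)))
  gb <- setdiff(ann$probe_id, ga)
  r <- location_enrichment(ga, gb, ann, "island_relation")
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)
  # [[8,2],[3,7]] against the brute-force oracle
  tab <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  expect_equal(tissueclock:::fisher_exact_2x2(tab), fisher_oracle(tab))
  expect_equal(tissueclock:::fisher_exact_2x2(tab),
               fisher.test(tab)$p.value)
  # random tables: implementation == oracle == stats::fisher.test
  set.seed(15)
  for (i in 1:100) {
    t2 <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(tissueclock:::fisher_exact_2x2(t2), fisher_oracle(t2))
    expect_equal(tissueclock:::fisher_exact_2x2(t2),
                 fisher.test(t2)$p.value, tolerance = 1e-10)
  }
  expect_error(location_enrichment(character(0), gb, ann), "empty")
  expect_error(location_enrichment(c(ga, "pXX"), gb, ann), "pXX")
})

test_that("r x c tables fall through to the exact network test", {
  set.seed(33)
  ann <- data.frame(probe_id = sprintf("p%03d", 1:60),
                    gene_structure = sample(c("exon", "gene body", "TSS"),
                                            60, TRUE),
                    island_relation = "island", chrom = "chr1",
                    start = 1:60, end = 2:61, mean_conservation = 0.5)
  ga <- ann$probe_id[1:25]; gb <- ann$probe_id[26:60]
  r <- location_enrichment(ga, gb, ann, "gene_structure")
  expect_equal(r$method, "fisher_exact_rxc")
  tab <- r$table
  expect_equal(r$p_value, fisher.test(tab)$p.value)
})

test_that("planted island enrichment is detected between marker groups", {
  cfg <- sim_config(n_tissues = 1, n_samples_per_tissue = 5, n_probes = 300,
                    n_common_markers = 80, n_specific_markers_per_tissue = 80,
                    island_prob_common = 0.7, island_prob_specific = 0.3,
                    missing_rate = 0, platform_split = 0, seed = 51)
  p <- generate_panel(cfg)
  tr <- p$truth$probes
  r <- location_enrichment(tr$probe_id[tr$label == "common"],
                           tr$probe_id[tr$label == "specific"],
                           p$annotation, "island_relation",
                           levels = c("island", "shore"))
  expect_lt(r$p_value, 0.01)
  expect_gt(r$odds_ratio, 1)
})

test_that("background comparison is calibrated under a null draw", {
  set.seed(61)
  ann <- data.frame(probe_id = sprintf("p%04d", 1:2000),
                    gene_structure = sample(c("exon", "gene body", "intergenic"),
                                            2000, TRUE, c(0.2, 0.4, 0.4)),
                    island_relation = "island", chrom = "chr1",
                    start = 1:2000, end = 2:2001, mean_conservation = 0.5)
  ps <- replicate(40, {
    mk <- sample(ann$probe_id, 100)
    background_location_comparison(mk, ann, "gene_structure",
                                   mc_draws = 2e4)$p_value
  })
  # roughly uniform p under no enrichment: no pile-up at small values
  expect_gt(mean(ps > 0.05), 0.75)
  # markers all from one category -> strong enrichment signal
  mk1 <- ann$probe_id[ann$gene_structure == "exon"][1:60]
  expect_lt(background_location_comparison(mk1, ann,
                                           "gene_structure")$p_value, 1e-6)
  expect_error(background_location_comparison(character(0), ann), "empty")
})

test_that("conservation comparison equals the ECDF supremum oracle", {
  ann <- data.frame(probe_id = sprintf("p%02d", 1:6),
                    gene_structure = "exon", island_relation = "island",
                    chrom = "chr1", start = 1:6, end = 2:7,
                    mean_conservation = c(0.1, 0.2, 0.3, 0.2, 0.4, 0.6))
  r <- conservation_compare(c("p01", "p02", "p03"), c("p04", "p05", "p06"), ann)
  expect_equal(r$ks_statistic,
               ks_oracle(c(0.1, 0.2, 0.3), c(0.2, 0.4, 0.6)))
  # identical lists -> D = 0, p = 1
  r0 <- conservation_compare(c("p01", "p02", "p03"), c("p01", "p02", "p03"), ann)
  expect_equal(r0$ks_statistic, 0)
  expect_equal(r0$p_value, 1)
  # disjoint supports -> D = 1
  ann2 <- ann
  ann2$mean_conservation <- c(0.1, 0.15, 0.2, 0.7, 0.8, 0.9)
  r1 <- conservation_compare(c("p01", "p02", "p03"), c("p04", "p05", "p06"), ann2)
  expect_equal(r1$ks_statistic, 1)
  # random pairs: D always equals the brute-force supremum
  set.seed(44)
  for (i in 1:30) {
    na <- sample(3:50, 1); nb <- sample(3:50, 1)
    ann3 <- data.frame(probe_id = sprintf("q%03d", seq_len(na + nb)),
                       gene_structure = "exon", island_relation = "island",
                       chrom = "chr1", start = 1, end = 2,
                       mean_conservation = round(runif(na + nb), 2))
    r3 <- conservation_compare(ann3$probe_id[1:na],
                               ann3$probe_id[(na + 1):(na + nb)], ann3)
    expect_equal(r3$ks_statistic,
                 ks_oracle(ann3$mean_conservation[1:na],
                           ann3$mean_conservation[(na + 1):(na + nb)]))
  }
  expect_error(conservation_compare("p01", c("p02", "p03"), ann), "at least 2")
})

test_that("region conservation is a plain arithmetic mean", {
  expect_equal(mean_region_conservation(rep(0.5, 7)), 0.5)
  expect_equal(mean_region_conservation(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(mean_region_conservation(c(0.3, 0.1, 0.2)), 0.2)
  expect_error(mean_region_conservation(numeric(0)), "empty")
  expect_error(mean_region_conservation(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("young/old contrast finds planted hypermethylation with age", {
  cfg <- one_tissue_cfg(n = 40, n_probes = 60, n_markers = 20, seed = 28,
                        frac_positive_specific = 1)   # all positive markers
  p <- generate_panel(cfg)
  yo <- young_old_contrast(p$beta[[1]], p$samples[[1]], planted_ids(p), k = 5)
  expect_gt(yo$overall_difference, 0)
  expect_true(is.logical(yo$gap_gt_40))
  # null markers hover near zero difference
  nulls <- p$truth$probes$probe_id[p$truth$probes$label == "null"]
  yo0 <- young_old_contrast(p$beta[[1]], p$samples[[1]], nulls, k = 5)
  expect_lt(abs(yo0$overall_difference),
            4 * cfg$noise_sd / sqrt(5 * length(nulls)) + 0.01)
  # boundary k = n/2 accepted, beyond rejected
  expect_silent(young_old_contrast(p$beta[[1]], p$samples[[1]],
                                   planted_ids(p), k = 20))
  expect_error(young_old_contrast(p$beta[[1]], p$samples[[1]],
                                  planted_ids(p), k = 21), "2k")
})

test_that("per-tissue slopes of one marker are recovered within 3 SE", {
  set.seed(66)
  n <- 150
  slopes_true <- c(t1 = 0.001, t2 = 0.003, t3 = 0.005, t4 = 0)
  mats <- list(); tabs <- list()
  for (t in names(slopes_true)) {
    age <- runif(n, 20, 90)
    v <- matrix(pmin(pmax(0.2 + slopes_true[[t]] * age + rnorm(n, 0, 0.02),
                          0), 1), 1, n,
                dimnames = list("cgX", sprintf("%s_s%03d", t, 1:n)))
    mats[[t]] <- beta_matrix(v)
    tabs[[t]] <- data.frame(sample_id = colnames(v), age = age, tissue = t)
  }
  res <- marker_slope_by_tissue("cgX", mats, tabs)
  expect_true(all(abs(res$slope - slopes_true) <= 3 * res$std_error))
  # identical datasets give identical slopes
  res2 <- marker_slope_by_tissue("cgX", mats[c(1, 1)], tabs[c(1, 1)])
  expect_equal(res2$slope[1], res2$slope[2])
  expect_error(marker_slope_by_tissue("cgMISSING", mats, tabs), "cgMISSING")
})
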