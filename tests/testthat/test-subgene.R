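mk_ps_results <- function(...) {
  tibble::tibble(...)
}

test_that("region representatives take the smallest p with Bonferroni", {
  one <- mk_ps_results(
    probeset_id = "ps1", gene_id = "g1", region_kind = "five_utr",
    p = 0.03, delta = 1
  )
  rep1 <- select_region_representatives(one)
  expect_equal(rep1$p_adj, 0.03)
  three <- mk_ps_results(
    probeset_id = c("a", "b", "c"), gene_id = "g1", region_kind = "exon",
    p = c(0.01, 0.2, 0.5), delta = c(1, 1, -1)
  )
  rep3 <- select_region_representatives(three)
  expect_equal(rep3$probeset_id, "a")
  expect_equal(rep3$p_adj, 0.03)
  two <- mk_ps_results(
    probeset_id = c("a", "b"), gene_id = "g1", region_kind = "exon",
    p = c(0.4, 0.6), delta = c(1, 1)
  )
  expect_equal(select_region_representatives(two)$p_adj, 0.8)
  # ties break lexicographically
  tie <- mk_ps_results(
    probeset_id = c("zz", "aa"), gene_id = "g1", region_kind = "exon",
    p = c(0.01, 0.01), delta = c(1, 1)
  )
  expect_equal(select_region_representatives(tie)$probeset_id, "aa")
  expect_error(select_region_representatives(one[0, ]), "empty")
})

test_that("alternative-event rule fires on the right arms", {
  gene <- tibble::tibble(feature_id = "g1", p = 0.5, delta = -0.3)
  rep_opp <- mk_ps_results(
    probeset_id = "ps", gene_id = "g1", region_kind = "five_utr",
    p = 0.005, delta = 0.4, n_probesets = 2, p_adj = 0.01
  )
  ev <- detect_alternative_events(rep_opp, gene)
  expect_true(ev$event)
  expect_equal(ev$event_reason, "opposite_direction")
  # stronger-than-gene arm: same direction, ratio 500 >= 10
  gene2 <- tibble::tibble(feature_id = "g1", p = 0.5, delta = 0.3)
  rep_str <- rep_opp; rep_str$p <- 0.001; rep_str$p_adj <- 0.01
  ev2 <- detect_alternative_events(rep_str, gene2)
  expect_true(ev2$event)
  expect_equal(ev2$event_reason, "stronger_than_gene")
  # neither arm: same direction and similar p
  gene3 <- tibble::tibble(feature_id = "g1", p = 0.02, delta = 0.3)
  rep_no <- rep_opp; rep_no$p <- 0.01; rep_no$p_adj <- 0.01; rep_no$delta <- 0.4
  ev3 <- detect_alternative_events(rep_no, gene3)
  expect_false(ev3$event)
  # missing gene-level result errors
  expect_error(detect_alternative_events(
    rep_opp, tibble::tibble(feature_id = "other", p = 1, delta = 0)),
    "missing gene-level")
  # every called event satisfies p_adj < 0.05; with ratio_k -> Inf and no
  # opposite directions, no events are called
  set.seed(2)
  reps <- mk_ps_results(
    probeset_id = paste0("ps", 1:50), gene_id = paste0("g", 1:50),
    region_kind = "exon", p = runif(50, 1e-4, 1), delta = abs(rnorm(50)),
    n_probesets = 1, p_adj = pmin(1, runif(50, 1e-4, 1))
  )
  reps$p_adj <- reps$p
  genes <- tibble::tibble(feature_id = paste0("g", 1:50),
                          p = runif(50), delta = abs(rnorm(50)))
  evs <- detect_alternative_events(reps, genes)
  expect_true(all(evs$p_adj[evs$event] < 0.05))
  evs_inf <- detect_alternative_events(reps, genes, ratio_k = Inf)
  expect_equal(sum(evs_inf$event), 0L)
})

test_that("alternative events recover planted UTR-only effects", {
  cfg <- generator_config(
    n_genes = 150, frac_alt_event = 0.4, frac_gene_effect = 0.3,
    frac_are = 0, frac_gradient = 0, module_size = 0,
    antisense_fraction = 0, n_background_reference = 0,
    tf_effect_pct = c(), seed = 21
  )
  sim <- simulate_study(cfg)
  ps <- summarize_probesets(sim$intensity, sim$models$probes)
  ge <- summarize_gene_level(ps, sim$models$probes)
  d <- sim$design
  ids <- d$sample_id[d$tissue == "muscle"]
  labs <- d$disease[d$tissue == "muscle"]
  sam_ps <- sam_test(fx_log2(ps)[, c("probeset_id", ids)], labs, group_a = "RC",
                     n_perm = 200, seed = 1)
  sam_ge <- sam_test(fx_log2(ge)[, c("gene_id", ids)], labs, group_a = "RC",
                     n_perm = 200, seed = 2)
  ps_map <- dplyr::distinct(sim$models$probes, probeset_id, gene_id, region_kind)
  reps <- select_region_representatives(
    dplyr::inner_join(dplyr::rename(sam_ps, probeset_id = feature_id),
                      ps_map, by = "probeset_id")
  )
  ev <- detect_alternative_events(reps, sam_ge)
  tg <- sim$truth_genes
  alt <- tg$gene_id[tg$effect_class == "alt_event"]
  uniform <- tg$gene_id[tg$effect_class == "gene_effect"]
  called <- unique(ev$gene_id[ev$event])
  expect_gte(mean(alt %in% called), 0.8)           # recall on UTR-only effects
  expect_lte(mean(uniform %in% called), 0.05)      # false events on uniform genes
})

test_that("region change summary counts are consistent and filtered", {
  flat <- mk_ps_results(
    probeset_id = paste0("ps", 1:6), gene_id = paste0("g", 1:6),
    region_kind = rep(c("five_utr", "exon", "antisense"), 2),
    p = 1, delta = 0
  )
  s <- summarize_region_changes(flat)
  expect_true(all(s$n_up == 0 & s$n_down == 0))
  expect_true(all(s$n_up + s$n_down <= s$n_analyzed))
  # non-effective antisense probesets are never counted
  eff <- tibble::tibble(probeset_id = paste0("ps", 1:6),
                        effective = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                        background_z = 0)
  s2 <- summarize_region_changes(flat, eff)
  expect_true(!"antisense" %in% s2$region_kind ||
                s2$n_analyzed[s2$region_kind == "antisense"] == 0L)
})

test_that("sense-antisense concordance recovers mirrors and opposite outliers", {
  cfg <- generator_config(
    n_genes = 120, frac_gene_effect = 0.6, inverse_fraction = 0.5,
    frac_are = 0, frac_gradient = 0, frac_alt_event = 0, module_size = 0,
    antisense_fraction = 1, antisense_background_fraction = 0,
    antisense_opposite_fraction = 0.15, antisense_independent_fraction = 0,
    noise_sd = 0.05, tf_effect_pct = c(), seed = 31
  )
  sim <- simulate_study(cfg)
  ps <- summarize_probesets(sim$intensity, sim$models$probes)
  d <- sim$design
  ids <- d$sample_id[d$tissue == "muscle"]
  labs <- d$disease[d$tissue == "muscle"]
  sam_ps <- sam_test(fx_log2(ps)[, c("probeset_id", ids)], labs, group_a = "RC",
                     n_perm = 200, seed = 3)
  base <- tibble::tibble(
    feature_id = ps$probeset_id,
    baseline_log2 = rowMeans(log2(expr_matrix(ps))[, ids[labs == "control"]])
  )
  res <- dplyr::left_join(sam_ps, base, by = "feature_id")
  pm <- dplyr::distinct(sim$models$probes, probeset_id, gene_id, region_kind)
  pairs <- dplyr::inner_join(
    dplyr::select(dplyr::filter(pm, region_kind == "antisense",
                                !grepl(":bgref", probeset_id)),
                  gene_id, anti_id = probeset_id),
    dplyr::select(dplyr::filter(pm, region_kind == "five_utr"),
                  gene_id, sense_id = probeset_id),
    by = "gene_id"
  )
  conc <- sense_antisense_concordance(res, res, pairs)
  # mirror-mode pairs carry the concordance signal
  tg0 <- sim$truth_genes
  mirror_pairs <- pairs[pairs$gene_id %in%
                          tg0$gene_id[tg0$antisense_mode == "mirror"], ]
  conc_m <- sense_antisense_concordance(res, res, mirror_pairs)
  expect_gt(conc_m$delta_r, 0.8)
  expect_gt(conc_m$baseline_r, 0.8)
  # planted opposite-mode genes appear among the outliers
  tg <- sim$truth_genes
  opp <- tg$gene_id[tg$antisense_mode == "opposite" & tg$effect_class == "gene_effect"]
  if (length(opp) >= 3) {
    expect_gte(mean(opp %in% conc$outliers$gene_id), 0.9)
  }
  expect_error(sense_antisense_concordance(res, res, pairs[1:2, ]), "3")
})
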