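test_that("ARE classifier handles forced patterns and the ladder invariant", {
  expect_equal(classify_are("GCGCGC")$are_class, "none")
  expect_equal(classify_are("CCATTTACC")$are_class, "mer5")
  expect_equal(classify_are("TTTTATTTATTTT")$are_class, "mer13")
  # U is accepted as T; N never matches
  expect_equal(classify_are("CCAUUUACC")$are_class, "mer5")
  expect_equal(classify_are("CCANTTACC")$are_class, "none")
  expect_error(classify_are(""), "empty")
  # extending flanking Ws never downgrades the class
  core <- "GATTTAG"
  expect_equal(classify_are(core)$are_class, "mer5")
  for (k in 1:4) {
    seq <- paste0("G", strrep("A", k), "ATTTA", strrep("T", k), "G")
    expect_equal(classify_are(seq)$are_class,
                 c("mer7", "mer9", "mer11", "mer13")[k])
  }
})

test_that("ARE classifier agrees with a regex oracle on random sequences", {
  set.seed(17)
  seqs <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(20:80, 1),
                 replace = TRUE, prob = c(0.35, 0.15, 0.15, 0.35)),
          collapse = "")
  }, character(1))
  got <- vapply(seqs, function(s) classify_are(s)$are_class, character(1))
  want <- vapply(seqs, oracle_are_class, character(1))
  expect_equal(unname(got), unname(want))
})

test_that("ARE group statistics are exact averages and recover planted shifts", {
  ann <- tibble::tibble(gene_id = paste0("g", 1:10),
                        are_class = rep(c("none", "mer5"), each = 5))
  zero <- tibble::tibble(gene_id = paste0("g", 1:10), change_pct = 0)
  res0 <- are_group_change_test(ann, zero)
  expect_equal(res0$mean_change_pct, c(0, 0))
  # conservation: reported means are exact weighted averages of the input
  set.seed(4)
  ch <- tibble::tibble(gene_id = paste0("g", 1:10), change_pct = rnorm(10, 5, 3))
  res <- are_group_change_test(ann, ch)
  expect_equal(res$mean_change_pct[res$are_class == "mer5"],
               mean(ch$change_pct[6:10]))
  expect_warning(
    are_group_change_test(
      tibble::tibble(gene_id = paste0("g", 1:6),
                     are_class = c(rep("none", 5), "mer13")),
      tibble::tibble(gene_id = paste0("g", 1:6), change_pct = rnorm(6))
    ), "skipped")
})

test_that("positional profile recovers a planted gradient and strand symmetry", {
  cfg <- generator_config(
    n_genes = 60, frac_gradient = 1, frac_gene_effect = 0, frac_are = 0,
    frac_alt_event = 0, module_size = 0, antisense_fraction = 0,
    n_background_reference = 0, tf_effect_pct = c(), seed = 23
  )
  sim <- simulate_study(cfg)
  ps <- summarize_probesets(sim$intensity, sim$models$probes)
  prof <- positional_profile(sim$intensity, sim$models, ps,
                             region_kind = "three_utr", tissue = "muscle")
  g <- attr(prof, "gradient")
  expect_lt(abs(g - cfg$gradient_by_tissue[["muscle"]]),
            0.2 * abs(cfg$gradient_by_tissue[["muscle"]]))
  # sign flips with the planted sign in the second tissue
  prof2 <- positional_profile(sim$intensity, sim$models, ps,
                              region_kind = "three_utr", tissue = "fibroblast")
  expect_gt(attr(prof2, "gradient"), 0)
  # strand handling: plus- and minus-strand genes contribute the same
  # gradient (split the genes by strand and compare signs)
  strands <- sim$models$genes$strand
  for (s in c("+", "-")) {
    keep <- sim$models$genes$gene_id[strands == s]
    sub_models <- sim$models
    sub_models$probes <- sub_models$probes[sub_models$probes$gene_id %in% keep, ]
    p_s <- positional_profile(sim$intensity, sub_models, ps,
                              region_kind = "three_utr", tissue = "muscle")
    expect_lt(abs(attr(p_s, "gradient") - cfg$gradient_by_tissue[["muscle"]]),
              0.35 * abs(cfg$gradient_by_tissue[["muscle"]]))
  }
  # flat profile in a no-effect simulation
  cfg0 <- generator_config(n_genes = 60, frac_gradient = 0,
                           frac_gene_effect = 0, frac_are = 0,
                           frac_alt_event = 0, module_size = 0,
                           antisense_fraction = 0, n_background_reference = 0,
                           tf_effect_pct = c(), seed = 29)
  sim0 <- simulate_study(cfg0)
  ps0 <- summarize_probesets(sim0$intensity, sim0$models$probes)
  prof0 <- positional_profile(sim0$intensity, sim0$models, ps0,
                              region_kind = "three_utr", tissue = "muscle")
  expect_lt(abs(attr(prof0, "gradient")), 0.05)
  # a region with no probes is an error
  no_utr5 <- sim0$models
  no_utr5$probes <- no_utr5$probes[no_utr5$probes$region_kind != "five_utr", ]
  expect_error(positional_profile(sim0$intensity, no_utr5, ps0,
                                  region_kind = "five_utr"), "zero probes")
})

test_that("5'-UTR baseline association detects the planted rule and nulls", {
  cfg <- generator_config(
    n_genes = 400, utr5_baseline_rule = TRUE, frac_gene_effect = 0,
    frac_are = 0, frac_gradient = 0, frac_alt_event = 0, module_size = 0,
    antisense_fraction = 0, n_background_reference = 0,
    tf_effect_pct = c(), seed = 37
  )
  sim <- simulate_study(cfg)
  ps <- summarize_probesets(sim$intensity, sim$models$probes)
  ge <- summarize_gene_level(ps, sim$models$probes)
  d <- sim$design
  ctrl <- d$sample_id[d$tissue == "muscle" & d$disease == "control"]
  ids <- d$sample_id[d$tissue == "muscle"]
  labs <- d$disease[d$tissue == "muscle"]
  baseline <- relative_utr_level(ps, ge, sim$models$probes, "five_utr", ctrl)
  lg <- fx_log2(ps)
  m <- expr_matrix(lg[, c("probeset_id", ids)])
  pm <- dplyr::distinct(sim$models$probes, probeset_id, gene_id, region_kind)
  u5 <- pm[pm$region_kind == "five_utr", ]
  delta <- rowMeans(m[u5$probeset_id, labs == "RC"]) -
    rowMeans(m[u5$probeset_id, labs == "control"])
  change <- tibble::tibble(gene_id = u5$gene_id,
                           change_pct = 100 * (2^delta - 1))
  assoc <- baseline_abundance_association(baseline, change)
  expect_lt(assoc$rho, -0.3)
  expect_lt(assoc$p, 0.01)
  # shuffled baselines break the association
  set.seed(1)
  shuffled <- baseline
  shuffled$baseline <- sample(shuffled$baseline)
  null_assoc <- baseline_abundance_association(shuffled, change)
  expect_lt(abs(null_assoc$rho), 0.15)
  expect_error(baseline_abundance_association(
    tibble::tibble(gene_id = change$gene_id, baseline = 1), change),
    "constant")
})

test_that("TOP motif detection follows the pyrimidine-run rule", {
  expect_true(detect_top_motif("CTTTTCAGG"))
  expect_false(detect_top_motif("ATTTTT"))
  expect_true(detect_top_motif("CAACTTTTGG"))   # run starts within window
  expect_false(detect_top_motif("CAAAAAAGGGG"))
  expect_error(detect_top_motif("CTT"), "shorter than 6")
  # vectorized
  expect_equal(detect_top_motif(c("CTTTTCAGG", "GTTTTTTT")), c(TRUE, FALSE))
})
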