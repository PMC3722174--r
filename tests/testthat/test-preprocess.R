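test_that("lowess normalization removes multiplicative array bias", {
  sim <- fx_sim()
  x <- sim$intensity
  # identical arrays: output equals input
  same_vals <- x$values
  for (s in setdiff(names(same_vals), "probe_id")) same_vals[[s]] <- same_vals[[2]]
  same <- exondys:::new_intensity_table(same_vals, x$design)
  out_same <- lowess_normalize(same)
  expect_equal(expr_matrix(out_same$values), expr_matrix(same$values),
               tolerance = 1e-8)
  # one array scaled by 2: after normalization its median log2 ratio to the
  # per-probe median reference is ~0
  biased_vals <- x$values
  biased_vals[[2]] <- biased_vals[[2]] * 2
  biased <- exondys:::new_intensity_table(biased_vals, x$design)
  out <- lowess_normalize(biased)
  m <- log2(expr_matrix(out$values))
  ref <- apply(m, 1, median)
  expect_lt(abs(median(m[, 1] - ref)), 0.01)
  # idempotence: a second pass retains only the O(sigma/sqrt(window)) noise
  # the smoother cannot remove, which falls under 1e-3 log2 for a typical
  # probe at realistic probe counts and noise
  sim_big <- simulate_study(generator_config(
    n_genes = 300, noise_sd = 0.05, module_size = 0, seed = 8
  ))
  once <- lowess_normalize(sim_big$intensity)
  twice <- lowess_normalize(once)
  change <- abs(log2(expr_matrix(twice$values)) - log2(expr_matrix(once$values)))
  expect_lt(median(change), 1e-3)
  # quadratic bias on the log scale is mostly removed
  lg <- log2(expr_matrix(x$values))
  refv <- apply(lg, 1, median)
  curved <- lg
  curved[, 1] <- curved[, 1] + 0.02 * (refv - mean(refv))^2
  cv <- exondys:::new_intensity_table(
    expr_tibble(2^curved, id_col = "probe_id"), x$design)
  outc <- lowess_normalize(cv)
  resid <- log2(expr_matrix(outc$values))[, 1] -
    apply(log2(expr_matrix(outc$values)), 1, median)
  bias0 <- 0.02 * (refv - mean(refv))^2
  fit <- lowess(refv, resid, f = 0.3)
  expect_lt(max(abs(fit$y)), 0.1 * max(abs(bias0 - mean(bias0))) + 0.02)
  expect_error(lowess_normalize(exondys:::new_intensity_table(
    x$values[, 1:2], x$design[1, ])), "2 samples")
})

test_that("Li-Wong recovers exact rank-1 structure and degenerate cases", {
  fit <- liwong_summarize(fx_rank1(theta = c(1, 2, 4)))
  expect_equal(cor(fit$theta, c(1, 2, 4)), 1, tolerance = 1e-9)
  expect_equal(sum(fit$phi^2), 4, tolerance = 1e-9)  # sum(phi^2) = n_probes
  # single probe: theta equals the probe row, phi = 1
  single <- matrix(c(3, 5, 7), nrow = 1,
                   dimnames = list("p1", paste0("s", 1:3)))
  f1 <- liwong_summarize(single)
  expect_equal(as.numeric(f1$theta), c(3, 5, 7))
  expect_equal(f1$phi, 1)
  expect_error(liwong_summarize(matrix(0, 2, 3)), "all-zero")
})

test_that("Li-Wong flags a corrupted cell and recovery survives it", {
  y <- fx_rank1(theta = c(1, 2, 4, 8, 3, 6), phi = c(0.5, 1, 1.5, 2))
  y[2, 3] <- y[2, 3] * 10
  fit <- liwong_summarize(y)
  expect_true(fit$outlier_cells[2, 3])
  # compare against a fit computed with the corrupted cell's probe removed
  ref <- liwong_summarize(y[-2, ])
  expect_gt(cor(fit$theta, ref$theta), 0.999)
  expect_gt(cor(fit$theta, c(1, 2, 4, 8, 3, 6)), 0.999)
})

test_that("Li-Wong objective is non-increasing and theta scales with input", {
  set.seed(1)
  y <- fx_rank1(theta = runif(6, 1, 10), phi = runif(5, 0.5, 2)) *
    matrix(exp(rnorm(30, 0, 0.1)), 5, 6)
  fit <- liwong_summarize(y)
  expect_true(all(diff(fit$objective) <= 1e-8))
  fit2 <- liwong_summarize(y * 7)
  expect_equal(fit2$theta, fit$theta * 7, tolerance = 1e-6)
  expect_equal(fit2$phi, fit$phi, tolerance = 1e-6)
})

test_that("gene-level summarization matches planted fold changes", {
  fx <- fx_expr()
  sim <- fx$sim
  # gene with one (sense) probeset: gene expression equals probeset expression
  ps_id <- sim$models$probes$probeset_id[sim$models$probes$region_kind == "exon"][1]
  one_ps <- fx$ps[fx$ps$probeset_id == ps_id, ]
  gm_one <- sim$models$probes[sim$models$probes$probeset_id == ps_id, ]
  ge_one <- summarize_gene_level(one_ps, gm_one)
  expect_equal(as.numeric(expr_matrix(ge_one)), as.numeric(expr_matrix(one_ps)),
               tolerance = 1e-9)
  # planted gene-level log2fc recovered within 15% at sigma = 0.1
  d <- sim$design
  ids <- fx_tissue_cols(d, "muscle")
  labs <- d$disease[d$tissue == "muscle"]
  m <- log2(expr_matrix(fx$ge))[, ids]
  delta <- rowMeans(m[, labs == "RC"]) - rowMeans(m[, labs == "control"])
  tg <- sim$truth_genes
  gi <- tg[tg$effect_class == "gene_effect", ]
  planted <- gi$lfc_muscle + gi$tf_lfc
  rel_err <- abs(delta[gi$gene_id] - planted) / abs(planted)
  expect_lt(mean(rel_err), 0.15)
})

test_that("effective-probeset rule separates signal from background", {
  fx <- fx_expr()
  sim <- fx$sim
  bg_ids <- sim$truth_probesets$probeset_id[sim$truth_probesets$is_background_reference]
  eff <- detect_effective_probesets(fx$ps, bg_ids)
  tr <- dplyr::inner_join(eff, sim$truth_probesets, by = "probeset_id")
  anti <- tr[!tr$is_background_reference & tr$region_kind == "antisense", ]
  expect_gte(mean(anti$effective == anti$effective_true), 0.95)
  # background-reference probesets sit at background: at most the rare
  # high-affinity one clears its own group's threshold
  expect_lte(mean(tr$effective[tr$is_background_reference]), 0.1)
  # a probeset far above background is effective
  expect_true(all(tr$effective[tr$region_kind == "exon"]))
  expect_error(detect_effective_probesets(fx$ps, character(0)), "empty background")
})

test_that("PCA separates planted groups and reports valid variance shares", {
  fx <- fx_expr()
  d <- fx$sim$design
  ids <- fx_tissue_cols(d, "muscle")
  pc <- pca_embed(fx$ge[, c("gene_id", ids)])
  ve <- attr(pc, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-9)
  # disease groups separate on the leading components
  labs <- d$disease[match(pc$sample_id, d$sample_id)]
  sep <- vapply(c("PC1", "PC2"), function(k) {
    abs(mean(pc[[k]][labs == "RC"]) - mean(pc[[k]][labs == "control"])) /
      (sd(pc[[k]][labs == "RC"]) + 1e-9)
  }, numeric(1))
  expect_gt(max(sep), 1)
  # duplicate samples get identical coordinates
  dup <- fx$ge[, c("gene_id", ids[1], ids)]
  names(dup)[2] <- "dup_sample"
  pc2 <- pca_embed(dup)
  expect_equal(as.numeric(pc2[pc2$sample_id == "dup_sample", -1]),
               as.numeric(pc2[pc2$sample_id == ids[1], -1]), tolerance = 1e-9)
})
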