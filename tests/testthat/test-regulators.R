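test_that("PWM scanning matches the naive sliding-window oracle", {
  set.seed(41)
  cfg <- generator_config(n_genes = 1, n_tfs = 0, seed = 41)
  pwms <- simulate_pwm_library(cfg)
  pwm <- pwms$PPRE
  cons <- pwm_consensus(pwm)
  # a perfect consensus occurrence scores similarity 1
  seq <- paste0(strrep("G", 40), cons, strrep("C", 40))
  hits <- scan_pwm(seq, pwm, 0.95)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 40L)
  expect_equal(hits$similarity, 1, tolerance = 1e-12)
  # no window above threshold gives an empty result
  expect_equal(nrow(scan_pwm(strrep("G", 100), pwm, 0.95)), 0L)
  # 10 kb random sequence at a permissive threshold: identical to the
  # brute-force oracle (both strands)
  long <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  got <- as.data.frame(scan_pwm(long, pwm, 0.60))
  want <- oracle_scan_pwm(long, pwm, 0.60)
  got <- got[order(got$offset, got$strand), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got$offset, want$offset)
  expect_equal(got$strand, want$strand)
  expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
  # strand symmetry: scanning the reverse complement mirrors the offsets
  rc_hits <- scan_pwm(revcomp(long), pwm, 0.60)
  n <- nchar(long); L <- ncol(pwm)
  mirrored <- sort(n - L - rc_hits$offset)
  expect_equal(sort(got$offset), mirrored)
  expect_equal(sort(got$similarity), sort(rc_hits$similarity), tolerance = 1e-12)
  expect_error(scan_pwm("ACGT", pwm), "shorter than motif")
})

test_that("target sets equal the planted truth and scopes differ", {
  sim <- fx_sim()
  prom <- build_target_sets(sim$models, sim$sequences, sim$pwms,
                            scope = "promoter_1kb")
  tg <- sim$truth_genes
  for (tf in names(sim$pwms)) {
    truth <- tg$gene_id[vapply(tg$tf_promoter, function(x) tf %in% x, logical(1))]
    got <- sort(prom$gene_id[prom$tf_id == tf])
    expect_equal(got, sort(truth))
  }
  intr <- build_target_sets(sim$models, sim$sequences, sim$pwms,
                            scope = "intron")
  for (tf in unique(intr$tf_id)) {
    truth <- tg$gene_id[vapply(tg$tf_intron, function(x) tf %in% x, logical(1))]
    expect_equal(sort(intr$gene_id[intr$tf_id == tf]), sort(truth))
  }
  # promoter and intron scopes disagree where planted differently
  expect_false(identical(
    sort(paste(prom$tf_id, prom$gene_id)),
    sort(paste(intr$tf_id, intr$gene_id))
  ))
  empty <- build_target_sets(sim$models, sim$sequences, list())
  expect_equal(nrow(empty), 0L)
})

test_that("target-set activity recovers planted shifts and stays calibrated", {
  set.seed(43)
  n <- 2000
  genes <- paste0("g", seq_len(n))
  targets <- genes[1:200]
  changes <- tibble::tibble(
    gene_id = genes,
    change_pct = c(rnorm(200, 10, 5), rnorm(1800, 0, 5))
  )
  act <- target_set_activity(changes, targets)
  expect_lt(act$p, 0.01)
  expect_lt(abs(act$mean_difference - 10), 2)
  # identical changes give zero difference
  same <- tibble::tibble(gene_id = genes[1:10], change_pct = 3)
  act0 <- target_set_activity(same, genes[1:5])
  expect_equal(act0$mean_difference, 0)
  # order and missing-change invariance
  sh <- changes[sample(n), ]
  sh2 <- rbind(sh, tibble::tibble(gene_id = "extra", change_pct = NA))
  expect_equal(target_set_activity(sh2, targets), act)
  # null calibration over simulated TF target draws
  null_p <- vapply(1:400, function(i) {
    target_set_activity(
      tibble::tibble(gene_id = genes[1:400], change_pct = rnorm(400)),
      sample(genes[1:400], 50)
    )$p
  }, numeric(1))
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)
})

test_that("interaction test contrasts both-site genes against single sites", {
  set.seed(47)
  genes <- paste0("g", 1:450)
  set_a <- genes[1:300]           # A-only: 1..150, both: 151..300
  set_b <- genes[151:450]         # B-only: 301..450
  both <- genes[151:300]
  changes <- tibble::tibble(
    gene_id = genes,
    change_pct = rnorm(450, 0, 5) +
      ifelse(genes %in% both, -10, 0)
  )
  res <- interaction_test(set_a, set_b, changes)
  expect_equal(res$n_both, 150)
  expect_lt(res$p_both_vs_a, 0.05)
  expect_lt(res$p_both_vs_b, 0.05)
  expect_error(interaction_test(genes[1:2], genes[3:4],
                                tibble::tibble(gene_id = genes[5:6],
                                               change_pct = 1:2)),
               "both-set")
})

test_that("GSEA matches brute force and the exhaustive permutation oracle", {
  # all members at the top: ES = 1
  stats <- setNames(seq(10, 1), paste0("g", 1:10))
  top <- gsea_enrichment(stats, paste0("g", 1:3))
  expect_equal(top$es, 1, tolerance = 1e-12)
  # single member ranked first
  one <- gsea_enrichment(stats, "g1", min_set_size = 1)
  expect_equal(one$es, 1, tolerance = 1e-12)
  # 10-gene list, 3-member set: ES equals the hand-rolled running sum and p
  # equals exhaustive enumeration over C(10,3) = 120 member placements
  set.seed(53)
  stats2 <- setNames(rnorm(10), paste0("g", 1:10))
  gene_set <- c("g2", "g5", "g9")
  res <- gsea_enrichment(stats2, gene_set)
  sorted <- sort(stats2, decreasing = TRUE)
  member <- names(sorted) %in% gene_set
  expect_equal(res$es, oracle_gsea_es(sorted, member), tolerance = 1e-12)
  combos <- combn(10, 3, simplify = FALSE)
  es_all <- vapply(combos, function(ix) {
    mem <- logical(10); mem[ix] <- TRUE
    oracle_gsea_es(sorted, mem)
  }, numeric(1))
  expect_equal(res$p, mean(abs(es_all) >= abs(res$es)))
  # running sum returns to zero
  expect_lt(abs(attr(res, "running")[10]), 1e-9)
  expect_error(gsea_enrichment(stats2, c("g1", "g2")), "smaller than")
})

test_that("hypergeometric over-representation equals the factorial oracle", {
  bg <- paste0("g", 1:100)
  cat10 <- bg[1:10]
  # zero overlap with a tiny category: p is the hypergeometric tail at 0
  sub <- bg[51:60]
  r0 <- overrepresentation_test(sub, cat10, bg)
  expect_equal(r0$overlap, 0L)
  factorial_tail <- function(ov, m, N, k) {
    sum(vapply(ov:min(m, k), function(j) {
      choose(m, j) * choose(N - m, k - j) / choose(N, k)
    }, numeric(1)))
  }
  expect_equal(r0$p, factorial_tail(0, 10, 100, 10), tolerance = 1e-12)
  # subset identical to the category, background 10x larger
  r1 <- overrepresentation_test(cat10, cat10, bg)
  expect_equal(r1$overlap, 10L)
  expect_equal(r1$p, factorial_tail(10, 10, 100, 10), tolerance = 1e-12)
  # category = background: p = 1
  expect_equal(overrepresentation_test(sub, bg, bg)$p, 1)
  expect_error(overrepresentation_test(c(sub, "zz"), cat10, bg), "subset")
})
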