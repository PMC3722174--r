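#' Configuration for the synthetic exon-array generator
#'
#' Returns a validated list of generator settings. The defaults describe a
#' two-tissue (muscle, fibroblast) x two-state (RC disease, control) study
#' with 8 arrays per cell, multiplicative log-normal probe affinities and
#' log-normal intensity noise, and planted effect classes that exercise every
#' downstream analysis: gene-level fold changes (mostly sign-flipped between
#' tissues), ARE-class-dependent 3'-UTR shifts, positional 3'-UTR gradients,
#' UTR-only overrides (alternative events), antisense probesets (a mirror /
#' opposite / independent / background mixture), TF target sets planted as
#' PWM consensus sites, and a co-expression module for correlation analyses.
#'
#' @param n_genes number of genes.
#' @param probes_per_probeset probes per exon/5'-UTR/antisense probeset.
#' @param three_utr_probes probes in the single 3'-UTR probeset (kept high so
#'   positional profiles are informative).
#' @param samples_per_group arrays per (tissue, disease) cell.
#' @param tissues,diseases group labels; the first disease label is the
#'   affected state.
#' @param affinity_meanlog,affinity_sdlog log-normal probe affinity params.
#' @param noise_sd intensity noise SD on the log2 scale.
#' @param background_log2 log2 level of background-only probesets.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline abundance.
#' @param frac_gene_effect fraction of genes with a gene-level fold change.
#' @param inverse_fraction fraction of affected genes whose effect is
#'   sign-flipped between the two tissues.
#' @param lfc_range range of |log2 fold change| for gene-level effects.
#' @param frac_are fraction of genes carrying an ARE (split evenly over the
#'   five motif classes mer5..mer13).
#' @param are_pct named per-class planted 3'-UTR percent change in the first
#'   tissue (sign-flipped in the second).
#' @param frac_gradient fraction of genes with a positional 3'-UTR gradient.
#' @param gradient_by_tissue named log2-per-unit-position slopes.
#' @param frac_alt_event fraction of genes with a 5'-UTR-only override (the
#'   planted alternative events).
#' @param alt_event_lfc absolute log2 override for alternative-event genes.
#' @param antisense_fraction fraction of genes with an antisense probeset.
#' @param antisense_background_fraction of antisense probesets, fraction left
#'   at background level (the "not effective" mixture).
#' @param antisense_opposite_fraction,antisense_independent_fraction modes of
#'   the remaining (effective) antisense probesets; the rest mirror sense.
#' @param n_background_reference dedicated pure-background probesets used as
#'   the reference set for the effective-probeset rule.
#' @param module_size genes per planted co-expression set (one positively and
#'   one negatively coupled to the focal gene).
#' @param corr_sd log2 SD of the latent sample factor driving the module.
#' @param n_tfs number of generic TFs in the PWM library (besides the 15-bp
#'   PPRE and the TATA motif, which are always included).
#' @param tf_motif_length motif length of the generic TFs.
#' @param tf_target_fraction fraction of genes in each TF's target set.
#' @param tf_effect_pct named percent changes applied to target genes in the
#'   first tissue (sign-flipped in the second tissue).
#' @param interaction_extra_pct extra percent change for genes targeted by
#'   both PPRE and TATA (0 disables the interaction).
#' @param top_fraction fraction of genes with a 5' TOP motif.
#' @param utr5_baseline_rule if `TRUE`, genes in the top quartile of 5'-UTR
#'   baseline (relative) abundance get a -20 percent 5'-UTR change in the
#'   first tissue.
#' @param promoter_len,intron_len,utr5_len,utr3_len,exon_len segment lengths.
#' @param seed integer RNG seed; every generator call is deterministic in it.
#' @return a list with class `"generator_config"`.
#' @export
generator_config <- function(n_genes = 600,
                             probes_per_probeset = 4,
                             three_utr_probes = 20,
                             samples_per_group = 8,
                             tissues = c("muscle", "fibroblast"),
                             diseases = c("RC", "control"),
                             affinity_meanlog = 0,
                             affinity_sdlog = 0.4,
                             noise_sd = 0.1,
                             background_log2 = 4,
                             baseline_log2_mean = 9,
                             baseline_log2_sd = 0.8,
                             frac_gene_effect = 0.25,
                             inverse_fraction = 0.6,
                             lfc_range = c(0.4, 1.2),
                             frac_are = 0.3,
                             are_pct = c(mer5 = 8, mer7 = 16, mer9 = 16,
                                         mer11 = 16, mer13 = 16),
                             frac_gradient = 0.1,
                             gradient_by_tissue = c(muscle = -0.5, fibroblast = 0.25),
                             frac_alt_event = 0.1,
                             alt_event_lfc = 0.6,
                             antisense_fraction = 0.5,
                             antisense_background_fraction = 0.5,
                             antisense_opposite_fraction = 0.1,
                             antisense_independent_fraction = 0.1,
                             n_background_reference = 50,
                             module_size = 30,
                             corr_sd = 0.25,
                             n_tfs = 4,
                             tf_motif_length = 10,
                             tf_target_fraction = 0.15,
                             tf_effect_pct = c(PPRE = -10),
                             interaction_extra_pct = 0,
                             top_fraction = 0.3,
                             utr5_baseline_rule = FALSE,
                             promoter_len = 1000,
                             intron_len = 500,
                             utr5_len = 200,
                             utr3_len = 800,
                             exon_len = 300,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_genes, probes_per_probeset, three_utr_probes, samples_per_group)
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  fr <- c(frac_gene_effect, frac_are, frac_gradient, frac_alt_event)
  if (any(fr < 0) || sum(fr) > 1) abort("effect fractions must be >= 0 and sum <= 1")
  if (length(tissues) != 2) abort("exactly two tissue labels are required")
  structure(cfg, class = "generator_config")
}

ARE_CLASSES <- c("mer5", "mer7", "mer9", "mer11", "mer13")

#' Draw the planted effect table (the ground truth)
#'
#' Genes are partitioned into disjoint effect classes per the configured
#' fractions; all remaining genes are unaffected nulls (they also provide the
#' no-ARE comparison class). One row per gene.
#'
#' @param config a [generator_config()].
#' @return tibble with one row per gene: per-tissue gene-level log2 fold
#'   changes, 5'-UTR override, ARE class and per-tissue 3'-UTR shift,
#'   positional gradients, antisense mode, TF memberships (list columns),
#'   module role and TOP-motif flag.
#' @export
simulate_effects <- function(config) {
  cfg <- config
  set.seed(stage_seed(cfg$seed, "models"))
  n <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  t1 <- cfg$tissues[1]; t2 <- cfg$tissues[2]

  n_eff <- round(n * cfg$frac_gene_effect)
  n_are <- round(n * cfg$frac_are)
  n_grad <- round(n * cfg$frac_gradient)
  n_alt <- round(n * cfg$frac_alt_event)
  class_of <- rep("null", n)
  idx <- sample.int(n)  # random disjoint assignment
  take <- function(k) {
    if (k <= 0) return(integer(0))
    out <- head(idx, k)
    idx <<- idx[-seq_len(min(k, length(idx)))]
    out
  }
  class_of[take(n_eff)] <- "gene_effect"
  are_idx <- take(n_are)
  class_of[are_idx] <- "are"
  class_of[take(n_grad)] <- "gradient"
  class_of[take(n_alt)] <- "alt_event"
  module <- rep(NA_character_, n)
  if (cfg$module_size > 0 && length(idx) >= 2 * cfg$module_size + 1) {
    module[take(1)] <- "focal"
    module[take(cfg$module_size)] <- "cyto"
    module[take(cfg$module_size)] <- "mito"
  }

  lfc1 <- lfc2 <- numeric(n)
  is_eff <- class_of == "gene_effect"
  mag <- runif(sum(is_eff), cfg$lfc_range[1], cfg$lfc_range[2])
  sgn <- sample(c(-1, 1), sum(is_eff), replace = TRUE)
  lfc1[is_eff] <- mag * sgn
  flip <- runif(sum(is_eff)) < cfg$inverse_fraction
  lfc2[is_eff] <- ifelse(flip, -lfc1[is_eff], lfc1[is_eff])

  are_class <- rep("none", n)
  if (length(are_idx)) {
    are_class[are_idx] <- rep_len(ARE_CLASSES, length(are_idx))[sample.int(length(are_idx))]
  }
  shift1 <- ifelse(are_class == "none", 0, log2(1 + cfg$are_pct[are_class] / 100))
  shift1[is.na(shift1)] <- 0
  shift2 <- -shift1  # sign-flipped in the second tissue

  grad1 <- grad2 <- numeric(n)
  is_grad <- class_of == "gradient"
  grad1[is_grad] <- cfg$gradient_by_tissue[[t1]]
  grad2[is_grad] <- cfg$gradient_by_tissue[[t2]]

  over5 <- numeric(n)
  is_alt <- class_of == "alt_event"
  over5[is_alt] <- cfg$alt_event_lfc * sample(c(-1, 1), sum(is_alt), replace = TRUE)

  # antisense mode per gene
  anti <- rep("none", n)
  has_anti <- runif(n) < cfg$antisense_fraction
  mode_draw <- runif(n)
  eff_draw <- runif(n)
  p_op <- cfg$antisense_opposite_fraction
  p_ind <- cfg$antisense_independent_fraction
  anti[has_anti] <- ifelse(
    eff_draw[has_anti] < cfg$antisense_background_fraction, "background",
    ifelse(mode_draw[has_anti] < p_op, "opposite",
           ifelse(mode_draw[has_anti] < p_op + p_ind, "independent", "mirror"))
  )

  # TF memberships (promoter scope for all, intron scope for half of the TFs)
  tf_ids <- c("PPRE", "TATA",
              if (cfg$n_tfs > 0) sprintf("TF%02d", seq_len(cfg$n_tfs)))
  intron_tfs <- tf_ids[seq_along(tf_ids) %% 2 == 0]
  tf_prom <- lapply(seq_len(n), function(i) character(0))
  tf_intr <- lapply(seq_len(n), function(i) character(0))
  for (tf in tf_ids) {
    members <- runif(n) < cfg$tf_target_fraction
    for (i in which(members)) tf_prom[[i]] <- c(tf_prom[[i]], tf)
    if (tf %in% intron_tfs) {
      members_i <- runif(n) < cfg$tf_target_fraction
      for (i in which(members_i)) tf_intr[[i]] <- c(tf_intr[[i]], tf)
    }
  }

  top_motif <- runif(n) < cfg$top_fraction

  # 5'-UTR baseline offsets; optional planted baseline->downregulation rule
  utr5_baseline <- rnorm(n, 0, 0.6)
  if (isTRUE(cfg$utr5_baseline_rule)) {
    hi <- utr5_baseline >= quantile(utr5_baseline, 0.75)
    over5[hi] <- over5[hi] + log2(0.8)
  }

  tibble(
    gene_id = gene_id,
    effect_class = class_of,
    !!paste0("lfc_", t1) := lfc1,
    !!paste0("lfc_", t2) := lfc2,
    over_five_utr = over5,
    utr5_baseline = utr5_baseline,
    are_class = are_class,
    !!paste0("are_shift_", t1) := shift1,
    !!paste0("are_shift_", t2) := shift2,
    !!paste0("gradient_", t1) := grad1,
    !!paste0("gradient_", t2) := grad2,
    antisense_mode = anti,
    module = module,
    top_motif = top_motif,
    tf_promoter = tf_prom,
    tf_intron = tf_intr
  )
}
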