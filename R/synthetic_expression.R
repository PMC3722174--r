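#' Generate probe-level intensities with planted effects
#'
#' Probe intensity follows the multiplicative model
#' `I = theta(sample, probeset) * phi(probe) * 2^eps`, `eps ~ N(0, sd)` on
#' the log2 scale, which is exactly the factorization the Li-Wong
#' summarization stage assumes. `theta` carries the per-gene baseline, fixed
#' region offsets, the planted per-tissue disease effects (gene-level fold
#' change, 5'-UTR override, ARE-dependent 3'-UTR shift, per-probe positional
#' gradient) and the latent co-expression factor of the planted module.
#' Antisense probesets follow their configured mode; background-level
#' probesets are included so the effective-probeset filter has something to
#' reject.
#'
#' @param models output of [generate_gene_models()].
#' @param effects effect table (defaults to `models$effects`).
#' @param config the [generator_config()] used to build `models`.
#' @return list with `intensity` (an `intensity_table`), `truth_genes`
#'   (effects plus realized baselines) and `truth_probesets` (per-probeset
#'   region, antisense mode, and whether the probeset is truly above
#'   background).
#' @export
generate_expression <- function(models, effects = models$effects, config) {
  cfg <- config
  set.seed(stage_seed(cfg$seed, "expression"))
  gm <- models$models
  pm <- gm$probes
  n <- nrow(effects)
  if (!all(pm$gene_id %in% effects$gene_id)) abort("effect for unknown gene missing")
  t1 <- cfg$tissues[1]; t2 <- cfg$tissues[2]
  affected <- cfg$diseases[1]

  # sample design
  design <- tidyr::expand_grid(
    tissue = cfg$tissues, disease = cfg$diseases,
    rep = seq_len(cfg$samples_per_group)
  ) |>
    mutate(sample_id = sprintf("%s_%s_%02d", .data$tissue, .data$disease, .data$rep)) |>
    select("sample_id", "tissue", "disease")
  S <- nrow(design)
  z <- rnorm(S)  # latent module factor, one value per sample

  ef <- effects
  idx <- match(pm$gene_id, ef$gene_id)
  baseline <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  region_offset <- c(five_utr = -0.5, exon = 0, three_utr = -0.3)

  # per-probe relative transcript position within the 3'-UTR (0 = 5' end)
  utr3 <- gm$segments |> filter(.data$kind == "three_utr")
  u3 <- match(pm$gene_id, utr3$gene_id)
  strand_g <- gm$genes$strand[match(pm$gene_id, gm$genes$gene_id)]
  mid <- (pm$start + pm$end) / 2
  relpos <- (mid - utr3$start[u3]) / (utr3$end[u3] - utr3$start[u3])
  relpos <- ifelse(strand_g == "-", 1 - relpos, relpos)
  relpos[pm$region_kind != "three_utr"] <- 0

  is_anti <- pm$region_kind == "antisense"
  is_bgref <- grepl(":bgref", pm$probeset_id)
  mode <- ifelse(is_bgref, "background",
                 ifelse(is_anti, ef$antisense_mode[idx], "sense"))

  # TF-driven gene-level component: targets of each TF named in
  # tf_effect_pct shift by that percent in the first tissue (flipped in the
  # second); genes with both PPRE and TATA sites get the interaction extra.
  tf_lfc_gene <- vapply(seq_len(n), function(i) {
    tfs <- ef$tf_promoter[[i]]
    hit <- intersect(tfs, names(cfg$tf_effect_pct))
    e <- sum(log2(1 + cfg$tf_effect_pct[hit] / 100))
    if (cfg$interaction_extra_pct != 0 && all(c("PPRE", "TATA") %in% tfs)) {
      e <- e + log2(1 + cfg$interaction_extra_pct / 100)
    }
    e
  }, numeric(1))

  lfc1 <- ef[[paste0("lfc_", t1)]][idx] + tf_lfc_gene[idx]
  lfc2 <- ef[[paste0("lfc_", t2)]][idx] - tf_lfc_gene[idx]
  shift1 <- ef[[paste0("are_shift_", t1)]][idx]
  shift2 <- ef[[paste0("are_shift_", t2)]][idx]
  grad1 <- ef[[paste0("gradient_", t1)]][idx]
  grad2 <- ef[[paste0("gradient_", t2)]][idx]
  over5 <- ef$over_five_utr[idx]
  ub5 <- ef$utr5_baseline[idx]
  load <- ifelse(is.na(ef$module[idx]), 0,
                 c(focal = 1, cyto = 1, mito = -1)[ef$module[idx]])

  base <- baseline[idx] + region_offset[pm$region_kind]
  base[is.na(base)] <- 0  # antisense handled next
  base[pm$region_kind == "five_utr"] <- base[pm$region_kind == "five_utr"] +
    ub5[pm$region_kind == "five_utr"]

  eff_of <- function(lfc, shift, grad) {
    e <- lfc +
      ifelse(pm$region_kind == "five_utr", over5, 0) +
      ifelse(pm$region_kind == "three_utr", shift + grad * relpos, 0)
    # mirror/opposite antisense track the sense 5'-UTR signal they overlap
    e[is_anti] <- (c(mirror = 1, opposite = -1, independent = 0,
                     background = 0, none = 0)[mode[is_anti]]) *
      (lfc[is_anti] + over5[is_anti])
    e
  }
  eff1 <- eff_of(lfc1, shift1, grad1)
  eff2 <- eff_of(lfc2, shift2, grad2)

  # antisense / background baselines
  ind_base <- rnorm(sum(mode == "independent"), 7, 0.5)
  mir <- mode %in% c("mirror", "opposite")
  base[mir] <- baseline[idx][mir] + region_offset[["five_utr"]] + ub5[mir] - 2
  base[mode == "independent"] <- ind_base
  base[mode == "background"] <- cfg$background_log2
  load[is_anti] <- 0

  dis <- as.numeric(design$disease == affected)
  in_t1 <- as.numeric(design$tissue == t1)
  M <- matrix(base, nrow = nrow(pm), ncol = S) +
    outer(eff1, dis * in_t1) +
    outer(eff2, dis * (1 - in_t1)) +
    outer(load * cfg$corr_sd, z)
  phi_log2 <- log2(rlnorm(nrow(pm), cfg$affinity_meanlog, cfg$affinity_sdlog))
  M <- M + phi_log2
  if (cfg$noise_sd > 0) {
    M <- M + matrix(rnorm(length(M), 0, cfg$noise_sd), nrow = nrow(M))
  }
  dimnames(M) <- list(pm$probe_id, design$sample_id)
  values <- expr_tibble(2^M, id_col = "probe_id")

  truth_probesets <- tibble(
    probeset_id = pm$probeset_id, gene_id = pm$gene_id,
    region_kind = pm$region_kind, mode = mode
  ) |>
    distinct() |>
    mutate(
      is_background = .data$mode == "background",
      is_background_reference = grepl(":bgref", .data$probeset_id),
      effective_true = !.data$is_background
    )

  truth_genes <- ef |>
    mutate(baseline_log2 = baseline, tf_lfc = tf_lfc_gene)

  list(
    intensity = new_intensity_table(values, design),
    truth_genes = truth_genes,
    truth_probesets = truth_probesets
  )
}

#' One-call synthetic study
#'
#' Draws effects, builds gene models / sequences / PWMs and generates the
#' probe-level intensity table. If `dir` is given, writes every artifact to
#' plain-text files (GFF3, probe-map TSV, FASTA, PWM library, intensity and
#' design TSVs, truth TSVs) so the study round-trips through the readers.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory.
#' @return list combining the outputs of [generate_gene_models()] and
#'   [generate_expression()], plus `design`.
#' @export
simulate_study <- function(config = generator_config(), dir = NULL) {
  built <- generate_gene_models(config)
  expr <- generate_expression(built, built$effects, config)
  out <- list(
    models = built$models, sequences = built$sequences, pwms = built$pwms,
    effects = built$effects, intensity = expr$intensity,
    design = expr$intensity$design,
    truth_genes = expr$truth_genes, truth_probesets = expr$truth_probesets
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models(out$models, file.path(dir, "models.gff3"),
                      file.path(dir, "probe_map.tsv"))
    write_fasta(out$sequences, file.path(dir, "sequences.fa"))
    write_pwm_library(out$pwms, file.path(dir, "pwms.txt"))
    write_intensity_table(out$intensity, file.path(dir, "intensity.tsv"),
                          file.path(dir, "design.tsv"))
    cfg_plain <- config[!vapply(config, is.function, logical(1))]
    write_result_table(
      out$truth_genes |> mutate(
        tf_promoter = vapply(.data$tf_promoter, paste, character(1), collapse = ","),
        tf_intron = vapply(.data$tf_intron, paste, character(1), collapse = ",")
      ),
      file.path(dir, "truth_genes.tsv"), config = cfg_plain
    )
    write_result_table(out$truth_probesets, file.path(dir, "truth_probesets.tsv"),
                       config = cfg_plain)
  }
  out
}
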