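#' Assemble a validated pipeline configuration
#'
#' Every tunable of the individual stages is exposed here; unknown keys fail
#' immediately (R reports the offending argument name). The global seed fans
#' out deterministically into per-stage seeds, so stages can be rerun in
#' isolation and full reruns are byte-identical.
#'
#' @param generator a [generator_config()] describing the synthetic study
#'   (ignored when `input_dir` points at previously written artifacts).
#' @param input_dir optional directory holding `intensity.tsv`,
#'   `design.tsv`, `models.gff3`, `probe_map.tsv`, `sequences.fa`,
#'   `pwms.txt` (as written by [simulate_study()]).
#' @param out_dir where result tables are written (`NULL` skips writing).
#' @param seed global seed.
#' @param lowess_span normalization smoother span.
#' @param liwong_tol,liwong_max_iter,outlier_sd Li-Wong settings.
#' @param effective_sd,effective_fraction effective-probeset rule.
#' @param sam_n_perm,sam_s0 SAM settings (`NULL` s0 = automatic).
#' @param ratio_k alternative-event fold-smaller threshold.
#' @param p_cut significance threshold shared by event calling, quadrant
#'   classification and the correlation screen.
#' @param min_similarity PWM match threshold.
#' @param gsea_n_perm gene-set permutation count.
#' @return list with class `"run_config"`.
#' @export
run_config <- function(generator = generator_config(),
                       input_dir = NULL,
                       out_dir = NULL,
                       seed = 1L,
                       lowess_span = 0.3,
                       liwong_tol = 1e-6,
                       liwong_max_iter = 50,
                       outlier_sd = 3,
                       effective_sd = 2,
                       effective_fraction = 0.5,
                       sam_n_perm = 200,
                       sam_s0 = NULL,
                       ratio_k = 10,
                       p_cut = 0.05,
                       min_similarity = 0.95,
                       gsea_n_perm = 500) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orders the stages end-to-end: simulate (or load) probe-level data,
#' lowess-normalize, summarize probes to probesets and probesets to genes,
#' flag effective probesets, run SAM per tissue at gene and probeset level,
#' call alternative events and tabulate sub-gene region changes, analyze
#' sense-antisense concordance, classify AREs and test the class ladder,
#' profile positional 3'-UTR differences, associate 5'-UTR baseline with
#' its change, score TF target-set activity, and combine the two tissues
#' (quadrants, signed-score correlation, focal-gene meta-correlation,
#' correlation screen). Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of all stage results; tables are additionally
#'   written under `config$out_dir` when set, each with a JSON sidecar
#'   carrying the configuration and seed.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  gen <- cfg$generator
  gen$seed <- cfg$seed
  if (is.null(cfg$input_dir)) {
    sim <- simulate_study(gen)
  } else {
    sim <- load_study(cfg$input_dir)
  }
  design <- sim$intensity$design
  tissues <- unique(design$tissue)
  affected <- unique(design$disease)[1]
  control <- setdiff(unique(design$disease), affected)[1]

  # --- preprocess ----------------------------------------------------------
  norm <- lowess_normalize(sim$intensity, span = cfg$lowess_span)
  ps_expr <- summarize_probesets(norm, sim$models$probes, tol = cfg$liwong_tol,
                                 max_iter = cfg$liwong_max_iter,
                                 outlier_sd = cfg$outlier_sd)
  gene_expr <- summarize_gene_level(ps_expr, sim$models$probes,
                                    tol = cfg$liwong_tol,
                                    max_iter = cfg$liwong_max_iter,
                                    outlier_sd = cfg$outlier_sd)
  bg_ids <- if (!is.null(sim$truth_probesets)) {
    sim$truth_probesets$probeset_id[sim$truth_probesets$is_background_reference]
  } else {
    default_background_ids(ps_expr, sim$models$probes)
  }
  effective <- detect_effective_probesets(ps_expr, bg_ids,
                                          sd_mult = cfg$effective_sd,
                                          fraction = cfg$effective_fraction)
  pca <- pca_embed(gene_expr)

  # --- differential expression per tissue ----------------------------------
  lg_gene <- log2_expr(gene_expr)
  lg_ps <- log2_expr(ps_expr)
  per_tissue <- list()
  for (tis in tissues) {
    ids <- design$sample_id[design$tissue == tis]
    labs <- design$disease[design$tissue == tis]
    sub_gene <- lg_gene[, c(names(lg_gene)[1], ids)]
    sub_ps <- lg_ps[, c(names(lg_ps)[1], ids)]
    sg <- sam_test(sub_gene, labs, group_a = affected, n_perm = cfg$sam_n_perm,
                   seed = stage_seed(cfg$seed, "diffexp"), s0 = cfg$sam_s0)
    sp <- sam_test(sub_ps, labs, group_a = affected, n_perm = cfg$sam_n_perm,
                   seed = stage_seed(cfg$seed, "diffexp") + 1L, s0 = cfg$sam_s0)
    per_tissue[[tis]] <- list(
      gene = sg, probeset = sp, scores = signed_significance(sg)
    )
  }

  # --- sub-gene events and region summary ----------------------------------
  ps_map <- sim$models$probes |>
    distinct(.data$probeset_id, .data$gene_id, .data$region_kind)
  subgene <- list()
  region_tables <- list()
  for (tis in tissues) {
    pres <- per_tissue[[tis]]$probeset |>
      rename(probeset_id = "feature_id") |>
      inner_join(ps_map, by = "probeset_id")
    reps <- select_region_representatives(
      pres |> filter(.data$region_kind != "antisense")
    )
    events <- detect_alternative_events(reps, per_tissue[[tis]]$gene,
                                        ratio_k = cfg$ratio_k, alpha = cfg$p_cut)
    region_tables[[tis]] <- summarize_region_changes(
      pres |> mutate(tissue = tis), effective, alpha = cfg$p_cut
    )
    subgene[[tis]] <- list(representatives = reps, events = events)
  }
  region_summary <- bind_rows(region_tables)

  # --- sense-antisense concordance (first tissue) ---------------------------
  anti_map <- ps_map |> filter(.data$region_kind == "antisense",
                               !grepl(":bgref", .data$probeset_id))
  sense_map <- ps_map |> filter(.data$region_kind == "five_utr")
  pairs <- anti_map |>
    select("gene_id", anti_id = "probeset_id") |>
    inner_join(sense_map |> select("gene_id", sense_id = "probeset_id"),
               by = "gene_id")
  eff_ids <- effective$probeset_id[effective$effective]
  pairs <- pairs |> filter(.data$anti_id %in% eff_ids)
  concordance <- NULL
  if (nrow(pairs) >= 3) {
    base_ps <- tibble(
      feature_id = lg_ps[[1]],
      baseline_log2 = rowMeans(expr_matrix(lg_ps)[, design$sample_id[
        design$disease != affected], drop = FALSE])
    )
    pres1 <- per_tissue[[tissues[1]]]$probeset |>
      left_join(base_ps, by = "feature_id")
    concordance <- sense_antisense_concordance(pres1, pres1, pairs,
                                               alpha = cfg$p_cut)
  }

  # --- UTR features ---------------------------------------------------------
  utr3_seqs <- sim$sequences[grepl("\\|three_utr$", names(sim$sequences))]
  names(utr3_seqs) <- sub("\\|three_utr$", "", names(utr3_seqs))
  are_ann <- classify_are_table(utr3_seqs)
  are_tests <- list()
  profiles <- list()
  for (tis in tissues) {
    reps3 <- subgene[[tis]]$representatives |>
      filter(.data$region_kind == "three_utr",
             .data$probeset_id %in% eff_ids)
    changes3 <- reps3 |> select("gene_id", change_pct = "mean_change_pct")
    are_tests[[tis]] <- are_group_change_test(are_ann, changes3)
    profiles[[tis]] <- positional_profile(
      norm, sim$models, ps_expr, region_kind = "three_utr",
      tissue = tis, affected = affected, span = cfg$lowess_span
    )
  }
  ctrl_ids <- design$sample_id[design$tissue == tissues[1] &
                                 design$disease != affected]
  utr5_base <- relative_utr_level(ps_expr, gene_expr, sim$models$probes,
                                  kind = "five_utr", samples = ctrl_ids)
  utr5_change <- subgene[[tissues[1]]]$representatives |>
    filter(.data$region_kind == "five_utr") |>
    select("gene_id", change_pct = "mean_change_pct")
  baseline_assoc <- baseline_abundance_association(utr5_base, utr5_change)
  utr5_seqs <- sim$sequences[grepl("\\|five_utr$", names(sim$sequences))]
  names(utr5_seqs) <- sub("\\|five_utr$", "", names(utr5_seqs))
  top_flags <- tibble(gene_id = names(utr5_seqs),
                      top = detect_top_motif(unname(utr5_seqs)))
  top_assoc <- target_set_activity(utr5_change,
                                   top_flags$gene_id[top_flags$top])

  # --- TF target-set activity ----------------------------------------------
  targets_prom <- build_target_sets(sim$models, sim$sequences, sim$pwms,
                                    scope = "promoter_1kb",
                                    min_similarity = cfg$min_similarity)
  targets_intr <- build_target_sets(sim$models, sim$sequences, sim$pwms,
                                    scope = "intron",
                                    min_similarity = cfg$min_similarity)
  tf_activity <- list()
  for (tis in tissues) {
    ch <- per_tissue[[tis]]$gene |>
      select(gene_id = "feature_id", change_pct = "mean_change_pct")
    act <- lapply(unique(targets_prom$tf_id), function(tf) {
      target_set_activity(ch, targets_prom$gene_id[targets_prom$tf_id == tf]) |>
        mutate(tf_id = tf, scope = "promoter_1kb", tissue = tis)
    })
    tf_activity[[tis]] <- bind_rows(act)
  }
  tf_activity <- bind_rows(tf_activity)
  ch1 <- per_tissue[[tissues[1]]]$gene |>
    select(gene_id = "feature_id", change_pct = "mean_change_pct")
  ppar_tata <- NULL
  if (all(c("PPRE", "TATA") %in% targets_prom$tf_id)) {
    both_ok <- length(intersect(
      targets_prom$gene_id[targets_prom$tf_id == "PPRE"],
      targets_prom$gene_id[targets_prom$tf_id == "TATA"]
    )) > 0
    if (both_ok) {
      ppar_tata <- interaction_test(
        targets_prom$gene_id[targets_prom$tf_id == "PPRE"],
        targets_prom$gene_id[targets_prom$tf_id == "TATA"], ch1
      )
    }
  }

  # --- cross-tissue ---------------------------------------------------------
  quad <- quadrant_classify(per_tissue[[tissues[1]]]$gene,
                            per_tissue[[tissues[2]]]$gene,
                            p_cut = cfg$p_cut, tissue_names = tissues)
  xcor <- crosstissue_correlation(per_tissue[[tissues[1]]]$scores,
                                  per_tissue[[tissues[2]]]$scores)
  meta <- NULL
  screen <- NULL
  if (!is.null(sim$truth_genes) && any(!is.na(sim$truth_genes$module))) {
    tg <- sim$truth_genes
    focal <- tg$gene_id[!is.na(tg$module) & tg$module == "focal"][1]
    cyto <- tg$gene_id[!is.na(tg$module) & tg$module == "cyto"]
    mito <- tg$gene_id[!is.na(tg$module) & tg$module == "mito"]
    meta <- list(
      cyto = geneset_meta_correlation_summary(focal, cyto, gene_expr, design),
      mito = geneset_meta_correlation_summary(focal, mito, gene_expr, design)
    )
    screen <- correlation_screen(gene_expr, design, focal,
                                 p_cut = cfg$p_cut, disease = affected)
  }

  result <- list(
    config = cfg, sim = sim, normalized = norm,
    probeset_expr = ps_expr, gene_expr = gene_expr,
    effective = effective, pca = pca,
    per_tissue = per_tissue, subgene = subgene,
    region_summary = region_summary, concordance = concordance,
    are_annotation = are_ann, are_tests = are_tests, profiles = profiles,
    baseline_assoc = baseline_assoc, top_assoc = top_assoc,
    target_sets = list(promoter = targets_prom, intron = targets_intr),
    tf_activity = tf_activity, ppar_tata = ppar_tata,
    quadrants = quad, crosstissue = xcor, meta = meta, screen = screen
  )
  if (!is.null(cfg$out_dir)) write_pipeline_tables(result, cfg)
  invisible(result)
}

log2_expr <- function(tbl) {
  out <- tbl
  out[-1] <- log2(tbl[-1])
  out
}

# lowest-decile antisense probesets by mean log2 expression serve as the
# background reference when no dedicated background probesets exist
default_background_ids <- function(probeset_expr, probe_map) {
  anti <- probe_map |>
    filter(.data$region_kind == "antisense") |>
    distinct(.data$probeset_id)
  m <- log2(expr_matrix(probeset_expr))
  anti <- anti$probeset_id[anti$probeset_id %in% rownames(m)]
  if (!length(anti)) abort("no antisense probesets to estimate background from")
  mu <- rowMeans(m[anti, , drop = FALSE])
  anti[mu <= quantile(mu, 0.1)]
}

#' Load a study previously written by [simulate_study()]
#'
#' @param dir directory holding the study artifacts.
#' @return list shaped like the output of [simulate_study()] (truth tables
#'   included when present).
#' @export
load_study <- function(dir) {
  intensity <- read_intensity_table(file.path(dir, "intensity.tsv"),
                                    file.path(dir, "design.tsv"))
  models <- read_gene_models(file.path(dir, "models.gff3"),
                             file.path(dir, "probe_map.tsv"))
  sequences <- read_fasta(file.path(dir, "sequences.fa"))
  pwms <- read_pwm_library(file.path(dir, "pwms.txt"))
  truth_genes <- NULL; truth_probesets <- NULL
  tg <- file.path(dir, "truth_genes.tsv")
  tp <- file.path(dir, "truth_probesets.tsv")
  if (file.exists(tg)) truth_genes <- read_result_table(tg)
  if (file.exists(tp)) truth_probesets <- read_result_table(tp)
  list(models = models, sequences = sequences, pwms = pwms,
       intensity = intensity, design = intensity$design,
       truth_genes = truth_genes, truth_probesets = truth_probesets)
}

write_pipeline_tables <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  plain_cfg <- list(seed = cfg$seed, lowess_span = cfg$lowess_span,
                    sam_n_perm = cfg$sam_n_perm, ratio_k = cfg$ratio_k,
                    p_cut = cfg$p_cut, min_similarity = cfg$min_similarity)
  wr <- function(tbl, name) {
    write_result_table(tbl, file.path(cfg$out_dir, name), config = plain_cfg)
  }
  for (tis in names(result$per_tissue)) {
    wr(result$per_tissue[[tis]]$gene, paste0("sam_gene_", tis, ".tsv"))
    wr(result$subgene[[tis]]$events, paste0("events_", tis, ".tsv"))
  }
  wr(result$region_summary, "region_summary.tsv")
  wr(result$quadrants$counts, "quadrant_counts.tsv")
  wr(result$crosstissue, "crosstissue_correlation.tsv")
  wr(bind_rows(result$are_tests, .id = "tissue"), "are_class_tests.tsv")
  wr(result$tf_activity, "tf_activity.tsv")
  invisible(cfg$out_dir)
}
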