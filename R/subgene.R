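#' Pick the representative probeset of each gene region
#'
#' When a gene has several probesets in the same UTR or exon region, the one
#' with the smallest raw p-value represents the region, and its p-value is
#' Bonferroni-adjusted by the number of probesets in that gene region. Ties
#' break to the lexicographically smallest probeset id.
#'
#' @param probeset_results tibble with columns `probeset_id`, `gene_id`,
#'   `region_kind`, `p`, `delta` (and any others, which are carried along).
#' @return tibble with one row per (gene_id, region_kind): the representative
#'   row plus `n_probesets` and `p_adj = min(1, p * n_probesets)`.
#' @export
select_region_representatives <- function(probeset_results) {
  if (nrow(probeset_results) == 0) abort("empty probeset results")
  probeset_results |>
    group_by(.data$gene_id, .data$region_kind) |>
    mutate(n_probesets = n()) |>
    arrange(.data$p, .data$probeset_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(p_adj = pmin(1, .data$p * .data$n_probesets))
}

#' Call alternative expression events
#'
#' A region representative indicates an alternative event when its adjusted
#' p-value is below `alpha` and either (a) the region changed in the
#' opposite direction from the gene-level change, or (b) its raw p-value is
#' substantially smaller than the gene-level p-value
#' (`gene_p / p_raw >= ratio_k`). When both arms fire, the opposite-direction
#' reason is recorded.
#'
#' @param region_reps output of [select_region_representatives()].
#' @param gene_results gene-level tibble with `feature_id` (gene id), `p`,
#'   `delta`.
#' @param ratio_k fold-smaller threshold operationalizing "significantly
#'   smaller than the gene-level p value".
#' @param alpha adjusted significance cut.
#' @return tibble: one row per region representative with `gene_p`,
#'   `same_direction`, `event`, `event_reason`.
#' @export
detect_alternative_events <- function(region_reps, gene_results,
                                      ratio_k = 10, alpha = 0.05) {
  gl <- gene_results |>
    select(gene_id = "feature_id", gene_p = "p", gene_delta = "delta")
  missing <- setdiff(region_reps$gene_id, gl$gene_id)
  if (length(missing)) {
    abort(paste0("missing gene-level result for: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  region_reps |>
    left_join(gl, by = "gene_id") |>
    mutate(
      same_direction = sign(.data$delta) == sign(.data$gene_delta),
      opposite = !.data$same_direction & .data$delta != 0,
      stronger = .data$gene_p / .data$p >= ratio_k,
      event = .data$p_adj < alpha & (.data$opposite | .data$stronger),
      event_reason = dplyr::case_when(
        .data$event & .data$opposite ~ "opposite_direction",
        .data$event ~ "stronger_than_gene",
        TRUE ~ NA_character_
      )
    ) |>
    select(-"opposite", -"stronger")
}

#' Count up/down-regulated genes per sub-gene region
#'
#' Region representatives are tallied per region kind (and per tissue when a
#' `tissue` column is present): the number of genes analyzed, and the number
#' whose representative is significantly up- or down-regulated at the
#' Bonferroni-adjusted level. Antisense rows count only probesets flagged
#' effective.
#'
#' @param probeset_results tibble with `probeset_id`, `gene_id`,
#'   `region_kind`, `p`, `delta` (optionally `tissue`).
#' @param effective_flags tibble from [detect_effective_probesets()], used
#'   to restrict the antisense rows; `NULL` keeps all.
#' @param alpha adjusted significance cut.
#' @return tibble: (`tissue`,) `region_kind`, `n_analyzed`, `n_up`, `n_down`.
#' @export
summarize_region_changes <- function(probeset_results, effective_flags = NULL,
                                     alpha = 0.05) {
  res <- probeset_results
  if (!is.null(effective_flags)) {
    eff <- effective_flags$probeset_id[effective_flags$effective]
    res <- res |>
      filter(.data$region_kind != "antisense" | .data$probeset_id %in% eff)
  }
  grouping <- intersect(c("tissue", "region_kind"), names(res))
  res |>
    group_by(across(all_of(c(grouping, "gene_id")))) |>
    mutate(n_probesets = n()) |>
    arrange(.data$p, .data$probeset_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(p_adj = pmin(1, .data$p * .data$n_probesets)) |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n_analyzed = n(),
      n_up = sum(.data$p_adj < alpha & .data$delta > 0),
      n_down = sum(.data$p_adj < alpha & .data$delta < 0),
      .groups = "drop"
    )
}

#' Sense-antisense concordance and outliers
#'
#' Correlates baseline abundance and disease-control differences between
#' sense and antisense transcripts over the supplied pairs, and reports the
#' pairs where both sides change significantly but in opposite directions
#' (candidate functional antisense transcripts).
#'
#' @param sense_results,antisense_results tibbles with `feature_id`,
#'   `baseline_log2`, `delta`, `p_adj` (falls back to `p` when `p_adj` is
#'   absent).
#' @param pairs tibble with `sense_id`, `anti_id` (and optionally `gene_id`).
#' @param alpha significance cut for the outlier rule.
#' @return list: `baseline_r`, `delta_r`, `outliers` (tibble of pairs).
#' @export
sense_antisense_concordance <- function(sense_results, antisense_results,
                                        pairs, alpha = 0.05) {
  padj_of <- function(res) {
    if ("p_adj" %in% names(res)) res$p_adj else res$p
  }
  s <- sense_results |>
    mutate(p_use = padj_of(sense_results)) |>
    select(sense_id = "feature_id", s_base = "baseline_log2",
           s_delta = "delta", s_p = "p_use")
  a <- antisense_results |>
    mutate(p_use = padj_of(antisense_results)) |>
    select(anti_id = "feature_id", a_base = "baseline_log2",
           a_delta = "delta", a_p = "p_use")
  joined <- pairs |>
    inner_join(s, by = "sense_id") |>
    inner_join(a, by = "anti_id")
  if (nrow(joined) < 3) abort("need at least 3 sense-antisense pairs")
  outliers <- joined |>
    filter(.data$s_p < alpha, .data$a_p < alpha,
           sign(.data$s_delta) * sign(.data$a_delta) < 0)
  list(
    baseline_r = cor(joined$s_base, joined$a_base),
    delta_r = cor(joined$s_delta, joined$a_delta),
    outliers = outliers
  )
}
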