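ARE_LADDER <- c("mer5", "mer7", "mer9", "mer11", "mer13")

#' Classify the AU-rich element content of a 3'-UTR sequence
#'
#' Scans every position for the AUUUA core (DNA: `ATTTA`) and measures how
#' far it extends symmetrically with W (A/T) flanks: `ATTTA` alone is class
#' `mer5`, `WATTTAW` is `mer7`, up to `WWWWATTTAWWWW` (`mer13`). The
#' sequence is assigned the most complex class with at least one match;
#' `N` never matches. Classes are nested by construction: a 13-mer match
#' implies matches of every simpler class.
#'
#' @param utr_sequence DNA string over A,C,G,T,N (transcript sense; U is
#'   accepted and treated as T).
#' @return list of class `"are_annotation"`: `are_class` (`"none"` or one of
#'   `mer5..mer13`) and `match_positions` (0-based offsets of each AUUUA
#'   core, named by the class that core achieves).
#' @export
classify_are <- function(utr_sequence) {
  if (!nzchar(utr_sequence)) abort("empty sequence")
  s <- chartr("uU", "tT", utr_sequence)
  ch <- strsplit(toupper(s), "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "N"))) abort("sequence must be over A,C,G,T,N")
  n <- length(ch)
  is_w <- ch == "A" | ch == "T"
  core <- c("A", "T", "T", "T", "A")
  pos <- integer(0); cls <- character(0)
  i <- 1L
  while (i <= n - 4L) {
    if (all(ch[i:(i + 4L)] == core)) {
      k <- 0L
      while (k < 4L) {
        lo <- i - (k + 1L); hi <- i + 5L + k
        if (lo < 1L || hi > n || !is_w[lo] || !is_w[hi]) break
        k <- k + 1L
      }
      pos <- c(pos, i - 1L)          # 0-based offset of the core
      cls <- c(cls, ARE_LADDER[k + 1L])
    }
    i <- i + 1L
  }
  best <- if (!length(pos)) "none" else ARE_LADDER[max(match(cls, ARE_LADDER))]
  structure(list(are_class = best, match_positions = setNames(pos, cls)),
            class = "are_annotation")
}

#' @export
print.are_annotation <- function(x, ...) {
  cat(sprintf("<are_annotation> class %s, %d AUUUA core(s)\n",
              x$are_class, length(x$match_positions)))
  invisible(x)
}

#' Annotate many 3'-UTR sequences at once
#'
#' @param sequences named character vector of 3'-UTR sequences (names are
#'   gene ids).
#' @return tibble: `gene_id`, `are_class`, `n_matches`.
#' @export
classify_are_table <- function(sequences) {
  anns <- lapply(sequences, classify_are)
  tibble(
    gene_id = names(sequences),
    are_class = vapply(anns, `[[`, character(1), "are_class"),
    n_matches = vapply(anns, function(a) length(a$match_positions), integer(1))
  )
}

#' Average 3'-UTR change per ARE class
#'
#' Splits genes into the five exclusive ARE classes (plus the no-ARE
#' baseline class) and reports each class's mean percent 3'-UTR change and a
#' Welch test against the no-ARE class.
#'
#' @param annotations tibble with `gene_id`, `are_class`.
#' @param three_utr_changes tibble with `gene_id`, `change_pct` (per-gene
#'   mean percent 3'-UTR change).
#' @return tibble: `are_class`, `n`, `mean_change_pct`, `p_vs_none` (NA for
#'   the none class itself). Classes with fewer than 2 genes are skipped
#'   with a warning.
#' @export
are_group_change_test <- function(annotations, three_utr_changes) {
  dat <- inner_join(annotations, three_utr_changes, by = "gene_id")
  none <- dat$change_pct[dat$are_class == "none"]
  if (length(none) < 2) abort("need at least 2 genes in the none class")
  out <- lapply(c("none", ARE_LADDER), function(cl) {
    x <- dat$change_pct[dat$are_class == cl]
    if (length(x) < 2) {
      if (cl != "none" && length(x) == 1) {
        warn(paste0("ARE class ", cl, " has <2 genes; skipped"))
      }
      return(NULL)
    }
    tibble(
      are_class = cl, n = length(x), mean_change_pct = mean(x),
      p_vs_none = if (cl == "none") NA_real_ else t.test(x, none)$p.value
    )
  })
  bind_rows(out)
}

#' Positional differential-expression profile of a UTR
#'
#' Probes mapped to the chosen UTR kind are placed at their relative
#' transcript position (0 = 5' end, strand-aware), adjusted by subtracting
#' the log2 expression of the adjacent coding exon of the same gene (the
#' first exon for 5'-UTRs, the last for 3'-UTRs), assigned to `n_bins`
#' equal intervals, and averaged per disease group. A lowess-smoothed
#' disease-minus-control difference curve yields the positional gradient
#' (its least-squares slope per unit relative position).
#'
#' @param intensity normalized `intensity_table` (probe level).
#' @param models `gene_models` object.
#' @param probeset_expr probeset x sample tibble (theta scale) supplying the
#'   adjacent-exon expression.
#' @param region_kind `"three_utr"` or `"five_utr"`.
#' @param tissue restrict to one tissue label (`NULL` uses all samples).
#' @param affected disease label of the affected group.
#' @param span lowess span.
#' @param n_bins number of relative-position intervals.
#' @return tibble of class `"positional_profile"`: one row per non-empty
#'   bin (`bin`, `mid`, `n_probes`, `mean_control`, `mean_disease`, `diff`,
#'   `smooth_diff`), with attributes `gradient` and `region_kind`.
#' @export
positional_profile <- function(intensity, models, probeset_expr,
                               region_kind = "three_utr", tissue = NULL,
                               affected = "RC", span = 0.3, n_bins = 100) {
  design <- intensity$design
  if (!is.null(tissue)) design <- design[design$tissue %in% tissue, ]
  pm <- models$probes |>
    filter(.data$region_kind == !!region_kind)
  if (nrow(pm) == 0) abort("region has zero probes")
  seg <- models$segments |> filter(.data$kind == !!region_kind)
  gi <- match(pm$gene_id, seg$gene_id)
  strand <- models$genes$strand[match(pm$gene_id, models$genes$gene_id)]
  mid <- (pm$start + pm$end) / 2
  rel <- (mid - seg$start[gi]) / (seg$end[gi] - seg$start[gi])
  rel <- pmin(pmax(ifelse(strand == "-", 1 - rel, rel), 0), 1 - 1e-9)

  m <- log2(expr_matrix(intensity$values))[pm$probe_id, design$sample_id, drop = FALSE]
  adj <- adjacent_exon_log2(models, probeset_expr, region_kind)
  adj_m <- adj[pm$gene_id, design$sample_id, drop = FALSE]
  v <- m - adj_m

  is_dis <- design$disease == affected
  probe_ctrl <- rowMeans(v[, !is_dis, drop = FALSE])
  probe_dis <- rowMeans(v[, is_dis, drop = FALSE])
  bin <- pmin(floor(rel * n_bins), n_bins - 1L)
  agg <- tibble(bin = bin, ctrl = probe_ctrl, dis = probe_dis) |>
    group_by(.data$bin) |>
    summarise(n_probes = n(), mean_control = mean(.data$ctrl),
              mean_disease = mean(.data$dis), .groups = "drop") |>
    mutate(mid = (.data$bin + 0.5) / n_bins,
           diff = .data$mean_disease - .data$mean_control) |>
    arrange(.data$bin)
  sm <- lowess(agg$mid, agg$diff, f = span)
  agg$smooth_diff <- approx(sm$x, sm$y, xout = agg$mid, rule = 2, ties = mean)$y
  gradient <- unname(coef(lm(smooth_diff ~ mid, data = agg))[2])
  structure(
    agg[, c("bin", "mid", "n_probes", "mean_control", "mean_disease",
            "diff", "smooth_diff")],
    gradient = gradient, region_kind = region_kind,
    class = c("positional_profile", class(agg))
  )
}

# per-gene x sample log2 expression of the exon adjacent to the given UTR
adjacent_exon_log2 <- function(models, probeset_expr, region_kind) {
  exons <- models$segments |> filter(.data$kind == "exon")
  strand <- models$genes$strand[match(exons$gene_id, models$genes$gene_id)]
  # transcript order: ascending start on +, descending on -
  exons <- exons |>
    mutate(ord = ifelse(strand == "+", .data$start, -.data$start)) |>
    group_by(.data$gene_id) |>
    arrange(.data$ord, .by_group = TRUE) |>
    mutate(rank = row_number(), n_ex = n()) |>
    ungroup()
  pick <- if (region_kind == "five_utr") {
    exons |> filter(.data$rank == 1)
  } else {
    exons |> filter(.data$rank == .data$n_ex)
  }
  # exon probesets falling inside the picked segment
  pm <- models$probes |> filter(.data$region_kind == "exon")
  pk <- pick[match(pm$gene_id, pick$gene_id), ]
  inside <- pm$start >= pk$start & pm$end <= pk$end
  sel <- pm[inside, ] |> distinct(.data$probeset_id, .data$gene_id)
  m <- log2(expr_matrix(probeset_expr))
  sel <- sel[sel$probeset_id %in% rownames(m), ]
  ps_split <- split(sel$probeset_id, sel$gene_id)
  out <- t(vapply(ps_split, function(ids) {
    colMeans(m[ids, , drop = FALSE])
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  out
}

#' Association of 5'-UTR baseline abundance with its disease change
#'
#' @param baseline tibble: `gene_id`, `baseline` (control-group mean log2
#'   5'-UTR level relative to the whole gene).
#' @param change tibble: `gene_id`, `change_pct` (5'-UTR percent change in
#'   disease).
#' @param span lowess span for the exported trend.
#' @return list: `rho` (Spearman), `p`, `trend` (tibble `baseline`,
#'   `smooth_change`), `data` (the joined table).
#' @export
baseline_abundance_association <- function(baseline, change, span = 0.3) {
  dat <- inner_join(baseline, change, by = "gene_id") |>
    filter(complete.cases(.data$baseline, .data$change_pct))
  if (nrow(dat) < 10) abort("need at least 10 genes")
  if (sd(dat$baseline) == 0) abort("constant baseline vector")
  ct <- suppressWarnings(
    cor.test(dat$baseline, dat$change_pct, method = "spearman", exact = FALSE)
  )
  sm <- lowess(dat$baseline, dat$change_pct, f = span)
  list(
    rho = unname(ct$estimate), p = ct$p.value,
    trend = tibble(baseline = sm$x, smooth_change = sm$y),
    data = dat
  )
}

#' Relative UTR expression level per gene
#'
#' Mean log2 probeset expression of the requested UTR kind minus the gene's
#' log2 expression, averaged over the selected samples.
#'
#' @param probeset_expr probeset x sample tibble (theta scale).
#' @param gene_expr gene x sample tibble (theta scale).
#' @param probe_map probe map tibble.
#' @param kind `"five_utr"` or `"three_utr"`.
#' @param samples sample ids to average over (default all shared columns).
#' @return tibble: `gene_id`, `baseline`.
#' @export
relative_utr_level <- function(probeset_expr, gene_expr, probe_map,
                               kind = "five_utr", samples = NULL) {
  samples <- samples %||% intersect(sample_cols(probeset_expr), sample_cols(gene_expr))
  ps <- log2(expr_matrix(probeset_expr))[, samples, drop = FALSE]
  ge <- log2(expr_matrix(gene_expr))[, samples, drop = FALSE]
  map <- probe_map |>
    filter(.data$region_kind == kind) |>
    distinct(.data$probeset_id, .data$gene_id)
  map <- map[map$probeset_id %in% rownames(ps) & map$gene_id %in% rownames(ge), ]
  utr <- rowsum(ps[map$probeset_id, , drop = FALSE], map$gene_id) /
    as.vector(table(map$gene_id)[sort(unique(map$gene_id))])
  genes <- rownames(utr)
  tibble(
    gene_id = genes,
    baseline = rowMeans(utr - ge[genes, , drop = FALSE])
  )
}

#' Detect a 5' terminal oligopyrimidine (TOP) motif
#'
#' TRUE when the sequence starts with a C (the DNA sense of a pyrimidine
#' transcription start) followed by a run of at least `min_run` consecutive
#' pyrimidines (C/T) beginning within the first `window` bases.
#'
#' @param five_utr_start character vector of sequences beginning at the
#'   transcription start site.
#' @param min_run minimum pyrimidine run length after the initial C.
#' @param window how far into the sequence the run may start.
#' @return logical vector.
#' @export
detect_top_motif <- function(five_utr_start, min_run = 4, window = 15) {
  vapply(five_utr_start, function(s) {
    if (nchar(s) < 6) abort("sequence shorter than 6")
    s <- toupper(s)
    if (substr(s, 1, 1) != "C") return(FALSE)
    body <- substr(s, 2, min(nchar(s), window))
    pyr <- strsplit(body, "")[[1]] %in% c("C", "T")
    r <- rle(pyr)
    any(r$values & r$lengths >= min_run)
  }, logical(1), USE.NAMES = FALSE)
}
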