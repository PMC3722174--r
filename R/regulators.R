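#' Scan a sequence for PWM matches on both strands
#'
#' A window's score is the sum of the PWM probabilities of its bases; the
#' similarity is that score min-max scaled per PWM, i.e.
#' `(score - min_score) / (max_score - min_score)` where the extremes come
#' from the per-column minima and maxima. Both the given strand and its
#' reverse complement are scanned; minus-strand matches are reported at
#' their window start in forward coordinates. `N` bases score the column
#' minimum (they can never help a match).
#'
#' @param sequence DNA string.
#' @param pwm a PWM matrix (see [read_pwm_library()]).
#' @param min_similarity report windows at or above this similarity.
#' @param scoring `"prob"` sums base probabilities (default); `"logodds"`
#'   sums `log2(p / 0.25)`; both are min-max scaled to the same [0, 1]
#'   similarity so the threshold keeps its meaning.
#' @return tibble: `offset` (0-based window start), `strand`, `similarity`.
#' @export
scan_pwm <- function(sequence, pwm, min_similarity = 0.95,
                     scoring = c("prob", "logodds")) {
  scoring <- match.arg(scoring)
  if (min_similarity <= 0 || min_similarity > 1) abort("similarity must be in (0,1]")
  if (scoring == "logodds") pwm[] <- log2(pwm / 0.25)
  L <- ncol(pwm)
  n <- nchar(sequence)
  if (n < L) abort("sequence shorter than motif")
  lo <- sum(apply(pwm, 2, min))
  hi <- sum(apply(pwm, 2, max))
  code <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  score_matrix <- function(m) {
    k <- n - L + 1
    sc <- numeric(k)
    for (j in seq_len(L)) {
      col <- m[, j]
      v <- col[code[j:(j + k - 1)]]
      v[is.na(v)] <- min(col)   # N
      sc <- sc + v
    }
    unname((sc - lo) / (hi - lo))
  }
  # a minus-strand match at forward offset o is a match of the
  # reverse-complemented matrix scanned over the forward sequence
  rc <- pwm[c("T", "G", "C", "A"), rev(seq_len(L)), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  fwd <- score_matrix(pwm)
  rev <- score_matrix(rc)
  hits_f <- which(fwd >= min_similarity)
  hits_r <- which(rev >= min_similarity)
  bind_rows(
    tibble(offset = hits_f - 1L, strand = "+", similarity = fwd[hits_f]),
    tibble(offset = hits_r - 1L, strand = "-", similarity = rev[hits_r])
  ) |>
    arrange(.data$offset)
}

#' Build TF target sets by PWM scanning
#'
#' A gene belongs to a TF's target set when the scoped sequence region
#' (promoter or intron) contains at least one PWM match at or above the
#' similarity threshold. Genes without the scoped sequence are excluded with
#' a warning.
#'
#' @param models `gene_models` object (supplies the gene universe).
#' @param sequences named character vector; names `<gene>|promoter` and
#'   `<gene>|intron`.
#' @param pwm_library named list of PWMs.
#' @param scope `"promoter_1kb"`, `"promoter_10kb"` or `"intron"`.
#' @param min_similarity match threshold.
#' @return tibble of class `"target_sets"`: `tf_id`, `gene_id` (long form;
#'   attribute `scope`).
#' @export
build_target_sets <- function(models, sequences, pwm_library,
                              scope = "promoter_1kb", min_similarity = 0.95) {
  key <- switch(scope,
    promoter_1kb = , promoter_10kb = "promoter",
    intron = "intron",
    abort("scope must be promoter_1kb, promoter_10kb or intron")
  )
  genes <- models$genes$gene_id
  have <- paste0(genes, "|", key) %in% names(sequences)
  if (any(!have)) {
    warn(paste0(sum(!have), " gene(s) lack a ", key, " sequence; excluded"))
  }
  genes <- genes[have]
  codes <- lapply(genes, function(g) {
    match(strsplit(toupper(sequences[[paste0(g, "|", key)]]), "")[[1]],
          c("A", "C", "G", "T"))
  })
  rows <- list()
  for (tf in names(pwm_library)) {
    pwm <- pwm_library[[tf]]
    hit <- vapply(codes, function(code) pwm_any_hit(code, pwm, min_similarity),
                  logical(1))
    if (any(hit)) rows[[tf]] <- tibble(tf_id = tf, gene_id = genes[hit])
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(tf_id = character(), gene_id = character())
  attr(out, "scope") <- scope
  class(out) <- c("target_sets", class(out))
  out
}

#' Average differential expression of a TF's target set
#'
#' Welch two-sample test of target vs non-target genes on their percent
#' change; the workhorse for TF activity screens and for arbitrary gene
#' lists (e.g. miRNA targets or ribosomal-protein sets). Invariant to gene
#' order and to genes with missing change values.
#'
#' @param changes tibble: `gene_id`, `change_pct`.
#' @param targets character vector of target gene ids.
#' @return one-row tibble: `n_targets`, `n_nontargets`, `mean_targets`,
#'   `mean_nontargets`, `mean_difference`, `p`.
#' @export
target_set_activity <- function(changes, targets) {
  dat <- changes |> filter(!is.na(.data$change_pct))
  x <- dat$change_pct[dat$gene_id %in% targets]
  y <- dat$change_pct[!dat$gene_id %in% targets]
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 targets and >= 2 non-targets")
  p <- if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) 1 else 0
  } else t.test(x, y)$p.value
  tibble(
    n_targets = length(x), n_nontargets = length(y),
    mean_targets = mean(x), mean_nontargets = mean(y),
    mean_difference = mean(x) - mean(y), p = p
  )
}

#' Test whether genes with both TF sites change more than single-site genes
#'
#' Partitions genes into both / A-only / B-only / neither by membership in
#' the two target sets and Welch-tests the both-group against each
#' single-site group.
#'
#' @param set_a,set_b character vectors of target gene ids.
#' @param changes tibble: `gene_id`, `change_pct`.
#' @return one-row tibble: group sizes and means, `p_both_vs_a`,
#'   `p_both_vs_b`.
#' @export
interaction_test <- function(set_a, set_b, changes) {
  dat <- changes |> filter(!is.na(.data$change_pct))
  in_a <- dat$gene_id %in% set_a
  in_b <- dat$gene_id %in% set_b
  both <- dat$change_pct[in_a & in_b]
  a_only <- dat$change_pct[in_a & !in_b]
  b_only <- dat$change_pct[!in_a & in_b]
  if (length(both) == 0) abort("empty both-set")
  welch <- function(x, y) {
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    t.test(x, y)$p.value
  }
  tibble(
    n_both = length(both), n_a_only = length(a_only), n_b_only = length(b_only),
    mean_both = mean(both),
    mean_a_only = if (length(a_only)) mean(a_only) else NA_real_,
    mean_b_only = if (length(b_only)) mean(b_only) else NA_real_,
    p_both_vs_a = welch(both, a_only),
    p_both_vs_b = welch(both, b_only)
  )
}

# fast any-match check on a pre-encoded sequence (both strands)
pwm_any_hit <- function(code, pwm, min_similarity) {
  L <- ncol(pwm)
  n <- length(code)
  if (n < L) return(FALSE)
  lo <- sum(apply(pwm, 2, min)); hi <- sum(apply(pwm, 2, max))
  cut <- lo + min_similarity * (hi - lo)
  rc <- pwm[c("T", "G", "C", "A"), rev(seq_len(L)), drop = FALSE]
  k <- n - L + 1
  for (m in list(pwm, rc)) {
    sc <- numeric(k)
    for (j in seq_len(L)) {
      col <- m[, j]
      v <- col[code[j:(j + k - 1)]]
      v[is.na(v)] <- min(col)
      sc <- sc + v
    }
    if (any(sc >= cut)) return(TRUE)
  }
  FALSE
}

# running enrichment score for one set over a ranked stat vector
gsea_running_sum <- function(stat_sorted, in_set, weight = 1) {
  n <- length(stat_sorted)
  nh <- sum(in_set)
  w <- abs(stat_sorted)^weight
  inc <- ifelse(in_set, w / sum(w[in_set]), -1 / (n - nh))
  cumsum(inc)
}

#' GSEA-style running enrichment score with permutation p-value
#'
#' Genes are ranked by a signed statistic; walking down the list, set
#' members increment a running sum by `|stat|^weight` (normalized over the
#' set) and non-members decrement it by `1/(N - N_hits)`. The enrichment
#' score is the extremum of the running sum (it always returns to 0 at the
#' end). Significance is assessed by gene-label permutation: random (or,
#' for small problems, exhaustively enumerated) sets of the same size.
#'
#' @param ranked_stats tibble with `gene_id` and `stat` (signed), or a named
#'   numeric vector.
#' @param gene_set character vector of member gene ids.
#' @param weight exponent on `|stat|` for hit increments.
#' @param n_perm random set permutations in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param exhaustive_limit largest `choose(N, N_hits)` enumerated exactly.
#' @param min_set_size smallest post-intersection set size accepted (the
#'   degenerate single-member case is well defined; lower this to use it).
#' @return one-row tibble of class `"enrichment_result"`: `es`, `p`,
#'   `direction`, `n_set`; attribute `running` (the running-sum vector,
#'   ordered by rank).
#' @export
gsea_enrichment <- function(ranked_stats, gene_set, weight = 1,
                            n_perm = 1000, seed = 1, exhaustive_limit = 10000,
                            min_set_size = 3) {
  if (is.data.frame(ranked_stats)) {
    stats <- setNames(ranked_stats$stat, ranked_stats$gene_id)
  } else stats <- ranked_stats
  stats <- sort(stats, decreasing = TRUE)
  in_set <- names(stats) %in% gene_set
  nh <- sum(in_set)
  if (nh < min_set_size) abort("set smaller than minimum size after intersection")
  n <- length(stats)
  if (nh >= n) abort("gene set covers the whole ranked list")
  rs <- gsea_running_sum(stats, in_set, weight)
  es <- rs[which.max(abs(rs))]
  es_for <- function(idx) {
    member <- logical(n); member[idx] <- TRUE
    r <- gsea_running_sum(stats, member, weight)
    r[which.max(abs(r))]
  }
  exhaustive <- choose(n, nh) <= exhaustive_limit
  if (exhaustive) {
    perm_es <- vapply(combn(n, nh, simplify = FALSE), es_for, numeric(1))
    p <- mean(abs(perm_es) >= abs(es))
  } else {
    set.seed(seed)
    perm_es <- vapply(seq_len(n_perm), function(i) es_for(sample.int(n, nh)),
                      numeric(1))
    p <- (1 + sum(abs(perm_es) >= abs(es))) / (1 + n_perm)
  }
  out <- tibble(
    es = es, p = p,
    direction = ifelse(es >= 0, "up", "down"), n_set = nh
  )
  attr(out, "running") <- rs
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the given overlap between a
#' study subset and an annotation category drawn from a common background.
#'
#' @param subset,category,background character vectors of gene ids; subset
#'   and category must be contained in the background.
#' @return one-row tibble: `overlap`, `n_subset`, `n_category`,
#'   `n_background`, `expected`, `p`.
#' @export
overrepresentation_test <- function(subset, category, background) {
  subset <- unique(subset); category <- unique(category); background <- unique(background)
  if (!all(subset %in% background)) abort("subset not contained in background")
  if (!all(category %in% background)) abort("category not contained in background")
  ov <- length(intersect(subset, category))
  m <- length(category); N <- length(background); k <- length(subset)
  tibble(
    overlap = ov, n_subset = k, n_category = m, n_background = N,
    expected = k * m / N,
    p = phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
  )
}
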