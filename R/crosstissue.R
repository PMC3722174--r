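#' Classify genes into the eight cross-tissue dysregulation subsets
#'
#' Genes significant in both tissues fall into four signed quadrants
#' (up/up, up/down, down/up, down/down); genes significant in exactly one
#' tissue fall into four single-tissue subsets; the rest are unclassified.
#' The inverse fraction — the share of both-significant genes whose
#' directions disagree — summarizes how globally opposed the two tissue
#' responses are.
#'
#' @param results_a,results_b `sam_result` tibbles for the two tissues
#'   (need `feature_id`, `p`, `delta`).
#' @param p_cut significance threshold applied identically to both tissues.
#' @param tissue_names length-2 labels used in subset names.
#' @return list: `assignments` (tibble `feature_id`, `subset`), `counts`
#'   (tibble `subset`, `n`), `inverse_fraction`.
#' @export
quadrant_classify <- function(results_a, results_b, p_cut = 0.05,
                              tissue_names = c("muscle", "fibroblast")) {
  a <- results_a |> select("feature_id", p_a = "p", d_a = "delta")
  b <- results_b |> select("feature_id", p_b = "p", d_b = "delta")
  dat <- inner_join(a, b, by = "feature_id")
  if (nrow(dat) == 0) abort("empty shared gene universe")
  dir_of <- function(d) ifelse(d > 0, "up", "down")
  dat <- dat |>
    mutate(
      sig_a = .data$p_a < p_cut, sig_b = .data$p_b < p_cut,
      subset = dplyr::case_when(
        .data$sig_a & .data$sig_b ~
          paste0(dir_of(.data$d_a), "/", dir_of(.data$d_b)),
        .data$sig_a ~ paste0(tissue_names[1], "_only_", dir_of(.data$d_a)),
        .data$sig_b ~ paste0(tissue_names[2], "_only_", dir_of(.data$d_b)),
        TRUE ~ "unclassified"
      )
    )
  both <- dat |> filter(.data$sig_a & .data$sig_b)
  inverse_fraction <- if (nrow(both) == 0) NA_real_ else {
    mean(sign(both$d_a) * sign(both$d_b) < 0)
  }
  list(
    assignments = dat |> select("feature_id", "subset"),
    counts = dat |> dplyr::count(.data$subset, name = "n"),
    inverse_fraction = inverse_fraction
  )
}

#' Cross-tissue correlation of signed significance scores
#'
#' @param scores_a,scores_b tibbles from [signed_significance()].
#' @return one-row tibble: `r`, `p`, `n_shared`.
#' @export
crosstissue_correlation <- function(scores_a, scores_b) {
  dat <- inner_join(
    scores_a |> select("feature_id", score_a = "score"),
    scores_b |> select("feature_id", score_b = "score"),
    by = "feature_id"
  )
  if (nrow(dat) < 10) abort("need at least 10 shared genes")
  if (sd(dat$score_a) == 0 || sd(dat$score_b) == 0) abort("constant score vector")
  ct <- cor.test(dat$score_a, dat$score_b)
  tibble(r = unname(ct$estimate), p = ct$p.value, n_shared = nrow(dat))
}

#' DerSimonian-Laird meta-analysis of a gene-pair correlation
#'
#' The Pearson correlation of the two genes is computed within each sample
#' group (normally the four tissue x disease cells), transformed to Fisher
#' z with variance `1/(n_k - 3)`, and combined with the DerSimonian-Laird
#' random-effects estimator: `Q = sum w_k (z_k - z_bar_w)^2` with fixed
#' weights `w_k = 1/v_k`, between-group variance
#' `tau2 = max(0, (Q - (K-1)) / (sum w - sum w^2 / sum w))`, random-effects
#' weights `1/(v_k + tau2)`, and a normal approximation for the p-value of
#' the combined z.
#'
#' @param expr gene x sample tibble (theta scale; log2 is taken internally).
#' @param gene_a,gene_b gene ids present in `expr`.
#' @param design sample design tibble; groups are the tissue x disease cells.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return one-row tibble of class `"meta_correlation"`: `gene_a`, `gene_b`,
#'   `k_groups`, `Q`, `tau2`, `combined_z`, `combined_r`, `p`, plus a
#'   list-column `groups` holding the per-group `r_k`, `n_k`, `z_k`, `v_k`.
#' @export
meta_correlation <- function(expr, gene_a, gene_b, design,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- log2(expr_matrix(expr))
  if (!all(c(gene_a, gene_b) %in% rownames(m))) abort("gene not found in expression table")
  assert_design(design)
  groups <- split(design$sample_id, paste(design$tissue, design$disease, sep = "/"))
  per <- lapply(names(groups), function(g) {
    ids <- intersect(groups[[g]], colnames(m))
    if (length(ids) < 4) abort(paste0("group ", g, " has fewer than 4 samples"))
    r <- cor(m[gene_a, ids], m[gene_b, ids], method = method)
    tibble(group = g, r_k = r, n_k = length(ids))
  })
  per <- bind_rows(per)
  r <- per$r_k
  if (any(abs(r) >= 1)) {
    warn("correlation at +/-1 clamped for the Fisher transform")
    r <- pmin(pmax(r, -0.999999), 0.999999)
  }
  per$z_k <- atanh(r)
  per$v_k <- 1 / (per$n_k - 3)
  dl <- dl_combine(per$z_k, per$v_k)
  out <- tibble(
    gene_a = gene_a, gene_b = gene_b, k_groups = nrow(per),
    Q = dl$Q, tau2 = dl$tau2,
    combined_z = dl$z, combined_r = tanh(dl$z), p = dl$p,
    groups = list(per)
  )
  class(out) <- c("meta_correlation", class(out))
  out
}

# DerSimonian-Laird combination on the Fisher-z scale
dl_combine <- function(z, v) {
  w <- 1 / v
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  K <- length(z)
  tau2 <- if (K <= 1) 0 else max(0, (Q - (K - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  zc <- sum(ws * z) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  list(z = zc, Q = Q, tau2 = tau2, se = se, p = 2 * pnorm(-abs(zc / se)))
}

#' @export
tidy.meta_correlation <- function(x, ...) x$groups[[1]]

#' @export
glance.meta_correlation <- function(x, ...) {
  x |> select("gene_a", "gene_b", "k_groups", "Q", "tau2",
              "combined_z", "combined_r", "p")
}

#' Meta-correlation of a focal gene against a gene set
#'
#' Runs [meta_correlation()] of the focal gene against every member of the
#' set (the focal gene itself is excluded with a warning if present) and
#' tests the combined correlations against zero with a one-sample t-test.
#'
#' @param focal_gene gene id.
#' @param gene_set character vector of gene ids (>= 3 after exclusions).
#' @param expr gene x sample tibble (theta scale).
#' @param design sample design tibble.
#' @return list: `per_gene` (tibble `gene_id`, `combined_r`, `p`),
#'   `mean_r`, `p` (t-test of combined_r vs 0).
#' @export
geneset_meta_correlation_summary <- function(focal_gene, gene_set, expr, design) {
  if (focal_gene %in% gene_set) {
    warn("focal gene removed from its own gene set")
    gene_set <- setdiff(gene_set, focal_gene)
  }
  if (length(gene_set) < 3) abort("gene set needs at least 3 members")
  per <- bind_rows(lapply(gene_set, function(g) {
    mc <- meta_correlation(expr, focal_gene, g, design)
    tibble(gene_id = g, combined_r = mc$combined_r, p = mc$p)
  }))
  tt <- t.test(per$combined_r, mu = 0)
  list(per_gene = per, mean_r = mean(per$combined_r), p = tt$p.value)
}

#' Screen for genes correlated with a focal gene in both tissues
#'
#' Pearson correlation of each gene with the focal gene over the disease
#' samples of each tissue; genes passing `r > r_cut` and `p < p_cut` in
#' BOTH tissues are reported. The focal gene is excluded from its own
#' output.
#'
#' @param expr gene x sample tibble (theta scale).
#' @param design sample design tibble.
#' @param focal_gene gene id.
#' @param r_cut,p_cut per-tissue thresholds.
#' @param disease label of the disease samples used.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return tibble: `gene_id`, per-tissue `r_*` / `p_*`, `pass`.
#' @export
correlation_screen <- function(expr, design, focal_gene, r_cut = 0,
                               p_cut = 0.05, disease = "RC",
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- log2(expr_matrix(expr))
  if (!focal_gene %in% rownames(m)) abort("focal gene absent")
  assert_design(design)
  tissues <- unique(design$tissue)
  if (length(tissues) < 2) abort("both tissue datasets must be present")
  others <- setdiff(rownames(m), focal_gene)
  out <- tibble(gene_id = others)
  pass <- rep(TRUE, length(others))
  for (tis in tissues) {
    ids <- design$sample_id[design$tissue == tis & design$disease == disease]
    ids <- intersect(ids, colnames(m))
    n <- length(ids)
    if (n < 4) abort(paste0("tissue ", tis, " has fewer than 4 disease samples"))
    r <- as.numeric(cor(m[focal_gene, ids], t(m[others, ids, drop = FALSE]),
                        method = method))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    out[[paste0("r_", tis)]] <- r
    out[[paste0("p_", tis)]] <- p
    pass <- pass & (r > r_cut) & (p < p_cut)
  }
  out$pass <- pass
  out
}
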