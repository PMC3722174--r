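#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_col
#'   labs theme_minimal autoplot
NULL

#' Plot a positional UTR profile
#'
#' Disease-minus-control difference per relative-position bin with the
#' lowess-smoothed curve used for the gradient.
#'
#' @param object a `positional_profile`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.positional_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$mid)) +
    geom_point(aes(y = .data$diff), alpha = 0.4) +
    geom_line(aes(y = .data$smooth_diff), linewidth = 1) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(
      x = "relative position (5' → 3')",
      y = "disease - control (log2, exon-adjusted)",
      title = sprintf("%s positional profile (gradient %.3f / unit)",
                      attr(object, "region_kind"), attr(object, "gradient"))
    ) +
    theme_minimal()
}

#' Plot a GSEA running enrichment score
#'
#' @param object an `enrichment_result`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  rs <- attr(object, "running")
  dat <- tibble(rank = seq_along(rs), running = rs)
  ggplot(dat, aes(x = .data$rank, y = .data$running)) +
    geom_line(color = "darkgreen") +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "rank", y = "running enrichment score",
         title = sprintf("ES = %.3f, p = %.3g", object$es, object$p)) +
    theme_minimal()
}

#' Scatter plot of cross-tissue signed significance scores
#'
#' @param scores_a,scores_b tibbles from [signed_significance()].
#' @param tissue_names axis labels.
#' @return a ggplot.
#' @export
plot_crosstissue <- function(scores_a, scores_b,
                             tissue_names = c("muscle", "fibroblast")) {
  dat <- inner_join(
    scores_a |> select("feature_id", a = "score"),
    scores_b |> select("feature_id", b = "score"),
    by = "feature_id"
  )
  ggplot(dat, aes(x = .data$a, y = .data$b)) +
    geom_point(alpha = 0.3) +
    geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    labs(x = paste(tissue_names[1], "signed -log10 p"),
         y = paste(tissue_names[2], "signed -log10 p")) +
    theme_minimal()
}

#' Bar chart of the ARE class ladder
#'
#' @param are_test output of [are_group_change_test()].
#' @return a ggplot.
#' @export
plot_are_ladder <- function(are_test) {
  dat <- are_test |>
    mutate(are_class = factor(.data$are_class,
                              levels = c("none", ARE_LADDER)))
  ggplot(dat, aes(x = .data$are_class, y = .data$mean_change_pct)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0) +
    labs(x = "ARE class", y = "mean 3'-UTR change (%)") +
    theme_minimal()
}

#' PCA sample plot
#'
#' @param pca tibble from [pca_embed()].
#' @param design optional design tibble used to color points.
#' @return a ggplot.
#' @export
plot_pca <- function(pca, design = NULL) {
  dat <- pca
  if (!is.null(design)) {
    dat <- dat |> left_join(design, by = "sample_id") |>
      mutate(group = paste(.data$tissue, .data$disease))
  } else dat$group <- "samples"
  ve <- attr(pca, "var_explained")
  ggplot(dat, aes(x = .data$PC1, y = .data$PC2, color = .data$group)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * ve[2])) +
    theme_minimal()
}
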