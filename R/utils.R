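#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols distinct pull rename
#'   n across all_of row_number slice_min first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median sd quantile lowess t.test cor cor.test prcomp
#'   phyper pnorm setNames mad approx lm coef complete.cases rlnorm rnorm
#'   runif rbinom
#' @importFrom utils combn head
NULL

# Single place for the sample-column convention: every wide expression tibble
# has one id column (first) and one numeric column per sample.
sample_cols <- function(tbl) setdiff(names(tbl), names(tbl)[1])

#' Convert a wide expression tibble to a numeric matrix
#'
#' @param tbl a tibble whose first column is a feature id and remaining
#'   columns are per-sample numeric values.
#' @return numeric matrix with feature ids as rownames.
#' @export
expr_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric cell in expression table")
  rownames(m) <- as.character(tbl[[1]])
  m
}

#' Convert a feature x sample matrix back to a wide tibble
#'
#' @param m numeric matrix with rownames.
#' @param id_col name of the id column (default `"feature_id"`).
#' @return tibble.
#' @export
expr_tibble <- function(m, id_col = "feature_id") {
  out <- as_tibble(m)
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

# Deterministic fan-out of a global seed into per-stage seeds, kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    models = 101L, expression = 211L, preprocess = 307L, diffexp = 401L,
    subgene = 503L, utr = 601L, regulators = 701L, crosstissue = 809L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown stage: ", stage))
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

assert_design <- function(design) {
  need <- c("sample_id", "tissue", "disease")
  if (!all(need %in% names(design))) {
    abort("design must have columns sample_id, tissue, disease")
  }
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design")
  invisible(design)
}

# disease - control difference of group means, per row of a matrix
group_delta <- function(m, is_a, is_b) {
  rowMeans(m[, is_a, drop = FALSE]) - rowMeans(m[, is_b, drop = FALSE])
}

pct_change <- function(delta_log2) 100 * (2^delta_log2 - 1)
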