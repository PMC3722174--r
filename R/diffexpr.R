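#' SAM moderated difference statistic for one feature
#'
#' `d = (mean(a) - mean(b)) / (s + s0)` with
#' `s = sqrt((1/na + 1/nb) * (SS_a + SS_b) / (na + nb - 2))`, the pooled
#' two-group standard error; at `s0 = 0`, `d` is exactly the pooled-variance
#' two-sample t statistic.
#'
#' @param group_a,group_b numeric vectors (log2 expression).
#' @param s0 fudge factor added to the denominator (>= 0).
#' @return one-row tibble: `d`, `s`, `delta` (mean(a) - mean(b)).
#' @export
sam_statistic <- function(group_a, group_b, s0 = 0) {
  if (!length(group_a) || !length(group_b)) abort("empty group")
  if (s0 < 0) abort("s0 must be >= 0")
  na <- length(group_a); nb <- length(group_b)
  delta <- mean(group_a) - mean(group_b)
  df <- na + nb - 2
  s <- if (df <= 0) 0 else {
    ss <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
    sqrt((1 / na + 1 / nb) * ss / df)
  }
  tibble(d = delta / (s + s0), s = s, delta = delta)
}

# vectorized d/s/delta for all features over a set of group-a assignments
sam_stats_matrix <- function(x, assign_idx, na, s0) {
  nb <- ncol(x) - na
  ind <- matrix(0, ncol(x), length(assign_idx))
  for (k in seq_along(assign_idx)) ind[assign_idx[[k]], k] <- 1
  x2 <- x^2
  tot <- rowSums(x); tot2 <- rowSums(x2)
  sa <- x %*% ind; ssa <- x2 %*% ind
  sb <- tot - sa; ssb <- tot2 - ssa
  wa <- ssa - sa^2 / na
  wb <- ssb - sb^2 / nb
  df <- na + nb - 2
  s <- sqrt(pmax((1 / na + 1 / nb) * (wa + wb) / df, 0))
  delta <- sa / na - sb / nb
  list(d = delta / (s + s0), s = s, delta = delta)
}

#' Choose the SAM fudge factor s0
#'
#' Candidates are the percentiles {0, 5, ..., 100} of the per-feature pooled
#' standard errors `s`. For each candidate the features are binned into
#' `s`-quantile windows; the candidate minimizing the coefficient of
#' variation of the per-window median absolute deviations of `d` is chosen
#' (ties break to the smallest candidate). Deterministic and invariant to
#' feature order.
#'
#' @param s per-feature pooled standard errors.
#' @param delta per-feature mean differences.
#' @param n_windows number of s-quantile windows (capped by feature count).
#' @return the chosen s0 (a scalar).
#' @export
choose_s0 <- function(s, delta, n_windows = 100) {
  if (length(s) < 10) abort("need at least 10 features to choose s0")
  if (all(s == 0)) abort("all pooled standard errors are zero")
  cand <- unname(quantile(s, seq(0, 1, by = 0.05)))
  n_windows <- max(2, min(n_windows, floor(length(s) / 5)))
  breaks <- unique(quantile(s, seq(0, 1, length.out = n_windows + 1)))
  if (length(breaks) < 3) return(min(cand))  # degenerate: every candidate ties
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- delta / (s + a)
    mads <- tapply(d, win, mad)
    mads <- mads[!is.na(mads)]
    mu <- mean(mads)
    if (mu == 0) 0 else sd(mads) / abs(mu)
  }, numeric(1))
  cand[which.min(cv)]  # which.min takes the first (smallest) on ties
}

#' SAM permutation test over a two-group design
#'
#' Computes the SAM statistic for every feature, then permutes the group
#' labels: exhaustively over all `choose(n, na)` group-a assignments when
#' that count is at most `exhaustive_limit`, otherwise `n_perm` random
#' assignments. The permutation p-value is the fraction of assignments with
#' `|d_perm| >= |d_obs|` (exact count over the enumeration in exhaustive
#' mode; with a +1 correction in sampled mode). The false discovery rate at
#' each feature's own cut `c = |d|` is the SAM median ratio
#' `median_perm(#{|d_perm| >= c}) / #{|d_obs| >= c}`, capped at 1.
#'
#' @param expr wide tibble (feature id + one numeric column per sample) of
#'   log2 expression.
#' @param labels group label per sample column (length = number of samples).
#' @param group_a label of the first group (differences are `a - b`);
#'   defaults to the first label encountered.
#' @param n_perm random permutations when exhaustive enumeration is not
#'   feasible.
#' @param seed RNG seed for sampled permutations.
#' @param s0 fudge factor; `NULL` chooses it with [choose_s0()].
#' @param pool if `TRUE`, p-values are computed against the permutation null
#'   pooled across all features (the classic SAM reference distribution,
#'   which makes p monotone in `|d|` across features); the default compares
#'   each feature against its own permuted statistics.
#' @param exhaustive_limit largest enumeration size used for exact mode.
#' @return tibble of class `"sam_result"`: `feature_id`, `delta`,
#'   `mean_change_pct`, `d`, `s`, `p`, `q_fdr`, `direction`; attributes
#'   `s0`, `n_perm`, `exhaustive`.
#' @export
sam_test <- function(expr, labels, group_a = NULL, n_perm = 200, seed = 1,
                     s0 = NULL, pool = FALSE, exhaustive_limit = 10000) {
  x <- expr_matrix(expr)
  if (length(labels) != ncol(x)) abort("labels must match sample columns")
  lv <- unique(labels)
  if (length(lv) != 2) abort("exactly two groups required")
  group_a <- group_a %||% lv[1]
  is_a <- labels == group_a
  na <- sum(is_a); nb <- sum(!is_a)
  if (na < 2 || nb < 2) abort("each group needs at least 2 samples")
  # put group-a columns in a canonical order: observed assignment = indices
  obs <- sam_stats_matrix(x, list(which(is_a)), na, 0)
  if (is.null(s0)) s0 <- choose_s0(as.numeric(obs$s), as.numeric(obs$delta))
  d_obs <- as.numeric(obs$delta) / (as.numeric(obs$s) + s0)

  n <- ncol(x)
  exhaustive <- choose(n, na) <= exhaustive_limit
  if (exhaustive) {
    assigns <- combn(n, na, simplify = FALSE)
  } else {
    if (n_perm < 100) abort("n_perm must be >= 100 in sampled mode")
    set.seed(seed)
    assigns <- lapply(seq_len(n_perm), function(i) sample.int(n, na))
  }
  K <- length(assigns)
  abs_obs <- abs(d_obs)
  # tie guard: complementary assignments reproduce |d_obs| up to float
  # rounding and must count as "at least as extreme"
  cuts <- abs_obs - 1e-9 * pmax(abs_obs, 1)
  cnt_ge <- integer(nrow(x))
  n_ge_perm <- matrix(0L, nrow(x), K)
  chunk <- 1000
  for (start in seq(1, K, by = chunk)) {
    ix <- start:min(start + chunk - 1, K)
    dP <- abs(sam_stats_matrix(x, assigns[ix], na, s0)$d)
    cnt_ge <- cnt_ge + rowSums(dP >= rep(cuts, ncol(dP)))
    for (j in seq_along(ix)) {
      v <- sort(dP[, j])
      # per cut c_i: how many permuted |d| are >= c_i
      n_ge_perm[, ix[j]] <- nrow(x) - findInterval(cuts, v, left.open = TRUE)
    }
  }
  p <- if (pool) {
    pooled <- rowSums(n_ge_perm)
    if (exhaustive) pooled / (nrow(x) * K) else (1 + pooled) / (1 + nrow(x) * K)
  } else if (exhaustive) cnt_ge / K else (1 + cnt_ge) / (1 + K)
  n_ge_obs <- nrow(x) + 1 - rank(abs_obs, ties.method = "min")
  med_perm <- apply(n_ge_perm, 1, median)
  q <- pmin(1, med_perm / pmax(n_ge_obs, 1))
  delta <- as.numeric(obs$delta)
  out <- tibble(
    feature_id = rownames(x),
    delta = delta,
    mean_change_pct = pct_change(delta),
    d = d_obs,
    s = as.numeric(obs$s),
    p = p,
    q_fdr = q,
    direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "flat"))
  )
  attr(out, "s0") <- s0
  attr(out, "n_perm") <- K
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("sam_result", class(out))
  out
}

#' @export
glance.sam_result <- function(x, ...) {
  tibble(
    n_features = nrow(x), s0 = attr(x, "s0"),
    n_perm = attr(x, "n_perm"), exhaustive = attr(x, "exhaustive"),
    n_p05 = sum(x$p < 0.05)
  )
}

#' Signed significance scores
#'
#' Default: `score = sign(delta) * (-log10 p)`; features with no change
#' score 0. The bounded alternative `sign(delta) * (1 - p)` is available
#' for plots that need a finite axis.
#'
#' @param result a `sam_result` tibble (needs `delta` and `p`).
#' @param method `"neg_log10_p"` (default) or `"one_minus_p"`.
#' @return tibble: `feature_id`, `score`.
#' @export
signed_significance <- function(result, method = c("neg_log10_p", "one_minus_p")) {
  method <- match.arg(method)
  if (any(result$p <= 0)) abort("p must be > 0")
  mag <- switch(method,
    neg_log10_p = -log10(result$p),
    one_minus_p = 1 - result$p
  )
  tibble(
    feature_id = result$feature_id,
    score = sign(result$delta) * mag
  )
}
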